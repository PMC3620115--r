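Package: turbidmc
Title: Monte Carlo Photon Transport in Mesh-Bounded Turbid Media with
    Free-Space CCD Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates photon-packet migration through heterogeneous turbid
    media (biological tissue) bounded by nested closed triangular surface
    meshes, using the weighted Monte Carlo method: exponential step sampling,
    Henyey-Greenstein scattering, Fresnel reflection and Snell refraction at
    refractive-index mismatches, continuous absorption deposition and Russian
    roulette termination. Supports continuous-wave and time-domain runs,
    fluorescence excitation/emission conversion, and forward simulation of
    bioluminescence, diffuse-optical and fluorescence tomography experiments.
    Surface transmittance is mapped to CCD detector images at arbitrary view
    angles through a thin-lens/pinhole position mapping and a Lambertian
    cosine-law energy mapping with visibility testing. Includes phantom mesh
    generators, STL/PLY/OFF mesh input and output, JSON configuration files,
    packaged example experiments, line-profile/NRMSE analysis utilities and a
    command-line interface. The photon tracing core is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
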