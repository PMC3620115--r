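---
title: "Photon transport in mesh-bounded turbid media: model, assumptions and numerical policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon transport in mesh-bounded turbid media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbidmc)
```

## The physical model

Biological tissue both absorbs and scatters light. `turbidmc` solves the
radiative transfer problem by the weighted Monte Carlo method: the source
power is split into `n_photons` packets of initial weight
`total_power / n_photons`, and each packet performs a random walk whose
local rules are probability distributions derived from the optical
properties of the medium it currently occupies:

* **absorption coefficient** μa (mm⁻¹) and **scattering coefficient** μs
  (mm⁻¹) — interaction probabilities per unit length; their sum sets the
  mean free path 1/(μa+μs);
* **anisotropy factor** g ∈ (−1, 1) — the mean cosine of the
  single-scattering deflection angle under the Henyey–Greenstein phase
  function (tissue is strongly forward-scattering, g ≈ 0.85–0.95);
* **refractive index** n ≥ 1 — governs Fresnel reflection, Snell
  refraction and the speed of light in the medium.

Geometry is a tree of **nested closed triangular surface meshes**: every
region has a unique parent (another region or the ambient medium), there
is exactly one outermost surface, and a child mesh must lie strictly
inside its parent. Region transitions at a triangle hit are deduced in
O(1) from the sign of `direction · outward normal` — entering the
triangle's region when moving against its normal — rather than by
point-membership re-tests.

The walk cycle is: sample a step; if a boundary is nearer, interact with
it (all-or-nothing reflect/refract against the Fresnel reflectance, with
the residual dimensionless step carried across the interface and rescaled
by the new medium's μa+μs); otherwise deposit `w·μa/(μa+μs)` at the
interaction site, optionally test fluorescence conversion, scatter, and
apply Russian roulette when the weight falls below the threshold.
Transmission through the outermost boundary terminates the packet and
records its residual weight.

Two recorders follow directly from the walk: a **transmittance record**
of exited weight (per boundary triangle always; additionally binned into
six rows×cols per-face matrices when the outer surface is an axis-aligned
cube) and an **absorption voxel grid** of deposited weight with an
overflow bucket, so no weight is ever silently lost. Time-domain runs
add a clock `t += s·n/c` (c = 0.299792458 mm/ps) and gate every recorder;
events after the last gate land in an overflow gate, again so that
accounting stays exact.

## Free-space imaging

Photons leaving the tissue travel in straight lines. The camera model is
an ideal thin lens focused on the scene: object distance u, image
distance v with 1/u + 1/v = 1/f (enforced at construction to 1e−9). The
central ray through the lens centre maps a surface point at axial
distance `u_P` and lateral height h to the detector at `−h·v/u_P`
(inverted, magnification v/u). Energy is evaluated on the object-side
conjugate of the detector (the virtual detector plane at distance v in
front of the lens) with the Lambertian kernel

    dE = J cosθs cosθd ξ(r, r_d) dS / (π |r − r_d|²),

and carried to the detector pixel unchanged, since the pinhole mapping
preserves flux density between a point and its conjugate. The π in the
denominator is the Lambertian radiosity normalization (a diffuse emitter
of radiosity J has radiance J/π). The visibility factor ξ is a 0/1
segment–mesh intersection test; back-facing elements are culled by the
cosθs clamp rather than a separate test. Pixel assignment is
nearest-pixel with no anti-aliasing, so images are bit-reproducible.

**Geometric constraint worth knowing:** the virtual detector plane sits
at distance v in front of the lens. Configure cameras with u > 2f (so
v < u) and a lens distance large enough that v stays outside the scene;
otherwise the conjugate plane slices the phantom and the visibility test
correctly, but unhelpfully, reports the scene itself as the occluder.
The packaged cube example uses f = 25 mm, u = 100 mm (v ≈ 33 mm, lens at
100 mm from the origin of a 10 mm phantom).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `roulette_threshold` | 1e−4 | roulette trigger, as a fraction of the initial packet weight; 0 disables roulette (exact energy balance) |
| `roulette_m` | 10 | survival constant: survive with probability 1/m at weight m·w |
| `max_steps` | 1e6 | per-packet step cap guarding pathological configurations; capped weight goes to a diagnostics bucket and a warning is emitted |
| `gates` | c(0, 100, 10) ps | time gates (start, stop, Δt) for `mode = "td"` |
| `seed` | 1 | run seed; every photon gets its own splitmix64 stream keyed by (seed, photon index), so results do not depend on tracing order |
| `ambient_n` | 1.0 | refractive index of the surrounding free space |

## Numerical policies

* **Epsilon policy.** After any boundary event the packet is nudged
  1e−7 mm along its new direction, and ray queries discard hits closer
  than 1e−7 mm; this prevents self-intersection without perceptibly
  biasing path lengths (the mean free path in the packaged phantoms is
  ≥ 0.02 mm).
* **Ray–triangle tests** are Möller–Trumbore with inclusive edges
  (tolerance 1e−12 in barycentric units); coincident hits resolve to the
  smallest triangle id, so replays are deterministic. Meshes above 1000
  triangles are traversed through an axis-aligned bounding-box hierarchy
  whose results are required — and tested — to be identical to the
  brute-force scan.
* **Degenerate scattering frames.** The local-frame direction update
  switches to the degenerate formula when |uz| > 0.99999.
* **HG clamping.** The closed-form HG cosine is clamped to [−1, 1]
  against floating-point overshoot.
* **Normal-incidence Fresnel** switches to the ((ni−nt)/(ni+nt))² limit
  above cosθi > 1 − 1e−9 to avoid 0/0 in the oblique forms.
* **Mesh validation** (closedness, outward orientation, degeneracy,
  nesting) runs once at scene construction, not per query.

## Design choices where the design was genuinely open

* **Continuous absorption weighting.** Packets deposit
  `w·μa/(μa+μs)` per interaction instead of dying on an absorption draw.
  This is the standard variance-reduction choice of the multi-layer
  Monte Carlo lineage this engine follows, and it makes the energy-
  conservation contract exact rather than statistical.
* **Isotropic internal emission** uses cosθ uniform on [−1, 1] (true
  isotropy). Describing an isotropic source by "a deflection angle on
  [0, π]" is ambiguous — uniform-in-angle is not isotropic — and we
  resolve it physically.
* **External-beam entry loss.** A beam entering the tissue pays the
  Fresnel reflectance at its actual incidence angle, logged as a separate
  specular channel so the balance closes; for the perpendicular
  illumination used by all packaged examples this reduces exactly to the
  normal-incidence constant ((n₁−n₂)/(n₁+n₂))².
* **All-or-nothing boundary draws** (no packet splitting) at internal
  and external interfaces alike, matching the single-uniform-comparison
  rule of the flowchart this engine implements.
* **Frequency-domain data are derived, not tracked.** `td_to_fd()`
  computes `Σ h_k exp(−i2πf t_k)` over gate centres of a time-domain
  record; f = 0 reproduces the CW total. Native phase tracking is out of
  scope.
* **Fluorescence conversion fires once per interaction site** of an
  excitation packet inside the fluorophore region, before scattering; the
  emission packet inherits the full residual weight, position and clock,
  and emission packets never re-convert (no re-absorption cascade).
* **Time-gated transmittance** is recorded per-triangle × gate plus
  exit-time histograms; the 300×300 cube face grids are continuous-wave
  (a full face-grid × gate product would cost ~50 MB per band at default
  sizes with no example needing it).

## What the packaged generators emulate — and what they do not

`builtin_example()` ships three experiments whose parameters are the
published study conditions: the homogeneous BLT cube (10 mm, μa 0.0002,
μs 11.7, g 0.95, n 1.37, source 3 mm under a face, 300×300 face matrices,
four CCDs at 90°, ten million packets), the DOT contrast scene
(heterogeneous organ properties at 670 nm with a solid tumor of μa 0.55,
μs 29.5, external perpendicular beam, 0.5 mm absorption voxels) and the
TD FMT scene (two-wavelength 620/690 nm tables, η = 0.6 fluorophore in
the right kidney, 10 ps gates on [0, 100) ps).

The `dot_mouse`/`fmt_td` anatomy is an explicitly **synthetic, schematic
stand-in**: nested ellipsoidal "organs" placed inside an ellipsoidal body
surface, chosen to preserve the computational content (nested
heterogeneous regions, realistic property contrasts, an external beam)
without the digital-mouse atlas geometry, which is not distributable with
this package. Consequences: organ volumes, depths and inter-organ
distances are not anatomical, so absolute transmittance levels and gate
occupancies differ from figures produced on the atlas; what is preserved
is the physics (property-driven contrast, time-of-flight ordering,
excitation/emission separation). Passing tests on these phantoms
demonstrate correctness of the transport and imaging operators, not
agreement with any animal-derived dataset. Likewise, no CCD noise,
spectral filter curves or camera calibration are modelled, so comparisons
against laboratory camera data are out of scope.

## Problem sizes used by the test-suite

The published experiments use 10⁷ packets; the suite runs the same
configurations at 10³–10⁵ packets, which keeps the full test run in the
low minutes on one CPU while leaving Monte Carlo counting errors small
enough for 3-standard-error assertions (at 10⁵ packets a face total of
~0.17 carries a relative SE of ~0.7 %). Statistical checks state their
tolerances as multiples of exact standard errors computed from the run
itself (per-face Σw² from the exit log), never as hand-tuned constants.

## Known limitations

* Sibling regions must not intersect; validation checks child-in-parent
  nesting but mutual sibling overlap is the caller's responsibility.
* The parity-based point-locator and the watertightness contract assume
  clean closed meshes; meshes read from files are validated on read, but
  geometrically self-intersecting (yet topologically closed) meshes are
  not detected.
* A region source samples by rejection from the mesh bounding box, which
  is slow for very thin or highly concave source regions; prefer
  `"sphere"`/`"point"` sources there.
* Reflectance/transmittance recording keys off the outermost boundary
  only; light re-entering the tissue after exit (possible only with
  concave outer surfaces) is not re-traced, consistent with the
  terminate-on-exit rule.
* The camera model is an ideal pinhole with thin-lens conjugates: no
  finite aperture, depth of field, aberrations or detector noise.
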