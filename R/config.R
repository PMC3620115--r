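# Simulation configuration: a validated, serializable description of a
# whole experiment (scene + source + optional fluorophore + run controls +
# recorders + cameras). The JSON schema mirrors the constructor arguments;
# a legacy flat key=value parameter-file grammar is also accepted.

known_keys <- list(
  top = c("scene", "source", "fluorophore", "controls", "recorders",
          "cameras", "output_dir"),
  scene = c("ambient_n", "regions"),
  region = c("id", "parent", "generator", "mesh_path", "mu_a", "mu_s", "g",
             "n", "emission"),
  generator = c("type", "side", "subdivisions", "center", "semi_axes",
                "radius", "refinement"),
  source = c("kind", "position", "radius", "region", "direction",
             "total_power", "n_photons", "band"),
  fluorophore = c("region", "eta"),
  controls = c("n_photons", "seed", "roulette_threshold", "roulette_m",
               "mode", "gates", "max_steps"),
  recorders = c("face_grid", "absorption", "exit_log_cap"),
  cameras = c("n_views", "radius", "f", "u", "npix", "pitch", "axis"))

#' Parse and validate a simulation configuration
#'
#' Accepts a JSON document (path or literal text) or a legacy flat
#' `key = value` parameter file (see Details). All validation errors are
#' collected and reported together, including unknown keys and missing
#' required sections. The returned object serializes losslessly through
#' [write_config()] (`parse_config(write_config(c))` equals `c`).
#'
#' @details The legacy grammar is one `key = value` pair per line, `#`
#' comments, with dotted key paths addressing the JSON structure
#' (`scene.ambient_n = 1`, `region.1.id = phantom`,
#' `region.1.generator.type = cube`, `source.kind = sphere`, ...); list
#' values are comma-separated (`source.position = 0,0,2`).
#'
#' @param x path to a `.json` or parameter file, or a JSON string.
#' @return a `simulation_config`.
#' @export
parse_config <- function(x) {
  if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x)) {
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  } else txt <- x
  lst <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else parse_flat_params(txt)
  validate_config(lst)
}

parse_flat_params <- function(txt) {
  lines <- strsplit(txt, "\n")[[1]]
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("legacy parameter line not of the form key = value: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    v <- if (any(is.na(num))) val else num
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (path[1] == "region") {
      i <- as.integer(path[2])
      path <- c("scene", "regions", path[-(1:2)])
      if (is.null(out$scene$regions)) out$scene$regions <- list()
      while (length(out$scene$regions) < i) out$scene$regions <-
          c(out$scene$regions, list(list()))
      out$scene$regions[[i]] <- assign_path(out$scene$regions[[i]], path[-(1:2)], v)
    } else {
      out <- assign_path(out, path, v)
    }
  }
  out
}

assign_path <- function(lst, path, value) {
  if (length(path) == 1) { lst[[path]] <- value; return(lst) }
  if (is.null(lst[[path[1]]])) lst[[path[1]]] <- list()
  lst[[path[1]]] <- assign_path(lst[[path[1]]], path[-1], value)
  lst
}

validate_config <- function(lst) {
  errs <- character()
  chk_keys <- function(obj, allowed, where) {
    unk <- setdiff(names(obj), allowed)
    if (length(unk))
      errs <<- c(errs, paste0("unknown key(s) in ", where, ": ",
                              paste(unk, collapse = ", ")))
  }
  chk_keys(lst, known_keys$top, "config")
  for (req in c("scene", "source", "controls"))
    if (is.null(lst[[req]])) errs <- c(errs, paste0("missing required section: ", req))
  if (!is.null(lst$scene)) {
    chk_keys(lst$scene, known_keys$scene, "scene")
    regs <- lst$scene$regions
    if (is.null(regs) || !length(regs)) {
      errs <- c(errs, "scene must declare at least one region")
    } else {
      ids <- vapply(regs, function(r) as.character(r$id %||% NA), "")
      for (i in seq_along(regs)) {
        r <- regs[[i]]
        w <- paste0("scene.regions[", i, "]")
        chk_keys(r, known_keys$region, w)
        if (is.null(r$id)) errs <- c(errs, paste0(w, ": missing id"))
        if (is.null(r$generator) && is.null(r$mesh_path))
          errs <- c(errs, paste0(w, ": needs a generator or mesh_path"))
        if (!is.null(r$generator))
          chk_keys(r$generator, known_keys$generator, paste0(w, ".generator"))
        for (fld in c("mu_a", "mu_s", "g", "n"))
          if (is.null(r[[fld]])) errs <- c(errs, paste0(w, ": missing ", fld))
        if (!is.null(r$g) && abs(r$g) >= 1)
          errs <- c(errs, paste0(w, ": anisotropy g must lie in (-1, 1)"))
        if (!is.null(r$mu_a) && r$mu_a < 0) errs <- c(errs, paste0(w, ": mu_a < 0"))
        if (!is.null(r$mu_s) && r$mu_s < 0) errs <- c(errs, paste0(w, ": mu_s < 0"))
        if (!is.null(r$n) && r$n < 1) errs <- c(errs, paste0(w, ": n < 1"))
        pr <- as.character(r$parent %||% "ambient")
        if (pr != "ambient" && !pr %in% ids)
          errs <- c(errs, paste0(w, ": unresolved parent '", pr, "'"))
      }
    }
  }
  if (!is.null(lst$source)) {
    chk_keys(lst$source, known_keys$source, "source")
    if (is.null(lst$source$kind)) {
      errs <- c(errs, "source: missing kind")
    } else if (!lst$source$kind %in% c("point", "sphere", "region", "beam")) {
      errs <- c(errs, paste0("source: unknown kind '", lst$source$kind, "'"))
    }
    if (identical(lst$source$kind, "region")) {
      ids <- vapply(lst$scene$regions %||% list(), function(r)
        as.character(r$id %||% ""), "")
      if (!is.null(lst$source$region) && !lst$source$region %in% ids)
        errs <- c(errs, paste0("source: unresolved region '", lst$source$region, "'"))
    }
  }
  if (!is.null(lst$fluorophore)) {
    chk_keys(lst$fluorophore, known_keys$fluorophore, "fluorophore")
    ids <- vapply(lst$scene$regions %||% list(), function(r)
      as.character(r$id %||% ""), "")
    if (!is.null(lst$fluorophore$region) && !lst$fluorophore$region %in% ids)
      errs <- c(errs, paste0("fluorophore: unresolved region '",
                             lst$fluorophore$region, "'"))
    if (!is.null(lst$fluorophore$eta) &&
        (lst$fluorophore$eta < 0 || lst$fluorophore$eta > 1))
      errs <- c(errs, "fluorophore: eta must lie in [0, 1]")
  }
  if (!is.null(lst$controls)) {
    chk_keys(lst$controls, known_keys$controls, "controls")
    if (!is.null(lst$controls$roulette_m) && lst$controls$roulette_m <= 1)
      errs <- c(errs, "controls: roulette_m must be > 1")
  }
  if (!is.null(lst$recorders)) chk_keys(lst$recorders, known_keys$recorders,
                                        "recorders")
  if (!is.null(lst$cameras)) chk_keys(lst$cameras, known_keys$cameras, "cameras")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(lst, class = "simulation_config")
}

#' Serialize a configuration to JSON
#'
#' @param config a `simulation_config`.
#' @param path optional output path; when `NULL` the JSON text is
#'   returned.
#' @export
write_config <- function(config, path = NULL) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every output
#' file so results can be traced to the exact configuration.
#' @param config a `simulation_config`.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tf)
  unname(tools::md5sum(tf))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", length(x$scene$regions), "region(s), source kind",
      x$source$kind, "\n")
  cat(write_config(x), "\n")
  invisible(x)
}

#' Build runnable objects from a configuration
#'
#' Realizes the scene (running the mesh generators or readers), source,
#' controls, optional fluorophore, recorder spec and camera set described
#' by a configuration.
#'
#' @param config a `simulation_config`.
#' @param base_dir directory against which relative `mesh_path`s resolve.
#' @return list with `scene`, `source`, `controls`, `fluorophore`,
#'   `recorders`, `cameras`.
#' @export
build_simulation <- function(config, base_dir = ".") {
  stopifnot(inherits(config, "simulation_config"))
  regs <- lapply(config$scene$regions, function(r) {
    mesh <- if (!is.null(r$generator)) {
      g <- r$generator
      switch(g$type,
             cube = make_cube_phantom(g$side, g$subdivisions %||% 1L,
                                      g$center %||% c(0, 0, 0)),
             ellipsoid = make_ellipsoid_mesh(g$semi_axes,
                                             g$center %||% c(0, 0, 0),
                                             g$refinement %||% 3L),
             sphere = make_sphere_mesh(g$radius, g$center %||% c(0, 0, 0),
                                       g$refinement %||% 3L),
             stop("unknown generator type: ", g$type))
    } else {
      p <- r$mesh_path
      if (!file.exists(p)) p <- file.path(base_dir, r$mesh_path)
      read_mesh(p)
    }
    em <- if (!is.null(r$emission))
      optical_props(r$emission$mu_a, r$emission$mu_s, r$emission$g, r$emission$n)
    region(r$id, mesh, optical_props(r$mu_a, r$mu_s, r$g, r$n),
           parent = r$parent %||% "ambient", emission_props = em)
  })
  sc <- scene(regs, ambient_n = config$scene$ambient_n %||% 1.0)
  s <- config$source
  src <- source_spec(s$kind, position = s$position, radius = s$radius,
                     region = s$region, direction = s$direction,
                     total_power = s$total_power %||% 1,
                     n_photons = s$n_photons %||%
                       (config$controls$n_photons %||% 1e5),
                     band = s$band %||%
                       (if (is.null(config$fluorophore)) "single" else "excitation"))
  ctl <- config$controls
  controls <- run_controls(
    n_photons = ctl$n_photons %||% src$n_photons,
    seed = ctl$seed %||% 1L,
    roulette_threshold = ctl$roulette_threshold %||% 1e-4,
    roulette_m = ctl$roulette_m %||% 10,
    mode = ctl$mode %||% "cw",
    gates = ctl$gates %||% c(0, 100, 10),
    max_steps = ctl$max_steps %||% 1e6)
  fl <- if (!is.null(config$fluorophore))
    fluorophore_spec(config$fluorophore$region, config$fluorophore$eta)
  rec <- config$recorders %||% list()
  recorders <- recorder_spec(face_grid = rec$face_grid,
                             absorption = rec$absorption,
                             exit_log_cap = rec$exit_log_cap %||% 0L)
  cams <- NULL
  if (!is.null(config$cameras)) {
    cc <- config$cameras
    tmpl <- camera_model(lens_center = c(cc$radius, 0, 0),
                         optical_axis = c(-1, 0, 0), f = cc$f, u = cc$u,
                         npix = cc$npix %||% c(120, 120),
                         pitch = cc$pitch %||% 0.1)
    cams <- place_cameras(cc$n_views %||% 1, cc$radius, tmpl,
                          axis = cc$axis %||% c(0, 0, 1))
  }
  list(scene = sc, source = src, controls = controls, fluorophore = fl,
       recorders = recorders, cameras = cams)
}

#' Packaged example configurations
#'
#' Three ready-to-run forward experiments:
#' \describe{
#'   \item{`blt_cube`}{Continuous-wave bioluminescence phantom: a
#'     homogeneous 10 mm cube (`mu_a` 0.0002 mm^-1, `mu_s` 11.7 mm^-1,
#'     `g` 0.95, `n` 1.37), an internal isotropic source region 3 mm below
#'     the top face, 300 x 300 per-face transmittance matrices, and four
#'     CCD cameras at 0/90/180/270 degrees.}
#'   \item{`dot_mouse`}{Continuous-wave diffuse-optical contrast scene: a
#'     *synthetic, simplified* stand-in for a digital-mouse atlas — nested
#'     ellipsoidal "organs" carrying the published heterogeneous property
#'     table (lung, kidney, heart, stomach, liver and a solid tumor:
#'     `mu_a` 0.55, `mu_s` 29.5) inside a body surface, illuminated by an
#'     external perpendicular beam, with a 0.5 mm absorption voxel grid.}
#'   \item{`fmt_td`}{Time-domain fluorescence scene on the same schematic
#'     anatomy: two-wavelength property tables (620 nm excitation, 690 nm
#'     emission), a fluorophore of quantum efficiency 0.6 in the right
#'     kidney, an external excitation beam, and ten 10 ps time gates on
#'     [0, 100) ps.}
#' }
#' The photon count defaults to ten million; pass smaller counts through
#' [run_simulation()]'s controls (or the CLI `--photons` flag) for quick
#' runs.
#'
#' @param name one of `"blt_cube"`, `"dot_mouse"`, `"fmt_td"`.
#' @return a `simulation_config`.
#' @export
builtin_example <- function(name) {
  if (!name %in% c("blt_cube", "dot_mouse", "fmt_td"))
    stop("unknown example '", name,
         "'; available: blt_cube, dot_mouse, fmt_td")
  if (name == "blt_cube") {
    lst <- list(
      scene = list(ambient_n = 1.0, regions = list(
        list(id = "phantom", parent = "ambient",
             generator = list(type = "cube", side = 10, subdivisions = 1),
             mu_a = 0.0002, mu_s = 11.7, g = 0.95, n = 1.37),
        list(id = "source_region", parent = "phantom",
             generator = list(type = "sphere", radius = 0.5,
                              center = c(0, 0, 2), refinement = 2),
             mu_a = 0.0002, mu_s = 11.7, g = 0.95, n = 1.37))),
      source = list(kind = "region", region = "source_region",
                    total_power = 1, n_photons = 1e7, band = "single"),
      controls = list(n_photons = 1e7, seed = 1, roulette_threshold = 1e-4,
                      roulette_m = 10, mode = "cw"),
      recorders = list(face_grid = list(side = 10, rows = 300, cols = 300,
                                        center = c(0, 0, 0)),
                       exit_log_cap = 0),
      cameras = list(n_views = 4, radius = 100, f = 25, u = 100,
                     npix = c(150, 150), pitch = 0.05),
      output_dir = "blt_cube_out")
  } else {
    organs <- list(
      list(id = "lung", semi = c(3, 2, 2), center = c(7, 0, 1)),
      list(id = "heart", semi = c(2, 1.7, 1.7), center = c(2.5, 2.5, -1)),
      list(id = "stomach", semi = c(2.2, 1.8, 1.8), center = c(-1.5, -3, 0)),
      list(id = "liver", semi = c(2.8, 2, 2), center = c(-6, 0, -1)),
      list(id = "kidney_r", semi = c(1.6, 1.2, 1.2), center = c(-1.5, 3, -2)))
    if (name == "dot_mouse") {
      # property table at 670 nm: mu_a, mu_s, g, n per tissue
      tab <- list(surface = c(0.004, 20.13, 0.94, 1.37),
                  lung = c(0.196, 36.23, 0.94, 1.37),
                  kidney_r = c(0.066, 16.09, 0.86, 1.37),
                  heart = c(0.059, 6.42, 0.85, 1.37),
                  stomach = c(0.011, 17.96, 0.92, 1.37),
                  liver = c(0.035, 6.78, 0.9, 1.37),
                  tumor = c(0.55, 29.5, 0.9, 1.37))
      regs <- c(
        list(list(id = "surface", parent = "ambient",
                  generator = list(type = "ellipsoid", semi_axes = c(15, 7, 7),
                                   refinement = 3),
                  mu_a = tab$surface[1], mu_s = tab$surface[2],
                  g = tab$surface[3], n = tab$surface[4])),
        lapply(organs, function(o) {
          p <- tab[[o$id]]
          list(id = o$id, parent = "surface",
               generator = list(type = "ellipsoid", semi_axes = o$semi,
                                center = o$center, refinement = 2),
               mu_a = p[1], mu_s = p[2], g = p[3], n = p[4])
        }),
        list(list(id = "tumor", parent = "surface",
                  generator = list(type = "ellipsoid",
                                   semi_axes = c(1.5, 1.2, 1.2),
                                   center = c(1, -2, 4), refinement = 2),
                  mu_a = tab$tumor[1], mu_s = tab$tumor[2],
                  g = tab$tumor[3], n = tab$tumor[4])))
      lst <- list(
        scene = list(ambient_n = 1.0, regions = regs),
        source = list(kind = "beam", position = c(1, -2, 20),
                      direction = c(0, 0, -1), total_power = 1,
                      n_photons = 1e7, band = "single"),
        controls = list(n_photons = 1e7, seed = 1, roulette_threshold = 1e-4,
                        roulette_m = 10, mode = "cw"),
        recorders = list(absorption = list(origin = c(-4, -7, -1),
                                           spacing = 0.5,
                                           dims = c(20, 20, 16)),
                         exit_log_cap = 0),
        output_dir = "dot_mouse_out")
    } else {
      # two-band property table: excitation 620 nm / emission 690 nm
      ex <- list(surface = c(0.0088, 20.97, 0.94, 1.37),
                 heart = c(0.138, 7.18, 0.85, 1.37),
                 stomach = c(0.026, 19.36, 0.92, 1.37),
                 lung = c(0.46, 37.75, 0.94, 1.37),
                 liver = c(0.829, 7.35, 0.9, 1.37),
                 kidney_r = c(0.155, 18.09, 0.86, 1.37))
      em <- list(surface = c(0.003, 19.82, 0.94, 1.37),
                 heart = c(0.04367, 6.16, 0.85, 1.37),
                 stomach = c(0.0086, 17.46, 0.92, 1.37),
                 lung = c(0.145, 35.67, 0.94, 1.37),
                 liver = c(0.261, 6.57, 0.9, 1.37),
                 kidney_r = c(0.05, 15.39, 0.86, 1.37))
      mk <- function(id, gen, parent) {
        e <- ex[[id]]; m <- em[[id]]
        list(id = id, parent = parent, generator = gen,
             mu_a = e[1], mu_s = e[2], g = e[3], n = e[4],
             emission = list(mu_a = m[1], mu_s = m[2], g = m[3], n = m[4]))
      }
      regs <- c(
        list(mk("surface", list(type = "ellipsoid", semi_axes = c(15, 7, 7),
                                refinement = 3), "ambient")),
        lapply(organs, function(o)
          mk(o$id, list(type = "ellipsoid", semi_axes = o$semi,
                        center = o$center, refinement = 2), "surface")))
      lst <- list(
        scene = list(ambient_n = 1.0, regions = regs),
        source = list(kind = "beam", position = c(-1.5, 3, 20),
                      direction = c(0, 0, -1), total_power = 1,
                      n_photons = 1e7, band = "excitation"),
        fluorophore = list(region = "kidney_r", eta = 0.6),
        controls = list(n_photons = 1e7, seed = 1, roulette_threshold = 1e-4,
                        roulette_m = 10, mode = "td", gates = c(0, 100, 10)),
        recorders = list(exit_log_cap = 0),
        output_dir = "fmt_td_out")
    }
  }
  validate_config(lst)
}
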