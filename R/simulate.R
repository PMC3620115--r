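#' Run controls for a Monte Carlo transport run
#'
#' @param n_photons number of photon packets.
#' @param seed non-negative integer seed; every random draw in the engine
#'   derives from it via one splitmix64 stream per photon index, so runs
#'   are bit-reproducible and independent of tracing order.
#' @param roulette_threshold roulette trigger as a fraction of the initial
#'   packet weight (default 1e-4); `0` disables roulette, giving exact
#'   energy accounting.
#' @param roulette_m roulette survival constant `m > 1` (default 10):
#'   survive with probability `1/m` at weight `m w`.
#' @param mode `"cw"` (continuous wave) or `"td"` (time domain).
#' @param gates for `mode = "td"`: `c(start, stop, dt)` in ps, uniform
#'   gates on `[start, stop)`; events after `stop` fall in an overflow
#'   gate. The packaged fluorescence example gates 0-100 ps at 10 ps.
#' @param max_steps per-photon step cap guarding pathological configs.
#' @export
run_controls <- function(n_photons = 1e5, seed = 1L,
                         roulette_threshold = 1e-4, roulette_m = 10,
                         mode = c("cw", "td"), gates = c(0, 100, 10),
                         max_steps = 1e6) {
  mode <- match.arg(mode)
  if (roulette_m <= 1) stop("roulette_m must be > 1")
  if (roulette_threshold < 0) stop("roulette_threshold must be >= 0")
  if (n_photons < 0) stop("n_photons must be >= 0")
  if (mode == "td") {
    if (length(gates) != 3 || gates[3] <= 0 || gates[2] <= gates[1])
      stop("gates must be c(start, stop, dt) with stop > start and dt > 0")
    ng <- (gates[2] - gates[1]) / gates[3]
    if (abs(ng - round(ng)) > 1e-9)
      stop("gate width dt must divide the interval [start, stop) evenly")
  }
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_m = roulette_m, mode = mode, gates = gates,
                 max_steps = max_steps),
            class = "run_controls")
}

#' Fluorophore specification for fluorescence runs
#'
#' Excitation packets interacting inside `region` convert to emission
#' packets with probability `eta` (the quantum efficiency); the excitation
#' packet then terminates and the emission packet continues from the same
#' position and elapsed time with an isotropic direction and the
#' emission-band optical properties.
#'
#' @param region region id hosting the fluorophore.
#' @param eta quantum efficiency in `[0, 1]`.
#' @export
fluorophore_spec <- function(region, eta) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  structure(list(region = as.character(region), eta = eta),
            class = "fluorophore_spec")
}

#' Recorder specification
#'
#' @param face_grid `NULL`, or `list(side =, rows =, cols =, center =)`
#'   to bin exits through an axis-aligned cubic outer surface into six
#'   per-face matrices.
#' @param absorption `NULL`, or `list(origin =, spacing =, dims =)` for a
#'   voxel grid of deposited weight.
#' @param exit_log_cap keep at most this many per-photon exit records
#'   (0 disables the log).
#' @export
recorder_spec <- function(face_grid = NULL, absorption = NULL,
                          exit_log_cap = 0L) {
  structure(list(face_grid = face_grid, absorption = absorption,
                 exit_log_cap = as.integer(exit_log_cap)),
            class = "recorder_spec")
}

# flatten scene + band tables for the C++ engine
engine_props <- function(sc, fluoro = NULL) {
  n <- length(sc$ids)
  tab <- function(get) {
    ex <- c(0, vapply(sc$regions, function(r) get(r$props), 0))
    ex
  }
  ex <- list(mu_a = tab(function(p) p$mu_a), mu_s = tab(function(p) p$mu_s),
             g = tab(function(p) p$g), n = c(sc$ambient_n,
               vapply(sc$regions, function(r) r$props$n, 0)))
  has_em <- any(vapply(sc$regions, function(r) !is.null(r$emission_props), TRUE))
  em <- NULL
  if (has_em) {
    getp <- function(r) if (is.null(r$emission_props)) r$props else r$emission_props
    em <- list(mu_a = c(0, vapply(sc$regions, function(r) getp(r)$mu_a, 0)),
               mu_s = c(0, vapply(sc$regions, function(r) getp(r)$mu_s, 0)),
               g = c(0, vapply(sc$regions, function(r) getp(r)$g, 0)),
               n = c(sc$ambient_n, vapply(sc$regions, function(r) getp(r)$n, 0)))
  }
  list(excitation = ex, emission = em,
       region_depth = as.integer(sc$depth))
}

engine_source <- function(src, sc) {
  out <- list(kind = src$kind, position = src$position,
              direction = src$direction)
  if (src$kind == "sphere") out$radius <- src$radius
  if (src$kind == "region") {
    ri <- match(src$region, sc$ids)
    if (is.na(ri)) stop("source region not found: ", src$region)
    vv <- sc$regions[[ri]]$mesh$vertices
    out$region <- ri
    out$bbox_lo <- apply(vv, 2, min)
    out$bbox_hi <- apply(vv, 2, max)
  }
  out
}

engine_recorders <- function(rec, controls) {
  fg <- rec$face_grid
  face <- if (is.null(fg)) list(enabled = FALSE) else
    list(enabled = TRUE, center = as.numeric(fg$center %||% c(0, 0, 0)),
         side = fg$side, rows = as.integer(fg$rows), cols = as.integer(fg$cols))
  ab <- rec$absorption
  absr <- if (is.null(ab)) list(enabled = FALSE) else
    list(enabled = TRUE, origin = as.numeric(ab$origin), spacing = ab$spacing,
         dims = as.integer(ab$dims))
  gates <- if (controls$mode == "td") {
    g <- controls$gates
    list(enabled = TRUE, start = g[1], dt = g[3],
         n = as.integer(round((g[2] - g[1]) / g[3])))
  } else list(enabled = FALSE)
  list(face_grid = face, absorption = absr, gates = gates,
       exit_log_cap = rec$exit_log_cap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a Monte Carlo photon transport simulation
#'
#' Traces `n_photons` weighted photon packets through the scene: sample an
#' exponential step, truncate at the nearest mesh boundary when closer
#' (carrying the residual dimensionless step across the interface and
#' rescaling it by the new medium's `mu_a + mu_s`), reflect or refract by
#' an all-or-nothing Fresnel draw, deposit `w mu_a / (mu_a + mu_s)` at
#' each interaction site, scatter by a Henyey-Greenstein deflection, and
#' apply Russian roulette below the weight threshold. Transmission through
#' the outermost boundary terminates the packet and records its residual
#' weight. With a fluorophore, excitation packets convert to emission
#' packets as described in [fluorophore_spec()].
#'
#' @param scene an [scene()].
#' @param source a [source_spec()].
#' @param controls a [run_controls()].
#' @param fluorophore optional [fluorophore_spec()].
#' @param recorders a [recorder_spec()].
#' @param init optional matrix of explicit initial photon states (columns
#'   x, y, z, dx, dy, dz, weight, time); overrides `source` placement and
#'   `n_photons`.
#' @return an `mc_result`: recorders (`tri_exit`, `face_grid`,
#'   `absorption`, time-gated variants, `exit_log`) plus a `totals`
#'   accounting of every launched unit of weight and the run metadata.
#' @examples
#' sc <- scene(region("phantom", make_cube_phantom(10),
#'                    optical_props(0.0002, 11.7, 0.95, 1.37)))
#' src <- source_spec("sphere", position = c(0, 0, 2), radius = 0.5,
#'                    n_photons = 200)
#' res <- run_simulation(sc, src, run_controls(n_photons = 200, seed = 1))
#' res$totals$exited[1] + res$totals$deposited[1]  # ~ launched weight
#' @export
run_simulation <- function(scene, source, controls = run_controls(),
                           fluorophore = NULL,
                           recorders = recorder_spec(), init = NULL) {
  stopifnot(inherits(scene, "mc_scene"))
  if (is.null(init)) stopifnot(inherits(source, "source_spec"))
  stopifnot(inherits(controls, "run_controls"))
  fl <- list(region = NULL)
  has_em <- any(vapply(scene$regions, function(r) !is.null(r$emission_props), TRUE))
  if (!is.null(fluorophore)) {
    stopifnot(inherits(fluorophore, "fluorophore_spec"))
    ri <- match(fluorophore$region, scene$ids)
    if (is.na(ri)) stop("fluorophore region not found: ", fluorophore$region)
    if (!has_em)
      stop("fluorescence runs need emission-band properties on the regions")
    fl <- list(region = ri, eta = fluorophore$eta)
  }
  esrc <- if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(ncol(init) == 8)
    list(kind = "init", states = init)
  } else engine_source(source, scene)
  n_ph <- if (!is.null(init)) nrow(init) else controls$n_photons
  ctl <- list(n_photons = as.double(n_ph),
              seed = as.double(controls$seed),
              total_power = if (!is.null(init)) sum(init[, 7]) else
                source$total_power,
              roulette_threshold = controls$roulette_threshold,
              roulette_m = controls$roulette_m,
              max_steps = as.double(controls$max_steps))
  raw <- cpp_run_transport(scene_ptr(scene), engine_props(scene), esrc, fl,
                           ctl, engine_recorders(recorders, controls))
  log <- raw$exit_log
  colnames(log) <- c("x", "y", "z", "dx", "dy", "dz", "weight", "time",
                     "triangle", "band")
  structure(
    list(tri_exit = raw$tri_exit,
         face_grid = if (length(raw$face_grid)) raw$face_grid,
         absorption = if (length(raw$absorption)) raw$absorption,
         exit_time = if (length(raw$exit_time)) raw$exit_time,
         absorbed_time = if (length(raw$absorbed_time)) raw$absorbed_time,
         tri_gate = if (length(raw$tri_gate)) raw$tri_gate,
         exit_log = log,
         totals = raw$totals,
         gate_edges = if (controls$mode == "td")
           seq(controls$gates[1], controls$gates[2], by = controls$gates[3]),
         scene = scene, controls = controls,
         source = if (is.null(init)) source,
         fluorophore = fluorophore,
         recorders = recorders),
    class = "mc_result")
}

#' Propagate explicit photon packets
#'
#' Traces photon packets from explicit initial states through the same
#' engine as [run_simulation()] (one RNG stream per row index derived from
#' the seed). Useful for ballistic and conservation checks.
#'
#' @param states matrix with columns x, y, z, dx, dy, dz, weight, time.
#' @inheritParams run_simulation
#' @return an `mc_result`.
#' @export
propagate <- function(states, scene, controls = run_controls(),
                      fluorophore = NULL, recorders = recorder_spec()) {
  run_simulation(scene, source = NULL, controls = controls,
                 fluorophore = fluorophore, recorders = recorders,
                 init = states)
}

#' @export
print.mc_result <- function(x, ...) {
  tt <- x$totals
  cat("mc_result:", format(x$controls$n_photons, big.mark = ","),
      "photons, seed", x$controls$seed, "\n")
  cat(sprintf("  launched weight  %.6g\n", tt$launched))
  cat(sprintf("  exited           %.6g (%.0f packets)\n",
              sum(tt$exited), sum(tt$n_exited)))
  cat(sprintf("  deposited        %.6g\n", sum(tt$deposited)))
  if (tt$specular > 0) cat(sprintf("  specular (entry) %.6g\n", tt$specular))
  if (tt$n_converted > 0)
    cat(sprintf("  fluorescence conversions: %.0f (weight %.6g)\n",
                tt$n_converted, tt$converted_weight))
  if (tt$n_roulette_killed > 0)
    cat(sprintf("  roulette net     %.3g (%.0f kills)\n",
                sum(tt$roulette_net), tt$n_roulette_killed))
  invisible(x)
}

#' @export
summary.mc_result <- function(object, ...) {
  tt <- object$totals
  bal <- tt$launched - sum(tt$deposited) - sum(tt$exited) -
    sum(tt$roulette_net) - sum(tt$cap_lost) - tt$specular - tt$missed
  out <- list(totals = tt,
              balance_residual = bal,
              relative_residual = bal / tt$launched,
              escape_fraction = sum(tt$exited) / tt$launched)
  class(out) <- "summary.mc_result"
  out
}

#' @export
print.summary.mc_result <- function(x, ...) {
  cat("Energy accounting:\n")
  t <- x$totals
  cat(sprintf("  launched   %.8g\n  deposited  %.8g\n  exited     %.8g\n",
              t$launched, sum(t$deposited), sum(t$exited)))
  cat(sprintf("  roulette   %.4g   specular %.4g   cap %.4g   missed %.4g\n",
              sum(t$roulette_net), t$specular, sum(t$cap_lost), t$missed))
  cat(sprintf("  residual   %.3e (relative %.3e)\n",
              x$balance_residual, x$relative_residual))
  cat(sprintf("  escape fraction %.4f\n", x$escape_fraction))
  invisible(x)
}

#' Plot a recorded transmittance face
#'
#' Images one face of the cube transmittance recorder (log10 scale by
#' default).
#'
#' @param x an `mc_result` with a face-grid recorder.
#' @param face face index 1..6 in the order x-, x+, y-, y+, z-, z+.
#' @param band `"excitation"` or `"emission"`.
#' @param log10 plot log10(weight + eps).
#' @param ... passed to [graphics::image()].
#' @export
plot.mc_result <- function(x, face = 6, band = "excitation", log10 = TRUE, ...) {
  if (is.null(x$face_grid)) stop("no face-grid recorder in this result")
  m <- x$face_grid[[band]][, , face]
  z <- if (log10) base::log10(m + max(m) * 1e-6 + 1e-300) else m
  graphics::image(z, useRaster = TRUE, asp = 1,
                  main = sprintf("face %d (%s)", face, band), ...)
  invisible(x)
}

#' Fourier-derive frequency-domain data from a time-gated record
#'
#' Discrete Fourier transform of a time-domain histogram at modulation
#' frequency `f`: `A e^{i phi} = sum_k h_k exp(-i 2 pi f t_k)` over the
#' gate centres. `f = 0` reproduces the continuous-wave total with zero
#' phase.
#'
#' @param counts gate-integrated weights (uniform gates).
#' @param gate_edges gate edges in ps, length `length(counts) + 1`.
#' @param f modulation frequency in cycles per ps (1 GHz = 1e-3 /ps).
#' @return list with `amplitude`, `phase` (radians), and the complex sum.
#' @export
td_to_fd <- function(counts, gate_edges, f) {
  if (length(gate_edges) != length(counts) + 1)
    stop("gate_edges must have length(counts) + 1 entries")
  if (length(counts) == 0 || all(counts == 0)) {
    warning("empty histogram: amplitude 0, phase undefined")
    return(list(amplitude = 0, phase = NA_real_, z = 0 + 0i))
  }
  dt <- diff(gate_edges)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("gates must be uniform")
  tc <- (gate_edges[-length(gate_edges)] + gate_edges[-1]) / 2
  z <- sum(counts * exp(-2i * pi * f * tc))
  list(amplitude = Mod(z), phase = Arg(z), z = z)
}
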