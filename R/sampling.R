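#' Sample a photon step length
#'
#' Free path between interaction sites: `s = -log(xi) / (mu_a + mu_s)`,
#' the inverse CDF of the exponential interaction law with total
#' interaction coefficient `mu_t = mu_a + mu_s`.
#'
#' @param props an [optical_props()] (or list with `mu_a`, `mu_s`).
#' @param xi uniform(0,1) deviate(s); strictly inside (0, 1).
#' @return step length(s) in mm.
#' @examples
#' sample_step(optical_props(0, 1, 0, 1), exp(-1))  # 1 mm
#' @export
sample_step <- function(props, xi) {
  mut <- props$mu_a + props$mu_s
  if (mut <= 0) stop("mu_a + mu_s must be positive")
  if (any(xi <= 0 | xi >= 1)) stop("xi must lie strictly in (0, 1)")
  -log(xi) / mut
}

#' Sample the cosine of the Henyey-Greenstein deflection angle
#'
#' Inverse-CDF draw from the Henyey-Greenstein phase function with
#' anisotropy `g` (the mean cosine): for `g != 0`,
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 + g - 2 g xi))^2) / (2 g)`,
#' and `cos(theta) = 2 xi - 1` for the isotropic case `g = 0`. Results are
#' clamped to `[-1, 1]`.
#'
#' @param g anisotropy factor, `|g| < 1`.
#' @param xi uniform(0,1) deviate(s).
#' @return cosine(s) of the deflection angle.
#' @export
sample_hg_cos <- function(g, xi) {
  if (abs(g) >= 1) stop("g must satisfy |g| < 1")
  if (g == 0) return(2 * xi - 1)
  tt <- (1 - g^2) / (1 + g - 2 * g * xi)
  pmin(1, pmax(-1, (1 + g^2 - tt^2) / (2 * g)))
}

#' Rotate a direction by a scattering deflection
#'
#' Updates a unit direction by deflection angle `theta` (given as its
#' cosine) and azimuth `phi` about the incoming direction, using the
#' standard local-frame rotation; the near-vertical case `|uz| ~ 1` uses
#' the degenerate-frame formula. With `direction = (0,0,1)`, `cos_theta =
#' 0`, `phi = 0` the result is `(1,0,0)` (frame convention).
#'
#' @param direction length-3 unit vector.
#' @param cos_theta cosine of the deflection angle, in `[-1, 1]`.
#' @param phi azimuth in radians, `[0, 2*pi)`.
#' @return the rotated unit vector.
#' @export
scatter_direction <- function(direction, cos_theta, phi) {
  u <- as.numeric(direction)
  u <- u / sqrt(sum(u^2))
  ct <- min(1, max(-1, cos_theta))
  st <- sqrt(1 - ct^2)
  if (abs(u[3]) > 0.99999) {
    out <- c(st * cos(phi), st * sin(phi), ct * sign(u[3]))
  } else {
    den <- sqrt(1 - u[3]^2)
    out <- c(st * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / den + u[1] * ct,
             st * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / den + u[2] * ct,
             -st * cos(phi) * den + u[3] * ct)
  }
  out / sqrt(sum(out^2))
}

#' Critical angle for total internal reflection
#'
#' `theta_c = asin(n_t / n_i)` when the photon heads from the optically
#' denser medium (`n_i > n_t`); beyond it the Fresnel reflectance is 1.
#' `NULL` when `n_i < n_t` (no total internal reflection); `pi/2` for
#' matched indices.
#'
#' @param n_i refractive index of the incidence medium.
#' @param n_t refractive index of the transmission medium.
#' @return the critical angle in radians, or `NULL`.
#' @export
critical_angle <- function(n_i, n_t) {
  if (n_i < n_t) return(NULL)
  asin(n_t / n_i)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized reflectances,
#' `R = (sin^2(ai - at) / sin^2(ai + at) + tan^2(ai - at) / tan^2(ai + at)) / 2`
#' with the transmission angle from Snell's law; `R = 1` beyond the
#' critical angle, `R = ((n_i - n_t)/(n_i + n_t))^2` at normal incidence,
#' and `R = 0` for matched media.
#'
#' @param n_i,n_t refractive indices of the incidence/transmission media.
#' @param theta_i incidence angle(s) in radians, `[0, pi/2]`.
#' @return reflectance(s) in `[0, 1]`.
#' @export
fresnel_reflectance <- function(n_i, n_t, theta_i) {
  if (any(theta_i < 0 | theta_i > pi / 2)) stop("theta_i must lie in [0, pi/2]")
  if (n_i == n_t) return(rep(0, length(theta_i)))
  ci <- cos(theta_i)
  si <- sin(theta_i)
  st <- n_i / n_t * si
  R <- rep(1, length(theta_i))          # total internal reflection default
  ok <- st < 1
  ct <- sqrt(pmax(0, 1 - st[ok]^2))
  rs <- (n_i * ci[ok] - n_t * ct) / (n_i * ci[ok] + n_t * ct)
  rp <- (n_t * ci[ok] - n_i * ct) / (n_t * ci[ok] + n_i * ct)
  R[ok] <- (rs^2 + rp^2) / 2
  R
}

#' Russian roulette survival draw
#'
#' Unbiased low-weight termination: with probability `1/m` the packet
#' survives with weight `m * w`, otherwise it terminates with weight 0, so
#' the expected weight is conserved.
#'
#' @param weight current packet weight.
#' @param m roulette constant, > 1 (user-settable).
#' @param xi uniform(0,1) deviate(s).
#' @return the post-roulette weight(s).
#' @export
roulette <- function(weight, m, xi) {
  if (m <= 1) stop("roulette constant m must be > 1")
  ifelse(xi <= 1 / m, m * weight, 0)
}

#' Fluorescence conversion draw
#'
#' When an excitation packet interacts inside the fluorophore region, it
#' converts to an emission packet with probability equal to the quantum
#' efficiency `eta`: returns `TRUE` iff `xi < eta`. On conversion the
#' excitation packet terminates and an emission packet is launched at the
#' same position and elapsed time with an isotropic direction, carrying
#' the residual weight, under the emission-band optical properties.
#'
#' @param eta quantum efficiency in `[0, 1]`.
#' @param xi uniform(0,1) deviate(s).
#' @return logical vector.
#' @export
fluorescence_convert <- function(eta, xi) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  xi < eta
}

#' Advance the photon clock over a flight segment
#'
#' Optical path time: `t += step * n / c` with `c = 0.299792458` mm/ps.
#'
#' @param photon a list with a `time` element (ps).
#' @param step flight distance in mm (>= 0).
#' @param n refractive index of the traversed medium.
#' @return the photon with updated `time`.
#' @export
advance_time <- function(photon, step, n) {
  if (any(step < 0)) stop("step must be >= 0")
  photon$time <- photon$time + step * n / 0.299792458
  photon
}

#' Reflect-or-transmit boundary interaction
#'
#' All-or-nothing draw against the Fresnel reflectance at the incidence
#' angle: if `xi <= R(theta_i)` the packet is specularly reflected and
#' stays in its region; otherwise it is refracted by Snell's law into the
#' neighbouring region. A transmission through the outermost boundary
#' terminates the packet (status `"exited"`) so its residual weight can be
#' recorded.
#'
#' @param photon list with `position`, `direction`, `weight`, `time`,
#'   `region`.
#' @param hit a hit record from [first_intersection()].
#' @param scene an `mc_scene`.
#' @param xi a single uniform(0,1) deviate.
#' @return the updated photon, with a `status` field of `"reflected"`,
#'   `"transmitted"` or `"exited"`.
#' @export
boundary_event <- function(photon, hit, scene, xi) {
  d <- photon$direction / sqrt(sum(photon$direction^2))
  nrm <- hit$surface_normal
  nf <- if (sum(d * nrm) < 0) nrm else -nrm
  ci <- min(1, max(0, -sum(d * nf)))
  idx_of <- function(id) if (id == "ambient") scene$ambient_n else
    scene$regions[[match(id, scene$ids)]]$props$n
  ni <- idx_of(hit$region_from)
  nt <- idx_of(hit$region_to)
  R <- fresnel_reflectance(ni, nt, acos(ci))
  if (xi <= R) {
    photon$direction <- d - 2 * sum(d * nf) * nf
    photon$status <- "reflected"
  } else {
    if (ni != nt) {
      si <- sqrt(max(0, 1 - ci^2))
      stt <- ni / nt * si
      ct <- sqrt(max(0, 1 - stt^2))
      d <- d * (ni / nt) + nf * (ni / nt * ci - ct)
      d <- d / sqrt(sum(d^2))
    }
    photon$direction <- d
    photon$region <- hit$region_to
    photon$status <- if (hit$region_to == "ambient") "exited" else "transmitted"
  }
  photon$position <- hit$hit_point
  photon
}

#' Continuous absorption deposition at an interaction site
#'
#' MCML-style weighting: the fraction `mu_a / (mu_a + mu_s)` of the packet
#' weight is deposited into the voxel containing the interaction site and
#' the packet keeps the rest. Positions outside the grid are accumulated
#' in an `overflow` bucket so total weight stays accounted.
#'
#' @param photon list with `position` and `weight`.
#' @param props [optical_props()] of the current region.
#' @param grid an [absorption_grid()].
#' @return list with the updated `photon` and `grid`.
#' @export
deposit <- function(photon, props, grid) {
  mut <- props$mu_a + props$mu_s
  dw <- if (props$mu_a > 0) photon$weight * props$mu_a / mut else 0
  if (dw > 0) {
    i <- floor((photon$position - grid$origin) / grid$spacing)
    if (all(i >= 0) && all(i < grid$dims)) {
      grid$weights[i[1] + 1, i[2] + 1, i[3] + 1] <-
        grid$weights[i[1] + 1, i[2] + 1, i[3] + 1] + dw
    } else {
      grid$overflow <- grid$overflow + dw
    }
    photon$weight <- photon$weight - dw
  }
  list(photon = photon, grid = grid)
}

#' Axis-aligned absorption voxel grid
#'
#' @param origin minimal corner (mm).
#' @param spacing voxel edge (mm); the packaged diffuse-optical example
#'   uses 0.5 mm.
#' @param dims integer c(nx, ny, nz).
#' @export
absorption_grid <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, spacing > 0, length(dims) == 3, all(dims >= 1))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims),
                 weights = array(0, as.integer(dims)), overflow = 0),
            class = "absorption_grid")
}

#' Launch a photon packet from a source
#'
#' Initial weight is `total_power / n_photons`. Internal sources place the
#' packet uniformly over the source volume (rejection sampling) with an
#' isotropic direction (cosine of the polar angle uniform on `[-1, 1]`,
#' azimuth uniform on `[0, 2*pi)`); external beams start at the entry
#' point along the beam direction. Uses R's RNG stream.
#'
#' @param source a [source_spec()].
#' @param scene an `mc_scene` (needed to place region sources).
#' @return a photon list: `position`, `direction`, `weight`, `time`,
#'   `region`, `band`.
#' @export
launch_photon <- function(source, scene = NULL) {
  w <- source$total_power / source$n_photons
  if (source$kind == "beam") {
    d <- source$direction / sqrt(sum(source$direction^2))
    return(list(position = as.numeric(source$position), direction = d,
                weight = w, time = 0, region = "ambient", band = source$band))
  }
  iso <- function() {
    ct <- stats::runif(1, -1, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    c(st * cos(phi), st * sin(phi), ct)
  }
  pos <- switch(source$kind,
    point = as.numeric(source$position),
    sphere = {
      repeat {
        p <- source$position + stats::runif(3, -1, 1) * source$radius
        if (sum((p - source$position)^2) <= source$radius^2) break
      }
      p
    },
    region = {
      if (is.null(scene)) stop("a scene is required to place a region source")
      ri <- match(source$region, scene$ids)
      if (is.na(ri)) stop("source region not found: ", source$region)
      vv <- scene$regions[[ri]]$mesh$vertices
      lo <- apply(vv, 2, min); hi <- apply(vv, 2, max)
      tries <- 0
      repeat {
        p <- lo + stats::runif(3) * (hi - lo)
        if (locate_region(p, scene) == source$region) break
        tries <- tries + 1
        if (tries > 1e5) stop("source region appears to be empty")
      }
      p
    },
    stop("unknown source kind: ", source$kind))
  reg <- if (!is.null(scene)) locate_region(pos, scene) else NA_character_
  list(position = pos, direction = iso(), weight = w, time = 0,
       region = reg, band = source$band)
}

#' Light source specification
#'
#' @param kind `"point"`, `"sphere"` or `"region"` for internal sources
#'   (bioluminescent inclusions), `"beam"` for an external collimated
#'   beam entering through the surface.
#' @param position source centre / beam entry point (mm).
#' @param radius sphere radius (mm), for `kind = "sphere"`.
#' @param region region id hosting a `"region"` source.
#' @param direction beam direction, for `kind = "beam"`.
#' @param total_power total source power (arbitrary units); each packet
#'   starts with `total_power / n_photons`.
#' @param n_photons number of photon packets.
#' @param band `"single"` for one-band runs, `"excitation"` for
#'   fluorescence runs.
#' @export
source_spec <- function(kind, position = NULL, radius = NULL, region = NULL,
                        direction = NULL, total_power = 1, n_photons = 1e5,
                        band = "single") {
  kind <- match.arg(kind, c("point", "sphere", "region", "beam"))
  if (kind %in% c("point", "sphere", "beam") && is.null(position))
    stop("position is required for kind '", kind, "'")
  if (kind == "sphere" && (is.null(radius) || radius <= 0))
    stop("a positive radius is required for a sphere source")
  if (kind == "region" && is.null(region))
    stop("a region id is required for a region source")
  if (kind == "beam" && is.null(direction))
    stop("a direction is required for a beam source")
  if (total_power <= 0) stop("total_power must be positive")
  if (n_photons < 0) stop("n_photons must be >= 0")
  structure(list(kind = kind, position = as.numeric(position),
                 radius = radius, region = region,
                 direction = if (!is.null(direction)) as.numeric(direction),
                 total_power = total_power, n_photons = n_photons,
                 band = band),
            class = "source_spec")
}
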