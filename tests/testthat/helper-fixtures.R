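# Shared fixtures and independent oracles, built in code at test time.

cube_phantom_props <- function() optical_props(0.0002, 11.7, 0.95, 1.37)

cube_scene <- function(side = 10, subdivisions = 1L, props = cube_phantom_props(),
                       ambient_n = 1.0) {
  scene(region("phantom", make_cube_phantom(side, subdivisions), props),
        ambient_n = ambient_n)
}

nested_scene <- function() {
  scene(list(
    region("phantom", make_cube_phantom(10), cube_phantom_props()),
    region("tumor", make_sphere_mesh(1, refinement = 2),
           optical_props(0.55, 29.5, 0.9, 1.37), parent = "phantom")))
}

# Independent brute-force ray/mesh oracle: vectorized Moller-Trumbore over
# every triangle, same inclusive-edge tolerances as the contract specifies.
brute_first_hit <- function(sc, origin, dir, tmin = 1e-7, tmax = Inf) {
  V <- sc$V; F1 <- sc$F + 1L
  a <- V[F1[, 1], , drop = FALSE]
  e1 <- V[F1[, 2], , drop = FALSE] - a
  e2 <- V[F1[, 3], , drop = FALSE] - a
  d <- dir
  p <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * p)
  s <- sweep(-a, 2, origin, "+")
  u <- rowSums(s * p) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- as.numeric(q %*% d) / det
  tt <- rowSums(e2 * q) / det
  ok <- abs(det) >= 1e-14 & u >= -1e-12 & u <= 1 + 1e-12 &
    v >= -1e-12 & (u + v) <= 1 + 1e-12 & tt > tmin & tt <= tmax
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[order(tt[cand], cand)][1]
  list(distance = tt[best], triangle = best)
}

# number of surface crossings along an infinite ray (brute force)
brute_crossings <- function(sc, origin, dir) {
  n <- 0L
  o <- origin
  repeat {
    h <- brute_first_hit(sc, o, dir, tmin = 1e-9)
    if (is.null(h)) return(n)
    n <- n + 1L
    o <- o + (h$distance + 1e-7) * dir
  }
}

random_unit_vectors <- function(n) {
  ct <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  cbind(st * cos(phi), st * sin(phi), ct)
}

# Henyey-Greenstein CDF on [-1, 1]; the inverse (by root finding) is an
# independent oracle for the closed-form sampler.
hg_cdf <- function(c3, g) {
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * c3) - 1 / (1 + g))
}
hg_quantile <- function(p, g) {
  stats::uniroot(function(c3) hg_cdf(c3, g) - p, c(-1, 1), tol = 1e-12)$root
}
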