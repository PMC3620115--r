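test_that("step sampling follows the exponential inverse CDF", {
  expect_equal(sample_step(optical_props(0, 1, 0, 1), exp(-1)), 1.0)
  # homogeneous phantom properties: -ln(0.5) / 11.7002
  expect_equal(sample_step(cube_phantom_props(), 0.5), log(2) / 11.7002,
               tolerance = 1e-12)
  expect_lt(sample_step(cube_phantom_props(), 1 - 1e-12), 1e-9)
  expect_error(sample_step(cube_phantom_props(), 0), "xi")
  expect_error(sample_step(cube_phantom_props(), 1), "xi")
  expect_error(sample_step(optical_props(0, 1, 0, 1) |>
                             (\(p) {p$mu_s <- 0; p})(), 0.5), "positive")
})

test_that("Henyey-Greenstein cosine sampling matches the CDF inverse and its moment", {
  expect_equal(sample_hg_cos(0, 0.5), 0)
  expect_equal(sample_hg_cos(0, c(0, 1)), c(-1, 1))
  # root-finding oracle: the sampler's xi maps to the (1 - xi) quantile
  for (g in c(0.3, 0.95, -0.5)) {
    for (xi in c(0.1, 0.5, 0.9)) {
      expect_equal(sample_hg_cos(g, xi), hg_quantile(1 - xi, g),
                   tolerance = 1e-8)
    }
  }
  expect_equal(sample_hg_cos(0.95, 0.5), 0.99631, tolerance = 1e-5)
  expect_error(sample_hg_cos(1, 0.5), "g")

  # sample mean equals g within 3 standard errors, for the anisotropy
  # values typical of tissue
  set.seed(5)
  for (g in c(-0.5, 0, 0.5, 0.9, 0.95)) {
    x <- sample_hg_cos(g, stats::runif(1e6))
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se + 1e-12)
  }
  # isotropic case: cosines uniform on [-1, 1]
  set.seed(6)
  ks <- stats::ks.test(sample_hg_cos(0, stats::runif(2e4)), "punif", -1, 1)
  expect_gt(ks$p.value, 1e-4)
})

test_that("scatter_direction rotates by the requested deflection", {
  d0 <- c(0, 0, 1)
  expect_equal(scatter_direction(d0, 1, 1.3), d0)
  expect_equal(scatter_direction(d0, -1, 0.4), -d0, tolerance = 1e-12)
  expect_equal(scatter_direction(d0, 0, 0), c(1, 0, 0))
  set.seed(7)
  for (k in 1:200) {
    u <- random_unit_vectors(1)[1, ]
    ct <- stats::runif(1, -1, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    v <- scatter_direction(u, ct, phi)
    expect_equal(sum(v^2), 1, tolerance = 1e-9)
    expect_equal(sum(u * v), ct, tolerance = 1e-9)
  }
})

test_that("critical angle and Fresnel reflectance take their closed forms", {
  expect_equal(critical_angle(1.37, 1.0), asin(1 / 1.37))
  expect_equal(critical_angle(1.37, 1.0) * 180 / pi, 46.89, tolerance = 1e-3)
  expect_equal(critical_angle(1.5, 1.5), pi / 2)
  expect_null(critical_angle(1.0, 1.37))

  expect_equal(fresnel_reflectance(1.5, 1.5, c(0, 0.3, 1.2)), c(0, 0, 0))
  expect_equal(fresnel_reflectance(1.37, 1.0, 0), (0.37 / 2.37)^2,
               tolerance = 1e-12)
  expect_equal(fresnel_reflectance(1.37, 1.0, 60 * pi / 180), 1.0)
  expect_error(fresnel_reflectance(1.4, 1.0, -0.1), "theta_i")

  # independent oracle: angle-difference form
  # R = (sin^2(ai-at)/sin^2(ai+at) + tan^2(ai-at)/tan^2(ai+at)) / 2
  angdiff_R <- function(ni, nt, ai) {
    at <- asin(pmin(1, ni / nt * sin(ai)))
    ifelse(ni / nt * sin(ai) >= 1, 1,
           ifelse(ai == 0, ((ni - nt) / (ni + nt))^2,
                  0.5 * (sin(ai - at)^2 / sin(ai + at)^2 +
                           tan(ai - at)^2 / tan(ai + at)^2)))
  }
  th <- seq(0.001, pi / 2 - 1e-6, length.out = 200)
  for (pair in list(c(1.37, 1.0), c(1.0, 1.37), c(1.5, 1.33))) {
    expect_equal(fresnel_reflectance(pair[1], pair[2], th),
                 angdiff_R(pair[1], pair[2], th), tolerance = 1e-12)
  }
})

test_that("roulette is the m-for-1 survival rule and is unbiased", {
  expect_equal(roulette(0.3, 10, 0.05), 3.0)
  expect_equal(roulette(0.3, 10, 0.5), 0)
  expect_error(roulette(1, 1, 0.5), "m")
  set.seed(8)
  xi <- stats::runif(2e5)
  out <- roulette(1, 10, xi)
  se <- stats::sd(out) / sqrt(length(out))
  expect_lt(abs(mean(out) - 1), 3 * se)
})

test_that("fluorescence conversion is a Bernoulli draw at the quantum efficiency", {
  expect_true(all(fluorescence_convert(1, stats::runif(100))))
  expect_false(any(fluorescence_convert(0, stats::runif(100))))
  set.seed(9)
  xi <- stats::runif(1e6)
  frac <- mean(fluorescence_convert(0.6, xi))
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 1e6))
  expect_error(fluorescence_convert(1.2, 0.5), "eta")
})

test_that("the photon clock advances by optical path length", {
  ph <- list(time = 0)
  expect_equal(advance_time(ph, 0, 1.37)$time, 0)
  t1 <- advance_time(ph, 10, 1.37)$time
  expect_equal(t1, 10 * 1.37 / 0.299792458)
  expect_equal(t1, 45.70, tolerance = 1e-3)
  # additivity
  t2 <- advance_time(advance_time(ph, 1, 1.5), 1, 1.5)$time
  expect_equal(t2, advance_time(ph, 2, 1.5)$time)
})

test_that("boundary_event reflects or refracts per the Fresnel draw", {
  sc <- cube_scene()
  h <- first_intersection(c(0, 0, 0), c(1, 0, 0), sc)
  ph <- list(position = c(0, 0, 0), direction = c(1, 0, 0), weight = 1,
             time = 0, region = "phantom")
  # normal incidence on n=1.37 -> 1.0: R = 0.0244; xi above it transmits
  out <- boundary_event(ph, h, sc, 0.9)
  expect_equal(out$status, "exited")
  expect_equal(out$direction, c(1, 0, 0))
  out2 <- boundary_event(ph, h, sc, 0.01)
  expect_equal(out2$status, "reflected")
  expect_equal(out2$direction, c(-1, 0, 0))

  # oblique transmission follows Snell: sin(at) = 1.37 sin(30 deg)
  d <- c(cos(pi / 6), 0, sin(pi / 6))  # 30 deg from the +x face normal
  hb <- first_intersection(c(0, 0, 0), d, sc)
  ph$direction <- d
  out3 <- boundary_event(ph, hb, sc, 0.99)
  expect_equal(out3$status, "exited")
  st <- sqrt(1 - sum(out3$direction * c(1, 0, 0))^2)
  expect_equal(st, 1.37 * sin(pi / 6), tolerance = 1e-9)
  expect_equal(asin(st) * 180 / pi, 43.23, tolerance = 0.005)

  # beyond the critical angle (46.9 deg) every draw reflects
  d2 <- c(cos(70 * pi / 180), 0, sin(70 * pi / 180))
  ph$position <- c(4.9, 0, 0)            # close to the +x face
  hc <- first_intersection(ph$position, d2, sc)
  ph$direction <- d2
  out4 <- boundary_event(ph, hc, sc, 1 - 1e-12)
  expect_equal(out4$status, "reflected")

  # matched media: no refraction, always transmit for xi > 0
  scm <- cube_scene(ambient_n = 1.37)
  hm <- first_intersection(c(0, 0, 0), c(1, 0, 0), scm)
  ph$direction <- c(1, 0, 0)
  outm <- boundary_event(ph, hm, scm, 1e-9)
  expect_equal(outm$status, "exited")
  expect_equal(outm$direction, c(1, 0, 0))
})

test_that("deposit takes the albedo-complement fraction and conserves weight", {
  g <- absorption_grid(c(-5, -5, -5), 0.5, c(20, 20, 20))
  ph <- list(position = c(0.1, 0.1, 0.1), weight = 1)
  out <- deposit(ph, optical_props(1, 1, 0, 1.37), g)
  expect_equal(out$photon$weight, 0.5)
  expect_equal(sum(out$grid$weights), 0.5)

  out0 <- deposit(ph, optical_props(0, 5, 0, 1.37), g)
  expect_equal(out0$photon$weight, 1)
  expect_equal(sum(out0$grid$weights), 0)

  ph2 <- list(position = c(0.1, 0.1, 0.1), weight = 1e-7)
  outp <- deposit(ph2, cube_phantom_props(), g)
  expect_equal(outp$photon$weight, 1e-7 * (1 - 0.0002 / 11.7002))
  expect_equal(1e-7 * 0.0002 / 11.7002, 1.709e-12, tolerance = 1e-4)

  # outside the grid: overflow bucket keeps the balance
  ph3 <- list(position = c(50, 0, 0), weight = 1)
  outo <- deposit(ph3, optical_props(1, 0, 0, 1.37), g)
  expect_equal(outo$grid$overflow, 1)
  expect_equal(outo$photon$weight, 0)
})

test_that("launch_photon places packets in the source volume with isotropic directions", {
  src <- source_spec("point", position = c(0, 0, 0), total_power = 1,
                     n_photons = 1e7)
  ph <- launch_photon(src)
  expect_equal(ph$weight, 1e-7)
  expect_equal(ph$time, 0)

  set.seed(10)
  D <- t(replicate(2e4, launch_photon(src)$direction))
  expect_true(all(abs(rowSums(D^2) - 1) < 1e-9))
  se <- 3 / sqrt(3 * 2e4)  # 3 SE per component (var = 1/3)
  expect_true(all(abs(colMeans(D)) < 3 * sqrt(1 / 3 / 2e4)))

  sc <- cube_scene(side = 1)
  srcr <- source_spec("region", region = "phantom", total_power = 1,
                      n_photons = 100)
  set.seed(11)
  P <- t(replicate(3000, launch_photon(srcr, sc)$position))
  expect_true(all(abs(P) <= 0.5))
  expect_true(all(abs(colMeans(P)) < 3 * sqrt(1 / 12 / 3000)))
  expect_error(launch_photon(source_spec("region", region = "nope",
                                         n_photons = 1), sc), "not found")
})
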