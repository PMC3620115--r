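ballistic_states <- function(n, w = 1) {
  cbind(-5 + 1e-6, 0, 0, 1, 0, 0, w, 0)[rep(1, n), , drop = FALSE]
}

test_that("non-interacting packets cross the phantom ballistically", {
  # matched indices, negligible interaction: full weight out the far face
  sc <- cube_scene(props = optical_props(1e-12, 1e-12, 0, 1.37),
                   ambient_n = 1.37)
  r <- propagate(ballistic_states(50), sc,
                 run_controls(seed = 2, roulette_threshold = 0, mode = "td",
                              gates = c(0, 100, 10)))
  expect_equal(sum(r$totals$exited), 50, tolerance = 1e-9)
  # all arrivals in the [40, 50) ps gate: 10 mm at n = 1.37 is 45.7 ps
  expect_equal(r$exit_time$excitation[[5]], sum(r$totals$exited),
               tolerance = 1e-9)
  expect_equal(sum(r$exit_time$excitation[-5]), 0)
})

test_that("a non-scattering absorbing slab obeys Beer-Lambert", {
  sc <- cube_scene(props = optical_props(0.1, 0, 0, 1), ambient_n = 1)
  n <- 1e5
  r <- propagate(ballistic_states(n), sc,
                 run_controls(seed = 7, roulette_threshold = 0))
  frac <- sum(r$totals$exited) / r$totals$launched
  p <- exp(-1)  # mu_a * d = 1
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  # absorbed packets deposit everything: exact balance
  expect_lt(abs(summary(r)$relative_residual), 1e-9)
})

test_that("energy is conserved exactly with roulette disabled and in expectation with it", {
  sc <- cube_scene()
  src <- source_spec("point", position = c(0, 0, 2), n_photons = 5000)
  r <- run_simulation(sc, src, run_controls(n_photons = 5000, seed = 5,
                                            roulette_threshold = 0))
  expect_lt(abs(summary(r)$relative_residual), 1e-9)

  # with roulette: E[deposited + exited] = launched (z-test across seeds)
  sc_abs <- cube_scene(props = optical_props(0.5, 5, 0.8, 1.37))
  outs <- vapply(1:30, function(s) {
    rr <- run_simulation(sc_abs, source_spec("point", position = c(0, 0, 0),
                                             n_photons = 400),
                         run_controls(n_photons = 400, seed = s,
                                      roulette_threshold = 1e-2))
    (sum(rr$totals$deposited) + sum(rr$totals$exited)) / rr$totals$launched
  }, 0)
  z <- abs(mean(outs) - 1) / (stats::sd(outs) / sqrt(length(outs)))
  expect_lt(z, 3)
})

test_that("an isotropic point source in a non-scattering absorber decays as exp(-mu_a r)", {
  mu_a <- 0.3
  frac_at <- function(radius, seed) {
    sc <- scene(region("ball", make_sphere_mesh(radius, refinement = 3),
                       optical_props(mu_a, 0, 0, 1)), ambient_n = 1)
    r <- run_simulation(sc, source_spec("point", position = c(0, 0, 0),
                                        n_photons = 2e4),
                        run_controls(n_photons = 2e4, seed = seed,
                                     roulette_threshold = 0))
    sum(r$totals$exited) / r$totals$launched
  }
  f1 <- frac_at(2, 21); f2 <- frac_at(4, 22)
  ratio <- f2 / f1
  expected <- exp(-mu_a * 2)
  se <- expected * sqrt((1 - f1) / (f1 * 2e4) + (1 - f2) / (f2 * 2e4))
  expect_lt(abs(ratio - expected), 3 * se + 0.01 * expected)
})

test_that("identical seed and configuration reproduce results bit-for-bit", {
  sc <- cube_scene()
  src <- source_spec("sphere", position = c(0, 0, 2), radius = 0.5,
                     n_photons = 3000)
  rec <- recorder_spec(face_grid = list(side = 10, rows = 30, cols = 30,
                                        center = c(0, 0, 0)),
                       absorption = list(origin = c(-5, -5, -5), spacing = 0.5,
                                         dims = c(20, 20, 20)),
                       exit_log_cap = 5000)
  ctl <- run_controls(n_photons = 3000, seed = 42)
  r1 <- run_simulation(sc, src, ctl, recorders = rec)
  r2 <- run_simulation(sc, src, ctl, recorders = rec)
  expect_identical(r1$face_grid, r2$face_grid)
  expect_identical(r1$absorption, r2$absorption)
  expect_identical(r1$tri_exit, r2$tri_exit)
  expect_identical(r1$exit_log, r2$exit_log)
  expect_identical(r1$totals, r2$totals)
  r3 <- run_simulation(sc, src, run_controls(n_photons = 3000, seed = 43),
                       recorders = rec)
  expect_false(identical(r1$tri_exit, r3$tri_exit))
})

test_that("zero photons give empty recorders and zero totals", {
  sc <- cube_scene()
  r <- run_simulation(sc, source_spec("point", position = c(0, 0, 0),
                                      n_photons = 0),
                      run_controls(n_photons = 0, seed = 1))
  expect_equal(r$totals$launched, 0)
  expect_equal(sum(r$totals$exited), 0)
  expect_equal(sum(r$tri_exit$excitation), 0)
})

test_that("recorder sums match the terminal-status totals", {
  sc <- nested_scene()
  rec <- recorder_spec(face_grid = list(side = 10, rows = 25, cols = 25,
                                        center = c(0, 0, 0)),
                       absorption = list(origin = c(-5, -5, -5), spacing = 0.5,
                                         dims = c(20, 20, 20)),
                       exit_log_cap = 20000)
  r <- run_simulation(sc, source_spec("point", position = c(3, 0, 0),
                                      n_photons = 1e4),
                      run_controls(n_photons = 1e4, seed = 9,
                                   roulette_threshold = 0), recorders = rec)
  tot <- r$totals
  expect_equal(sum(r$tri_exit$excitation), sum(tot$exited), tolerance = 1e-9)
  expect_equal(sum(r$face_grid$excitation), sum(tot$exited), tolerance = 1e-9)
  expect_equal(sum(r$absorption$excitation) + tot$absorption_overflow[1],
               sum(tot$deposited), tolerance = 1e-9)
  expect_equal(sum(r$exit_log[, "weight"]), sum(tot$exited), tolerance = 1e-9)
  expect_true(all(r$exit_log[, "time"] > 0))
})

test_that("fluorescence conversion transfers weight to the emission band", {
  props_ex <- optical_props(0.02, 10, 0.9, 1.37)
  props_em <- optical_props(0.01, 8, 0.9, 1.37)
  sc <- scene(list(
    region("body", make_cube_phantom(10), props_ex, emission_props = props_em),
    region("probe", make_sphere_mesh(1.5, refinement = 2),
           optical_props(0.05, 12, 0.9, 1.37),
           parent = "body", emission_props = optical_props(0.02, 9, 0.9, 1.37))))
  r <- run_simulation(sc, source_spec("point", position = c(3, 0, 0),
                                      n_photons = 2000, band = "excitation"),
                      run_controls(n_photons = 2000, seed = 3, mode = "td",
                                   gates = c(0, 200, 10),
                                   roulette_threshold = 0),
                      fluorophore = fluorophore_spec("probe", 0.6))
  tot <- r$totals
  expect_gt(tot$n_converted, 0)
  # band ledgers close: excitation weight ends as deposit, exit or conversion
  expect_equal(tot$launched,
               tot$deposited[1] + tot$exited[1] + tot$converted_weight,
               tolerance = 1e-9)
  expect_equal(tot$converted_weight, tot$deposited[2] + tot$exited[2],
               tolerance = 1e-9)
  # emission arrivals are never earlier than the first excitation arrivals
  ex_t <- r$exit_time$excitation
  em_t <- r$exit_time$emission
  expect_gt(sum(em_t), 0)
  first_gate <- function(h) which(h > 0)[1]
  expect_gte(first_gate(em_t), first_gate(ex_t))
  # emission-band exits are recorded separately from excitation
  expect_equal(sum(r$tri_exit$emission), tot$exited[2], tolerance = 1e-9)
})

test_that("an external beam pays the specular entry loss", {
  sc <- cube_scene(props = optical_props(0.01, 1, 0.5, 1.37))
  src <- source_spec("beam", position = c(0, 0, 20), direction = c(0, 0, -1),
                     n_photons = 500)
  r <- run_simulation(sc, src, run_controls(n_photons = 500, seed = 4,
                                            roulette_threshold = 0))
  R0 <- ((1.37 - 1) / (1.37 + 1))^2
  expect_equal(r$totals$specular, r$totals$launched * R0, tolerance = 1e-9)
  expect_lt(abs(summary(r)$relative_residual), 1e-9)
})

test_that("time-domain frequency conversion reduces to the expected limits", {
  edges <- seq(0, 100, by = 10)
  h <- c(0, 5, 9, 4, 2, 1, 0.5, 0.2, 0.1, 0)
  f0 <- td_to_fd(h, edges, 0)
  expect_equal(f0$amplitude, sum(h))
  expect_equal(f0$phase, 0)
  # single-gate impulse: phase is -2 pi f t0 (mod 2 pi)
  h1 <- c(0, 0, 3, 0, 0, 0, 0, 0, 0, 0)
  f <- 0.002
  f1 <- td_to_fd(h1, edges, f)
  expect_equal(f1$amplitude, 3)
  expect_equal(f1$phase %% (2 * pi), (-2 * pi * f * 25) %% (2 * pi),
               tolerance = 1e-9)
  # two equal gates half a period apart cancel
  fc <- 1 / (2 * 30)
  h2 <- c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(td_to_fd(h2, edges, fc)$amplitude, 0, tolerance = 1e-12)
  expect_warning(td_to_fd(rep(0, 10), edges, 0.01), "empty")
  expect_error(td_to_fd(h, edges[-1], 0.01), "length")
})
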