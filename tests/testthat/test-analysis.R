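test_that("line profiles sample bilinearly and exactly on linear fields", {
  img <- matrix(1, 10, 10)
  p <- extract_line_profile(img, c(1, 1), c(10, 10), n_samples = 25)
  expect_true(all(p$value == 1))
  expect_true(all(diff(p$position) > 0))

  # one-hot column crossed horizontally: single peak at the crossing
  img2 <- matrix(0, 11, 11); img2[, 6] <- 1
  p2 <- extract_line_profile(img2, c(6, 1), c(6, 11), n_samples = 11)
  expect_equal(which.max(p2$value), 6)
  expect_equal(sum(p2$value > 0.999), 1)

  # bilinear interpolation is exact on a linear ramp
  ramp <- outer(1:20, 1:20, function(i, j) 2 * i + 0.5 * j)
  p3 <- extract_line_profile(ramp, c(2, 3), c(18, 3), n_samples = 9, pitch = 0.2)
  expect_equal(p3$value, seq(2 * 2 + 1.5, 2 * 18 + 1.5, length.out = 9),
               tolerance = 1e-12)
  slope <- diff(p3$value) / diff(p3$position)
  expect_equal(slope, rep(2 / 0.2, 8), tolerance = 1e-9)

  expect_error(extract_line_profile(img, c(0, 1), c(5, 5)), "inside")
})

test_that("profile normalization is scale-invariant with unit peak", {
  p <- structure(data.frame(position = 1:3, value = c(2, 4, 8)),
                 class = c("line_profile", "data.frame"))
  expect_equal(normalize_profile(p)$value, c(0.25, 0.5, 1))
  expect_equal(normalize_profile(normalize_profile(p))$value,
               normalize_profile(p)$value)
  p2 <- p; p2$value <- p$value * 37.5
  expect_equal(normalize_profile(p2)$value, normalize_profile(p)$value)
  p0 <- p; p0$value <- 0 * p$value
  expect_error(normalize_profile(p0), "positive")
})

test_that("nrmse is the scaled L2 residual", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0.5, 0.5), c(1, 0)), sqrt(0.5), tolerance = 1e-12)
  set.seed(14)
  for (k in 1:20) {
    x <- stats::rnorm(50); y <- stats::rnorm(50)
    expect_equal(nrmse(x, y), sqrt(sum((x - y)^2)) / sqrt(sum(y^2)))
    expect_equal(nrmse(3.7 * x, 3.7 * y), nrmse(x, y), tolerance = 1e-12)
  }
  expect_error(nrmse(1:3, 1:4), "length")
  expect_error(nrmse(1:3, c(0, 0, 0)), "zero")
})

test_that("results serialize with metadata and read back", {
  dir <- withr::local_tempdir()
  sc <- cube_scene()
  cfg <- builtin_example("blt_cube")
  r <- run_simulation(sc, source_spec("point", position = c(0, 0, 2),
                                      n_photons = 1000),
                      run_controls(n_photons = 1000, seed = 2),
                      recorders = recorder_spec(face_grid = list(
                        side = 10, rows = 15, cols = 15, center = c(0, 0, 0))))
  write_result(r, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 2)
  expect_equal(meta$config_hash, unname(config_hash(cfg)))
  m <- read_result_matrix(file.path(dir, "face_zp_excitation.csv"))
  expect_equal(unname(m), unname(r$face_grid$excitation[, , 6]),
               tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "face_zp_excitation.png")))
  expect_true(file.exists(file.path(dir, "run_log.jsonl")))
})

test_that("the CLI runs the example-to-comparison workflow deterministically", {
  dir <- withr::local_tempdir()
  withr::local_dir(dir)
  cfgp <- file.path(dir, "blt.json")
  expect_equal(run_cli(c("example", "blt_cube", "--out", cfgp)), 0L)
  expect_true(file.exists(cfgp))

  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  code <- run_cli(c("simulate", cfgp, "--seed", "7", "--photons", "800",
                    "--out", out1))
  expect_equal(code, 0L)
  expect_equal(run_cli(c("simulate", cfgp, "--seed", "7", "--photons", "800",
                         "--out", out2)), 0L)
  f1 <- file.path(out1, "face_zp_excitation.csv")
  f2 <- file.path(out2, "face_zp_excitation.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))

  # compare a result with itself -> 0
  cmp <- utils::capture.output(code2 <- run_cli(c("compare", f1, f2)))
  expect_equal(code2, 0L)
  expect_equal(as.numeric(cmp[length(cmp)]), 0)

  # profile across the top-face map
  prof <- utils::capture.output(
    code3 <- run_cli(c("profile", f1, "--line", "8,1,8,15", "--n", "10")))
  expect_equal(code3, 0L)
  expect_gt(length(prof), 5)

  # failures exit non-zero with a one-line diagnostic
  expect_equal(run_cli(c("simulate", "no_such_config.json")), 1L)
  expect_equal(run_cli(character(0)), 1L)
  expect_equal(run_cli(c("frobnicate")), 1L)
})
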