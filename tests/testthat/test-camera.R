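test_that("camera construction enforces thin-lens conjugates", {
  cm <- camera_model(c(100, 0, 0), c(-1, 0, 0), f = 25, u = 100)
  expect_equal(1 / cm$u + 1 / cm$v, 1 / cm$f, tolerance = 1e-12)
  expect_equal(cm$v, 100 / 3, tolerance = 1e-9)
  expect_equal(sum(cm$axis^2), 1)
  expect_error(camera_model(c(0, 0, 0), c(1, 0, 0), f = 10, u = 5), "exceed")
})

test_that("lens mapping inverts and scales by the magnification", {
  cm <- camera_model(c(0, 0, 0), c(1, 0, 0), f = 10, u = 30,
                     npix = c(100, 100), pitch = 0.1)
  ctr <- c((100 + 1) / 2, (100 + 1) / 2)
  # on-axis point -> principal pixel
  expect_equal(unname(lens_image_point(c(30, 0, 0), cm)), ctr)
  # u = 3f: v = 1.5f, M = 0.5; height 2 mm images at -1 mm
  p <- lens_image_point(c(30, 0, 2), cm)
  expect_equal(unname(p - ctr) * cm$pitch, c(-1, 0))
  # u = 2f: unit magnification, inverted
  cm2 <- camera_model(c(0, 0, 0), c(1, 0, 0), f = 10, u = 20,
                      npix = c(100, 100), pitch = 0.1)
  p2 <- lens_image_point(c(20, 0, 1.5), cm2)
  expect_equal(unname(p2 - ctr) * cm2$pitch, c(-1.5, 0))
  # off-detector points return NULL; lens-plane points error
  expect_null(lens_image_point(c(30, 0, 500), cm))
  expect_error(lens_image_point(c(0, 0, 2), cm), "lens plane")
})

test_that("visibility blocks segments crossing the scene", {
  sc <- cube_scene()
  cam_pt <- c(50, 0, 0)
  expect_equal(visibility(c(5, 0, 0), cam_pt, sc), 1L)   # facing element
  expect_equal(visibility(c(-5, 0, 0), cam_pt, sc), 0L)  # behind the cube
  expect_equal(visibility(c(5, 2, 2), cam_pt, sc), 1L)
})

test_that("the Lambertian kernel takes its closed form and scaling laws", {
  # J = pi, dS = 1, unit distance, normal incidence both ends -> 1
  expect_equal(lambertian_contribution(pi, 1, c(0, 0, 0), c(1, 0, 0),
                                       c(1, 0, 0), c(-1, 0, 0)), 1.0)
  # grazing receiver: zero
  expect_equal(lambertian_contribution(pi, 1, c(0, 0, 0), c(1, 0, 0),
                                       c(1, 0, 0), c(0, 0, 1)), 0)
  # back-facing emitter: zero
  expect_equal(lambertian_contribution(pi, 1, c(0, 0, 0), c(-1, 0, 0),
                                       c(1, 0, 0), c(-1, 0, 0)), 0)
  # inverse square
  e1 <- lambertian_contribution(2, 0.1, c(0, 0, 0), c(1, 0, 0),
                                c(2, 0, 0), c(-1, 0, 0))
  e2 <- lambertian_contribution(2, 0.1, c(0, 0, 0), c(1, 0, 0),
                                c(4, 0, 0), c(-1, 0, 0))
  expect_equal(e1 / e2, 4)
  # geometric reciprocity: swapping emitter and receiver roles (each
  # normal keeps facing the other end) leaves the kernel unchanged
  r <- c(0, 0, 0); rd <- c(3, 1, 2)
  ns <- c(1, 0, 0); nd <- -c(3, 1, 2) / sqrt(14)
  k1 <- lambertian_contribution(1, 1, r, ns, rd, nd)
  k2 <- lambertian_contribution(1, 1, rd, nd, r, ns)
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("a small on-axis Lambertian disc matches the view-factor limit", {
  # total power on a distant patch: J dS dA / (pi r^2)
  J <- 2.5; disc_r <- 0.05; dist <- 40
  n_el <- 400
  set.seed(12)
  rr <- disc_r * sqrt(stats::runif(n_el))
  th <- stats::runif(n_el, 0, 2 * pi)
  dS <- pi * disc_r^2 / n_el
  dA <- 0.04
  tot <- 0
  for (k in 1:n_el) {
    tot <- tot + lambertian_contribution(
      J, dS, c(rr[k] * cos(th[k]), rr[k] * sin(th[k]), 0), c(0, 0, 1),
      c(0, 0, dist), c(0, 0, -1)) * dA
  }
  expect_equal(tot, J * pi * disc_r^2 * dA / (pi * dist^2), tolerance = 0.01)
})

test_that("surface flux maps conserve the exited weight", {
  sc <- cube_scene()
  src <- source_spec("point", position = c(0, 0, 2), n_photons = 5000)
  r <- run_simulation(sc, src, run_controls(n_photons = 5000, seed = 6),
                      recorders = recorder_spec(face_grid = list(
                        side = 10, rows = 20, cols = 20, center = c(0, 0, 0))))
  fg <- surface_flux_map(r, use = "face_grid")
  expect_equal(sum(fg$J * fg$area), sum(r$totals$exited), tolerance = 1e-9)
  tr <- surface_flux_map(r, use = "triangles")
  expect_equal(sum(tr$J * tr$area), sum(r$totals$exited), tolerance = 1e-9)
})

test_that("rendering maps flux to the detector and respects occlusion", {
  sc <- cube_scene()
  cm <- camera_model(c(60, 0, 0), c(-1, 0, 0), f = 10, u = 60,
                     npix = c(60, 60), pitch = 0.05)
  # zero flux -> zero image
  flux0 <- data.frame(x = 5, y = 0, z = 0, nx = 1, ny = 0, nz = 0,
                      area = 1, weight = 0, J = 0)
  class(flux0) <- c("surface_flux_map", "data.frame")
  expect_equal(sum(render_detector(flux0, cm)), 0)
  # a single on-axis luminous element lands at the image centre
  flux1 <- flux0; flux1$weight <- 1; flux1$J <- 1
  img <- render_detector(flux1, cm)
  expect_gt(sum(img), 0)
  hot <- which(unclass(img) == max(img), arr.ind = TRUE)
  expect_equal(unname(hot[1, ]), c(30, 30), tolerance = 1)
  # occluding the element kills the image
  img_occ <- render_detector(flux1, cm, scene = sc)
  # element sits on the cube surface: visible (epsilon guard), image survives
  expect_gt(sum(img_occ), 0)
  flux_back <- flux1; flux_back$x <- -5
  img_back <- render_detector(flux_back, cm, scene = sc)
  expect_equal(sum(img_back), 0)
})

test_that("occlusion testing can only decrease pixels", {
  sc <- cube_scene()
  src <- source_spec("point", position = c(0, 0, 0), n_photons = 4000)
  rec <- recorder_spec(face_grid = list(side = 10, rows = 20, cols = 20,
                                        center = c(0, 0, 0)))
  r <- run_simulation(sc, src, run_controls(n_photons = 4000, seed = 8),
                      recorders = rec)
  flux <- surface_flux_map(r)
  cm <- camera_model(c(60, 0, 0), c(-1, 0, 0), f = 10, u = 60,
                     npix = c(40, 40), pitch = 0.1)
  img_free <- render_detector(flux, cm, scene = NULL)
  img_occ <- render_detector(flux, cm, scene = sc)
  expect_true(all(unclass(img_occ) <= unclass(img_free) + 1e-15))
  # a synthetic luminous element hidden behind the cube, facing the
  # camera: visible without the occluder, dark with it
  hidden <- data.frame(x = -6, y = 0, z = 0, nx = 1, ny = 0, nz = 0,
                       area = 1, weight = 1, J = 1)
  class(hidden) <- c("surface_flux_map", "data.frame")
  expect_gt(sum(render_detector(hidden, cm, scene = NULL)), 0)
  expect_equal(sum(render_detector(hidden, cm, scene = sc)), 0)
})

test_that("place_cameras rings the scene aimed at the origin", {
  tmpl <- camera_model(c(100, 0, 0), c(-1, 0, 0), f = 25, u = 100)
  cams <- place_cameras(4, 100, tmpl)
  expect_length(cams, 4)
  expect_equal(vapply(cams, function(cm) cm$view_angle_deg, 0),
               c(0, 90, 180, 270))
  for (cm in cams) {
    # optical axis points from the lens at the origin
    expect_equal(cm$axis, -cm$lens_center / sqrt(sum(cm$lens_center^2)),
                 tolerance = 1e-12)
    expect_equal(sqrt(sum(cm$lens_center^2)), 100)
  }
  expect_equal(cams[[1]]$lens_center, c(100, 0, 0), tolerance = 1e-9)
  single <- place_cameras(1, 50, tmpl)
  expect_length(single, 1)
  sc <- cube_scene()
  expect_error(place_cameras(4, 5, tmpl, scene = sc), "bounding")
})
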