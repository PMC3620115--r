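#' Thin-lens/pinhole CCD camera model
#'
#' Geometry of Fig.-style non-contact detection: a thin lens with focal
#' length `f` focused on an object plane at distance `u`, imaging onto a
#' detector plane at distance `v` behind the lens with `1/u + 1/v = 1/f`
#' (enforced to 1e-9). The central ray through the lens centre maps a
#' surface point at axial distance `u_P` and lateral height `h` to the
#' detector at `-h * v / u_P` (magnification `v/u`, inverted); energy is
#' evaluated on the object-side conjugate (virtual detector) plane and
#' carried over unchanged, so no aperture integration is performed.
#'
#' @param lens_center length-3 lens centre (mm).
#' @param optical_axis unit vector from the lens toward the scene.
#' @param f focal length (mm).
#' @param u object distance (mm), `u > f`.
#' @param npix integer c(rows, cols) of the detector.
#' @param pitch pixel pitch (mm).
#' @param up approximate detector "up" direction (row axis).
#' @param view_angle_deg optional label.
#' @return a `camera_model`.
#' @export
camera_model <- function(lens_center, optical_axis, f, u,
                         npix = c(120, 120), pitch = 0.1,
                         up = c(0, 0, 1), view_angle_deg = NA_real_) {
  a <- as.numeric(optical_axis); a <- a / sqrt(sum(a^2))
  if (u <= f) stop("object distance u must exceed the focal length f")
  v <- 1 / (1 / f - 1 / u)
  if (abs(1 / u + 1 / v - 1 / f) > 1e-9) stop("thin-lens consistency failed")
  up <- as.numeric(up)
  if (abs(sum(up * a)) > 0.999) up <- c(1, 0, 0)
  right <- c(a[2] * up[3] - a[3] * up[2],
             a[3] * up[1] - a[1] * up[3],
             a[1] * up[2] - a[2] * up[1])
  right <- right / sqrt(sum(right^2))
  up2 <- c(right[2] * a[3] - right[3] * a[2],
           right[3] * a[1] - right[1] * a[3],
           right[1] * a[2] - right[2] * a[1])
  structure(list(lens_center = as.numeric(lens_center), axis = a,
                 f = f, u = u, v = v,
                 npix = as.integer(npix), pitch = pitch,
                 e_row = up2, e_col = right,
                 view_angle_deg = view_angle_deg),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: f=%g mm, u=%g, v=%g (M=%.3g), %dx%d px @ %g mm",
              x$f, x$u, x$v, x$v / x$u, x$npix[1], x$npix[2], x$pitch))
  if (!is.na(x$view_angle_deg)) cat(sprintf(", view %g deg", x$view_angle_deg))
  cat("\n")
  invisible(x)
}

#' Image a surface point through the lens onto the detector
#'
#' Pinhole position mapping: the central ray through the lens centre is
#' extended to the detector plane at distance `v` behind the lens; lateral
#' coordinates scale by `-v / u_P` (inverted image). Returns fractional
#' detector coordinates `(row, col)` (1-based, image centre at the
#' principal pixel), or `NULL` if the mapped point falls off the detector.
#'
#' @param surface_point length-3 point (mm), on the scene side of the lens
#'   plane.
#' @param camera a [camera_model()].
#' @export
lens_image_point <- function(surface_point, camera) {
  rel <- as.numeric(surface_point) - camera$lens_center
  ax <- sum(rel * camera$axis)
  if (abs(ax) < 1e-9) stop("point lies on the lens plane")
  if (ax < 0) stop("point is behind the lens")
  h_row <- sum(rel * camera$e_row)
  h_col <- sum(rel * camera$e_col)
  m <- -camera$v / ax
  ir <- h_row * m / camera$pitch + (camera$npix[1] + 1) / 2
  ic <- h_col * m / camera$pitch + (camera$npix[2] + 1) / 2
  if (ir < 0.5 || ic < 0.5 || ir > camera$npix[1] + 0.5 ||
      ic > camera$npix[2] + 0.5) return(NULL)
  c(row = ir, col = ic)
}

#' Visibility factor between a surface point and a receiving point
#'
#' `1` iff the open segment from `r` to `r_d` is unobstructed by any scene
#' triangle (with an epsilon guard at both ends), else `0`. This is the
#' indicator that discards surface elements invisible from the receiving
#' plane.
#'
#' @param r surface point (mm), or an n x 3 matrix of points.
#' @param r_d receiving point (mm).
#' @param scene an `mc_scene`.
#' @export
visibility <- function(r, r_d, scene) {
  r <- if (is.matrix(r)) r else matrix(as.numeric(r), 1, 3)
  blocked <- cpp_segment_blocked(scene_ptr(scene), r,
                                 matrix(as.numeric(r_d), 1, 3), 1e-6)
  as.integer(!blocked)
}

#' Lambertian free-space energy kernel
#'
#' Flux-density increment at a receiving element from a diffusely emitting
#' surface element:
#' `dE = J cos(theta_s) cos(theta_d) xi(r, r_d) dS / (pi |r - r_d|^2)`
#' where `J` is the element's outgoing flux density, `theta_s`/`theta_d`
#' the angles of the connecting line against the surface and detector
#' normals (clamped at 90 degrees, which also culls back-facing
#' elements), and `xi` the visibility factor.
#'
#' @param J element flux density (weight mm^-2).
#' @param dS element area (mm^2).
#' @param r element centre; `n_s` its outward normal.
#' @param r_d receiving point; `n_d` the receiver normal (facing the
#'   scene).
#' @param scene optional `mc_scene` for the visibility test (`NULL` skips
#'   it, i.e. assumes visible).
#' @return the flux-density increment at the receiver (weight mm^-2).
#' @export
lambertian_contribution <- function(J, dS, r, n_s, r_d, n_d, scene = NULL) {
  d <- as.numeric(r_d) - as.numeric(r)
  dist2 <- sum(d^2)
  if (dist2 < 1e-12) return(0)        # near-singular geometry: skip
  dhat <- d / sqrt(dist2)
  cs <- max(0, sum(n_s * dhat))
  cd <- max(0, -sum(n_d * dhat))
  if (cs == 0 || cd == 0) return(0)
  vis <- if (is.null(scene)) 1 else visibility(r, r_d, scene)
  J * cs * cd * vis * dS / (pi * dist2)
}

#' Surface flux map from a transport result
#'
#' Converts a transport run's exit recorders into per-element outgoing
#' flux densities `J = exited weight / element area`, with element
#' centres, areas and outward normals — the input of the free-space camera
#' model. Uses the cube face-grid recorder when present, else the
#' per-triangle exit record.
#'
#' @param result an `mc_result`.
#' @param band `"excitation"` or `"emission"`.
#' @param use one of `"auto"`, `"face_grid"`, `"triangles"`.
#' @return a `surface_flux_map`: data frame with columns `x,y,z`
#'   (centres), `nx,ny,nz` (normals), `area`, `weight`, `J`.
#' @export
surface_flux_map <- function(result, band = "excitation",
                             use = c("auto", "face_grid", "triangles")) {
  use <- match.arg(use)
  if (use == "auto") use <- if (!is.null(result$face_grid)) "face_grid" else "triangles"
  if (use == "face_grid") {
    if (is.null(result$face_grid)) stop("result has no face-grid recorder")
    fg <- result$recorders$face_grid
    ctr <- as.numeric(fg$center %||% c(0, 0, 0))
    side <- fg$side; rows <- fg$rows; cols <- fg$cols
    du <- side / rows; dv <- side / cols
    h <- side / 2
    arr <- result$face_grid[[band]]
    out <- vector("list", 6)
    for (face in 1:6) {
      ax <- (face + 1) %/% 2
      sg <- if (face %% 2 == 0) 1 else -1
      sp <- setdiff(1:3, ax)
      idx <- which(arr[, , face] > -1)  # all cells
      ij <- arrayInd(idx, c(rows, cols))
      p <- matrix(0, nrow(ij), 3)
      p[, ax] <- ctr[ax] + sg * h
      p[, sp[1]] <- ctr[sp[1]] - h + (ij[, 1] - 0.5) * du
      p[, sp[2]] <- ctr[sp[2]] - h + (ij[, 2] - 0.5) * dv
      nrm <- matrix(0, nrow(ij), 3); nrm[, ax] <- sg
      w <- as.numeric(arr[, , face])
      out[[face]] <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                                nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                                area = du * dv, weight = w)
    }
    df <- do.call(rbind, out)
  } else {
    sc <- result$scene
    w <- result$tri_exit[[band]]
    v <- sc$V; f <- sc$F + 1L
    cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
    ar <- unlist(lapply(sc$regions, function(r) r$mesh$areas))
    df <- data.frame(x = cen[, 1], y = cen[, 2], z = cen[, 3],
                     nx = sc$N[, 1], ny = sc$N[, 2], nz = sc$N[, 3],
                     area = ar, weight = w)
  }
  df$J <- df$weight / df$area
  class(df) <- c("surface_flux_map", "data.frame")
  df
}

#' Render a detector image from a surface flux map
#'
#' Every emitting surface element is mapped through the lens to its
#' conjugate pixel; its energy contribution is evaluated on the
#' object-side conjugate (virtual detector) plane with the Lambertian
#' kernel and visibility test, and assigned to the nearest pixel (flux
#' density at the detector equals that at the conjugate point).
#'
#' @param surface_flux a [surface_flux_map()].
#' @param camera a [camera_model()].
#' @param scene optional `mc_scene` for occlusion testing (`NULL` skips).
#' @return a `detector_image`: matrix of pixel flux densities (weight
#'   mm^-2) with the camera attached as an attribute.
#' @export
render_detector <- function(surface_flux, camera, scene = NULL) {
  df <- surface_flux[surface_flux$weight > 0, , drop = FALSE]
  img <- matrix(0, camera$npix[1], camera$npix[2])
  if (nrow(df)) {
    P <- as.matrix(df[, c("x", "y", "z")])
    Nrm <- as.matrix(df[, c("nx", "ny", "nz")])
    rel <- sweep(P, 2, camera$lens_center)
    ax <- as.numeric(rel %*% camera$axis)
    keep <- ax > 1e-9
    if (any(keep)) {
      P <- P[keep, , drop = FALSE]; Nrm <- Nrm[keep, , drop = FALSE]
      rel <- rel[keep, , drop = FALSE]; ax <- ax[keep]
      J <- df$J[keep]; dS <- df$area[keep]
      hr <- as.numeric(rel %*% camera$e_row)
      hc <- as.numeric(rel %*% camera$e_col)
      m <- -camera$v / ax
      ir <- round(hr * m / camera$pitch + (camera$npix[1] + 1) / 2)
      ic <- round(hc * m / camera$pitch + (camera$npix[2] + 1) / 2)
      onpix <- ir >= 1 & ic >= 1 & ir <= camera$npix[1] & ic <= camera$npix[2]
      if (any(onpix)) {
        P <- P[onpix, , drop = FALSE]; Nrm <- Nrm[onpix, , drop = FALSE]
        ax <- ax[onpix]; J <- J[onpix]; dS <- dS[onpix]
        ir <- ir[onpix]; ic <- ic[onpix]
        hr <- hr[onpix]; hc <- hc[onpix]
        # conjugate point P' on the object-side virtual detector plane
        tscl <- camera$v / ax
        Pp <- cbind(camera$lens_center[1] + camera$v * camera$axis[1] +
                      tscl * hr * camera$e_row[1] + tscl * hc * camera$e_col[1],
                    camera$lens_center[2] + camera$v * camera$axis[2] +
                      tscl * hr * camera$e_row[2] + tscl * hc * camera$e_col[2],
                    camera$lens_center[3] + camera$v * camera$axis[3] +
                      tscl * hr * camera$e_row[3] + tscl * hc * camera$e_col[3])
        D <- Pp - P
        dist2 <- rowSums(D^2)
        ok <- dist2 > 1e-12
        dhat <- D / sqrt(pmax(dist2, 1e-300))
        cs <- pmax(0, rowSums(Nrm * dhat))
        # receiver normal faces the scene (+axis): cos(theta_d) = -axis . dhat
        cd <- as.numeric(pmax(0, -(dhat %*% camera$axis)))
        dE <- J * cs * cd * dS / (pi * dist2)
        dE[!ok] <- 0
        live <- dE > 0
        if (any(live) && !is.null(scene)) {
          blocked <- cpp_segment_blocked(scene_ptr(scene),
                                         P[live, , drop = FALSE],
                                         Pp[live, , drop = FALSE], 1e-6)
          dE[live][blocked] <- 0
        }
        if (any(dE > 0)) {
          lin <- (ic - 1) * camera$npix[1] + ir
          acc <- tapply(dE, lin, sum)
          img[as.integer(names(acc))] <- img[as.integer(names(acc))] + acc
        }
      }
    }
  }
  structure(img, class = c("detector_image", "matrix"),
            camera = camera, pixel_area = camera$pitch^2)
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("detector_image: %d x %d px, total flux density %.6g, peak %.6g\n",
              nrow(x), ncol(x), sum(x), max(x)))
  invisible(x)
}

#' @export
plot.detector_image <- function(x, log10 = FALSE, ...) {
  z <- unclass(x)
  if (log10) z <- base::log10(z + max(z) * 1e-6 + 1e-300)
  graphics::image(t(z[nrow(z):1, ]), useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Place cameras around the scene
#'
#' `n_views` cameras equally spaced in angle about `axis` at distance
#' `radius` from the origin, each optical axis aimed at the origin. Four
#' views give the 0/90/180/270-degree arrangement of the packaged
#' bioluminescence example.
#'
#' @param n_views number of cameras (>= 1); view k sits at angle
#'   `(k-1) * 360 / n_views` degrees, with 0 degrees on `+x` for the
#'   default `axis = c(0, 0, 1)`.
#' @param radius lens distance from the origin (mm); must exceed the
#'   scene's bounding radius.
#' @param template a [camera_model()] whose optics (f, u, npix, pitch)
#'   are copied; its pose is ignored.
#' @param axis rotation axis (unit vector).
#' @param scene optional `mc_scene` used to validate the radius.
#' @return list of `camera_model`s.
#' @export
place_cameras <- function(n_views, radius, template, axis = c(0, 0, 1),
                          scene = NULL) {
  if (n_views < 1) stop("n_views must be >= 1")
  if (!is.null(scene)) {
    rmax <- sqrt(max(rowSums(scene$V^2)))
    if (radius <= rmax)
      stop("camera radius ", radius, " lies inside the scene bounding sphere (",
           signif(rmax, 4), " mm)")
  }
  a <- as.numeric(axis); a <- a / sqrt(sum(a^2))
  ref <- if (abs(a[3]) < 0.999) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e1 <- {  # 0 degrees on +x when axis is +z
    cand <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
    if (sqrt(sum(cand^2)) > 1e-6) cand / sqrt(sum(cand^2)) else e1
  }
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  lapply(seq_len(n_views), function(k) {
    ang <- (k - 1) * 2 * pi / n_views
    pos <- radius * (cos(ang) * e1 + sin(ang) * e2)
    camera_model(lens_center = pos, optical_axis = -pos / radius,
                 f = template$f, u = template$u, npix = template$npix,
                 pitch = template$pitch, up = a,
                 view_angle_deg = (k - 1) * 360 / n_views)
  })
}
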