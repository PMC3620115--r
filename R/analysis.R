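#' Bilinear line profile through an image
#'
#' Samples `n_samples` evenly spaced points along the segment from `start`
#' to `end` (pixel coordinates, 1-based `(row, col)`) with bilinear
#' interpolation — the sampling used for quantitative comparison of
#' transmittance/detector maps along a marked line.
#'
#' @param image numeric matrix.
#' @param start,end length-2 pixel coordinates `(row, col)` inside the
#'   image.
#' @param n_samples number of samples (>= 2).
#' @param pitch physical pixel pitch (mm) used for the position axis.
#' @return a `line_profile`: data frame with `position` (mm along the
#'   line, strictly increasing) and `value`.
#' @export
extract_line_profile <- function(image, start, end, n_samples = 100,
                                 pitch = 1) {
  image <- as.matrix(image)
  chk <- function(p) p[1] >= 1 && p[2] >= 1 && p[1] <= nrow(image) &&
    p[2] <= ncol(image)
  if (!chk(start) || !chk(end)) stop("profile endpoints must lie inside the image")
  if (n_samples < 2) stop("n_samples must be >= 2")
  tseq <- seq(0, 1, length.out = n_samples)
  r <- start[1] + tseq * (end[1] - start[1])
  c3 <- start[2] + tseq * (end[2] - start[2])
  r0 <- pmin(pmax(floor(r), 1), nrow(image) - 1)
  c0 <- pmin(pmax(floor(c3), 1), ncol(image) - 1)
  fr <- r - r0; fc <- c3 - c0
  v <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    fr * (1 - fc) * image[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * image[cbind(r0, c0 + 1)] +
    fr * fc * image[cbind(r0 + 1, c0 + 1)]
  seglen <- sqrt(sum((end - start)^2)) * pitch
  structure(data.frame(position = tseq * seglen, value = v),
            class = c("line_profile", "data.frame"))
}

#' Peak-normalize a line profile
#'
#' Divides by the maximum value so the peak equals 1 (the "normalized flux
#' density" convention used when comparing simulated and measured
#' profiles). Scale-invariant: `normalize_profile(k * p)` equals
#' `normalize_profile(p)` for any `k > 0`.
#'
#' @param p a `line_profile` (or anything with a `value` column).
#' @export
normalize_profile <- function(p) {
  mx <- max(p$value)
  if (!is.finite(mx) || mx <= 0) stop("profile maximum must be positive")
  p$value <- p$value / mx
  p
}

#' @export
plot.line_profile <- function(x, ...) {
  graphics::plot(x$position, x$value, type = "l", xlab = "position (mm)",
                 ylab = "flux density", ...)
  invisible(x)
}

#' Normalized root-mean-square error between two profiles
#'
#' `NRMSE = ||x - y||_2 / ||y||_2`: the L2 residual norm over the L2 norm
#' of the reference. Zero iff the profiles are identical; invariant under
#' a common positive rescaling of both inputs.
#'
#' @param x numeric vector (result under test).
#' @param y numeric reference vector of the same length with
#'   `sum(y^2) > 0`.
#' @export
nrmse <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1) stop("profiles must be non-empty")
  ny <- sqrt(sum(y^2))
  if (ny == 0) stop("reference norm is zero")
  sqrt(sum((x - y)^2)) / ny
}
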