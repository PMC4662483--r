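#' Estimate the wound main axis
#'
#' The main axis is the principal eigenvector of the second central moments
#' (covariance) of the wound pixel coordinates — the direction along which
#' the scratch runs. Axial positions used throughout the package are scalar
#' projections onto this direction, relative to the wound centroid.
#'
#' @param mask A `region_mask` from [segment_wound()] or a binary matrix.
#' @return An object of class `wound_axis`: list with `direction` (unit
#'   (row, col) vector, sign-normalised so its first nonzero component is
#'   positive), `centroid` (row, col), `extent` (`c(min, max)` projection of
#'   wound pixels onto the direction, relative to the centroid), and
#'   `angle_deg` (degrees from vertical, in `[-90, 90)`).
#' @details An empty wound is an error, as is a near-isotropic wound region
#'   (principal moments within 5% of each other), for which no main axis is
#'   defined.
#' @export
estimate_axis <- function(mask) {
  wound <- as_wound_mask(mask)
  idx <- which(wound, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty wound: no main axis")
  centroid <- colMeans(idx)
  xc <- sweep(idx, 2L, centroid)
  cv <- crossprod(xc) / nrow(idx)
  ev <- eigen(cv, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l1 <= 0 || (l1 - l2) / l1 < 0.05)
    stop("isotropic wound region: no well-defined main axis ",
         sprintf("(principal moments %.3g, %.3g)", l1, l2))
  d <- ev$vectors[, 1]
  nz <- which(abs(d) > 1e-12)[1]
  if (d[nz] < 0) d <- -d
  proj <- xc %*% d
  structure(list(direction = as.numeric(d),
                 centroid = as.numeric(centroid),
                 extent = range(proj),
                 angle_deg = atan2(d[2], d[1]) * 180 / pi),
            class = "wound_axis")
}

#' @export
print.wound_axis <- function(x, ...) {
  cat(sprintf(
    "<wound_axis> angle %.2f deg from vertical, centroid (%.1f, %.1f), extent [%.1f, %.1f] px\n",
    x$angle_deg, x$centroid[1], x$centroid[2], x$extent[1], x$extent[2]))
  invisible(x)
}

# Axial (s) and perpendicular (t) coordinates of points relative to an axis.
# pts is an n x 2 matrix of (row, col).
axis_coords <- function(pts, axis) {
  dr <- pts[, 1] - axis$centroid[1]
  dc <- pts[, 2] - axis$centroid[2]
  d <- axis$direction
  n <- c(-d[2], d[1])
  cbind(s = dr * d[1] + dc * d[2], t = dr * n[1] + dc * n[2])
}
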