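#' Extract the two cell/wound boundary contours
#'
#' Traces the boundary between the compacted cell layer and the wounded area
#' at subpixel precision (linear interpolation of the 0.5 level of the
#' binary mask, so straight boundaries sit at half-integer pixel
#' coordinates), splits it into the two sides of the wound by the sign of
#' each point's perpendicular offset from the main axis, and orders each
#' side by axial projection.
#'
#' @param mask A `region_mask` from [segment_wound()] or a binary matrix.
#' @param axis A `wound_axis` from [estimate_axis()].
#' @return An object of class `wound_contour`: list with `side_a` and
#'   `side_b`, each a matrix with columns `s` (axial projection, strictly
#'   increasing), `row`, `col`; and `span`, the axial interval over which
#'   both sides are defined.
#' @details Points with identical axial projection (jagged pixel steps) are
#'   merged by averaging, so each side is strictly monotone in `s` and can
#'   be intersected with a perpendicular measurement line by interpolation
#'   in `s`. If the boundary cannot be split into two nonempty sides (e.g. a
#'   wound filling the frame to all four borders), an error is raised.
#' @export
extract_contours <- function(mask, axis) {
  wound <- as_wound_mask(mask)
  if (!any(wound)) stop("empty wound: nothing to trace")
  stopifnot(inherits(axis, "wound_axis"))
  h <- nrow(wound); w <- ncol(wound)
  cl <- grDevices::contourLines(x = seq_len(h), y = seq_len(w),
                                z = wound * 1, levels = 0.5)
  if (length(cl) == 0L)
    stop("wound boundary not separable: no cell/wound interface in frame")
  pts <- do.call(rbind, lapply(cl, function(sg) cbind(sg$x, sg$y)))
  st <- axis_coords(pts, axis)

  one_side <- function(sel) {
    if (!any(sel)) return(NULL)
    s <- st[sel, "s"]; p <- pts[sel, , drop = FALSE]
    o <- order(s)
    s <- s[o]; p <- p[o, , drop = FALSE]
    # merge equal projections so s is strictly increasing
    g <- cumsum(c(TRUE, diff(s) > 1e-9))
    if (max(g) < length(s)) {
      s <- as.numeric(tapply(s, g, mean))
      p <- cbind(as.numeric(tapply(p[, 1], g, mean)),
                 as.numeric(tapply(p[, 2], g, mean)))
    }
    cbind(s = s, row = p[, 1], col = p[, 2])
  }
  side_a <- one_side(st[, "t"] < -1e-9)
  side_b <- one_side(st[, "t"] > 1e-9)
  if (is.null(side_a) || is.null(side_b) ||
      nrow(side_a) < 2L || nrow(side_b) < 2L)
    stop("wound boundary not separable into two sides")
  span <- c(max(side_a[1, "s"], side_b[1, "s"]),
            min(side_a[nrow(side_a), "s"], side_b[nrow(side_b), "s"]))
  if (span[1] >= span[2])
    stop("wound boundary not separable: sides do not overlap axially")
  structure(list(side_a = side_a, side_b = side_b, span = span),
            class = "wound_contour")
}

#' @export
print.wound_contour <- function(x, ...) {
  cat(sprintf(
    "<wound_contour> side A: %d pts, side B: %d pts, common axial span [%.1f, %.1f] px\n",
    nrow(x$side_a), nrow(x$side_b), x$span[1], x$span[2]))
  invisible(x)
}

# Interpolate the (row, col) point of one contour side at axial position s0.
# Returns NULL when s0 lies outside the side's span.
contour_point_at <- function(side, s0) {
  s <- side[, "s"]
  if (s0 < s[1] || s0 > s[length(s)]) return(NULL)
  i <- findInterval(s0, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(s) - 1L)
  f <- (s0 - s[i]) / (s[i + 1] - s[i])
  c(row = side[i, "row"] + f * (side[i + 1, "row"] - side[i, "row"]),
    col = side[i, "col"] + f * (side[i + 1, "col"] - side[i, "col"]))
}
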