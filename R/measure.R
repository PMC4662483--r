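#' Place equally-spaced measurement-line positions along the wound axis
#'
#' N measurement lines are placed at the interior fractions
#' `k / (N + 1)`, `k = 1..N`, of the axial extent, so lines are equally
#' spaced and none sits at the wound's axial tips where border artifacts
#' accumulate. Explicit positions can instead be supplied to
#' [measure_widths()] directly.
#'
#' @param axis A `wound_axis` (its `extent` defines the span), or a numeric
#'   `c(min, max)` extent.
#' @param n_lines Number of lines, `>= 1` (assay default 5).
#' @return Numeric vector of `n_lines` axial positions,
#'   `p_k = extent_min + k * (extent_max - extent_min) / (n_lines + 1)`.
#' @examples
#' place_measurement_lines(c(0, 600), 5)  # 100 200 300 400 500
#' @export
place_measurement_lines <- function(axis, n_lines = 5L) {
  ext <- if (inherits(axis, "wound_axis")) axis$extent else as.numeric(axis)
  if (length(ext) != 2L || ext[1] >= ext[2])
    stop("invalid axial extent")
  n_lines <- as.integer(n_lines)
  if (is.na(n_lines) || n_lines < 1L) stop("n_lines must be >= 1")
  ext[1] + seq_len(n_lines) * diff(ext) / (n_lines + 1)
}

#' Measure wound widths along perpendicular lines
#'
#' For each axial position, the line perpendicular to the wound main axis is
#' intersected with the two boundary contours (linear interpolation between
#' neighbouring contour points); the wound width at that line is the
#' Euclidean distance between the two intersection points.
#'
#' A position at which a side's contour is absent (the gap has closed there)
#' is reported with width 0 and `flag_closed = TRUE` — a closed gap is a
#' zero width, not missing data — and still enters the mean.
#'
#' @param contour A `wound_contour` from [extract_contours()].
#' @param axis The `wound_axis` the contour was extracted against.
#' @param positions Numeric vector of axial positions (e.g. from
#'   [place_measurement_lines()]).
#' @param scale Optional physical scale (um per pixel); when given,
#'   `width_um = width_px * scale` is reported as well.
#' @return An object of class `width_profile`: list with `lines` (a
#'   data.frame: `index`, `position_px`, `width_px`, `width_um`,
#'   `flag_closed`, endpoint coordinates), `mean_width_px`,
#'   `mean_width_um` (NA without a scale) and `n_lines`.
#' @export
measure_widths <- function(contour, axis, positions, scale = NULL) {
  stopifnot(inherits(contour, "wound_contour"), inherits(axis, "wound_axis"))
  n <- length(positions)
  if (n < 1L) stop("at least one measurement position is required")
  res <- data.frame(index = seq_len(n), position_px = as.numeric(positions),
                    width_px = 0, width_um = NA_real_, flag_closed = FALSE,
                    a_row = NA_real_, a_col = NA_real_,
                    b_row = NA_real_, b_col = NA_real_)
  for (i in seq_len(n)) {
    pa <- contour_point_at(contour$side_a, positions[i])
    pb <- contour_point_at(contour$side_b, positions[i])
    if (is.null(pa) || is.null(pb)) {
      res$flag_closed[i] <- TRUE
      next
    }
    wpx <- sqrt(sum((pa - pb)^2))
    res$width_px[i] <- wpx
    res[i, c("a_row", "a_col")] <- pa
    res[i, c("b_row", "b_col")] <- pb
    if (wpx == 0) res$flag_closed[i] <- TRUE
  }
  if (!is.null(scale)) res$width_um <- res$width_px * scale
  structure(list(lines = res,
                 mean_width_px = mean(res$width_px),
                 mean_width_um = if (is.null(scale)) NA_real_ else
                   mean(res$width_px) * scale,
                 n_lines = n),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("<width_profile> %d lines, mean width %.2f px", x$n_lines,
              x$mean_width_px))
  if (!is.na(x$mean_width_um)) cat(sprintf(" (%.2f um)", x$mean_width_um))
  if (any(x$lines$flag_closed))
    cat(sprintf(", %d closed", sum(x$lines$flag_closed)))
  cat("\n")
  invisible(x)
}

# Empty-wound profile: all lines flagged closed with width 0.
closed_profile <- function(n_lines, scale = NULL) {
  res <- data.frame(index = seq_len(n_lines), position_px = NA_real_,
                    width_px = 0,
                    width_um = if (is.null(scale)) NA_real_ else 0,
                    flag_closed = TRUE,
                    a_row = NA_real_, a_col = NA_real_,
                    b_row = NA_real_, b_col = NA_real_)
  structure(list(lines = res, mean_width_px = 0,
                 mean_width_um = if (is.null(scale)) NA_real_ else 0,
                 n_lines = n_lines),
            class = "width_profile")
}

#' Quantify the wound width of a single micrograph
#'
#' The full measurement pipeline: segment cell vs wound by local texture,
#' estimate the wound main axis, extract the two boundary contours, place
#' `n_lines` equally-spaced perpendicular measurement lines, and measure the
#' gap width at each. A fully closed image (empty wound) yields a profile of
#' zero widths with every line flagged closed.
#'
#' Measurement lines are placed across the axial span where both boundary
#' contours are present in the frame: for oblique wounds the band's axial
#' tips are cut by the image border, and widths there are censored by the
#' frame rather than biologically closed, so lines are kept off them.
#'
#' @param img A [micrograph] or numeric matrix.
#' @param n_lines Number of measurement lines (assay default 5).
#' @param window,min_wound_area_frac,morph_radius Passed to
#'   [segment_wound()].
#' @param positions Optional explicit axial positions overriding automatic
#'   placement.
#' @param scale Physical scale (um per pixel); defaults to the micrograph's
#'   own scale if present.
#' @return A `width_profile` (see [measure_widths()]) with attributes
#'   `axis`, `contour` and `mask` attached for QC.
#' @examples
#' sim <- generate_scratch_image(scratch_spec(256, 320, wound_width = 60,
#'                                            seed = 3))
#' wp <- quantify_image(sim$image, window = 15)
#' wp$mean_width_px
#' @export
quantify_image <- function(img, n_lines = 5L, window = 15L,
                           min_wound_area_frac = 0.02, morph_radius = 5L,
                           positions = NULL, scale = NULL) {
  mg <- as_micrograph(img)
  if (is.null(scale)) scale <- mg$scale
  n_lines <- as.integer(n_lines)
  if (is.na(n_lines) || n_lines < 1L) stop("n_lines must be >= 1")

  mask <- segment_wound(mg, window = window,
                        min_wound_area_frac = min_wound_area_frac,
                        morph_radius = morph_radius)
  if (!any(mask$wound)) {
    wp <- closed_profile(n_lines, scale)
    attr(wp, "mask") <- mask
    return(wp)
  }
  axis <- estimate_axis(mask)
  contour <- extract_contours(mask, axis)
  if (is.null(positions)) {
    span <- contour$span
    eps <- 1e-6 * diff(span)
    clipped <- axis
    clipped$extent <- c(max(axis$extent[1], span[1] + eps),
                        min(axis$extent[2], span[2] - eps))
    positions <- place_measurement_lines(clipped, n_lines)
  }
  wp <- measure_widths(contour, axis, positions, scale = scale)
  attr(wp, "axis") <- axis
  attr(wp, "contour") <- contour
  attr(wp, "mask") <- mask
  wp
}
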