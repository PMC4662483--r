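# Moving-window mean/variance by box filtering (replicate borders).
local_variance <- function(px, window) {
  k <- matrix(1 / (window * window), window, window)
  m1 <- EBImage::filter2(px, k, boundary = "replicate")
  m2 <- EBImage::filter2(px * px, k, boundary = "replicate")
  pmax(m2 - m1 * m1, 0)
}

# Otsu's threshold on a 256-bin histogram. Ties in the between-class
# variance criterion are broken toward the LOWEST threshold, so the result
# is deterministic on multimodal histograms.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b)  # which.max returns the first (lowest) maximum
  breaks[k + 1L]
}

# Lag-1 spatial autocorrelation, averaged over rows and columns. Cell
# granulation is spatially correlated; pure sensor noise is white.
lag1_autocor <- function(px) {
  h <- nrow(px); w <- ncol(px)
  r1 <- suppressWarnings(cor(as.vector(px[, -1]), as.vector(px[, -w])))
  r2 <- suppressWarnings(cor(as.vector(px[-1, ]), as.vector(px[-h, ])))
  mean(c(r1, r2), na.rm = TRUE)
}

#' Segment the wound region of a scratch-assay micrograph
#'
#' Splits the image into cell and wounded areas from appearance: a
#' moving-window variance map is computed (cell monolayers are high-texture
#' under phase contrast, the denuded wound is smooth), thresholded, and
#' cleaned up morphologically; the largest low-texture connected component
#' is retained as the wound.
#'
#' The variance map is first split by Otsu's method; the working threshold
#' is then refined to the midpoint of the two class means. Because windowed
#' variance falls off linearly with the window's cell-area fraction across
#' the boundary, the midpoint threshold crosses at the true cell/wound
#' interface rather than a window-half-width inside it, keeping the
#' segmentation unbiased at the pixel scale.
#'
#' @param img A [micrograph] or numeric matrix.
#' @param window Odd window size in pixels for the local-texture map
#'   (`>= 3`, `< min(height, width) / 2`).
#' @param min_wound_area_frac Minimum wound area as a fraction of the image;
#'   smaller low-texture components yield an empty wound (fully closed), not
#'   an error.
#' @param morph_radius Disk radius (pixels) for morphological
#'   opening/closing cleanup.
#' @return An object of class `region_mask`: list with `wound` (logical
#'   matrix; the cell region is exactly its complement), `threshold` (the
#'   refined variance threshold), and `diagnostics` (component counts and
#'   areas).
#' @details Degenerate images on which the cell/wound split is undefined —
#'   constant frames, or smooth background whose only variation is white
#'   noise — raise an error (`"degenerate appearance"`). A fully closed,
#'   all-cell image returns an empty wound mask.
#' @export
segment_wound <- function(img, window = 15L, min_wound_area_frac = 0.02,
                          morph_radius = 5L) {
  px <- as_micrograph(img)$pixels
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L || window >= min(dim(px)) / 2)
    stop("window must be odd, >= 3 and < min(height, width) / 2")

  v <- local_variance(px, window)
  empty <- matrix(FALSE, nrow(px), ncol(px))
  if (max(v) < 1e-10)
    stop("degenerate appearance: cannot split (uniform texture map)")

  t0 <- otsu_threshold(v)
  lo <- v[v <= t0]; hi <- v[v > t0]
  m_lo <- mean(lo); m_hi <- if (length(hi)) mean(hi) else m_lo
  if (!is.finite(m_hi) || m_hi < 4 * max(m_lo, 1e-12)) {
    # No bimodal texture split. Either the frame is all cell monolayer
    # (empty wound) or it has no correlated texture at all (degenerate).
    if (lag1_autocor(px) < 0.2)
      stop("degenerate appearance: cannot split (no cell texture)")
    return(structure(list(wound = empty, threshold = NA_real_,
                          diagnostics = list(n_components = 0L,
                                             areas = integer(0))),
                     class = "region_mask"))
  }
  thr <- (m_lo + m_hi) / 2
  raw <- v < thr

  brush <- EBImage::makeBrush(2L * as.integer(morph_radius) + 1L, "disc")
  clean <- EBImage::closing(EBImage::opening(raw * 1, brush), brush)
  lab <- EBImage::bwlabel(clean)
  n_comp <- max(lab)
  if (n_comp == 0L)
    return(structure(list(wound = empty, threshold = thr,
                          diagnostics = list(n_components = 0L,
                                             areas = integer(0))),
                     class = "region_mask"))
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  largest <- which.max(areas)
  if (areas[largest] < min_wound_area_frac * length(px))
    return(structure(list(wound = empty, threshold = thr,
                          diagnostics = list(n_components = n_comp,
                                             areas = areas)),
                     class = "region_mask"))
  wound <- EBImage::fillHull((lab == largest) * 1) > 0
  structure(list(wound = wound, threshold = thr,
                 diagnostics = list(n_components = n_comp, areas = areas)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d, wound area %d px (%.1f%%)\n",
              nrow(x$wound), ncol(x$wound), sum(x$wound),
              100 * mean(x$wound)))
  invisible(x)
}

# Accept a region_mask or a bare logical matrix.
as_wound_mask <- function(mask) {
  if (inherits(mask, "region_mask")) return(mask$wound)
  if (is.matrix(mask) && (is.logical(mask) || all(mask %in% c(0, 1))))
    return(mask > 0)
  stop("mask must be a region_mask or a binary matrix")
}
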