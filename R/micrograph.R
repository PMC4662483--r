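#' Construct a micrograph object
#'
#' A micrograph is a 2D grayscale intensity image with an optional physical
#' scale and assay metadata. Pixel intensities are normalised to `[0, 1]`.
#'
#' @param pixels Numeric matrix of intensities, `[row, col]`. Integer input
#'   (8- or 16-bit) is rescaled to `[0, 1]` by its nominal bit depth.
#' @param scale Optional physical scale in micrometres per pixel (`> 0`).
#' @param condition Optional condition label (e.g. `"treated"`, `"control"`).
#' @param timepoint Optional timepoint label (e.g. `"t0"`, `"t24"`).
#' @return An object of class `micrograph`: a list with elements `pixels`,
#'   `scale`, `condition`, `timepoint`.
#' @examples
#' m <- micrograph(matrix(runif(64 * 80), 64, 80))
#' dim(m$pixels)
#' @export
micrograph <- function(pixels, scale = NULL, condition = NA_character_,
                       timepoint = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("pixel intensities must be finite")
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop("image too small: height and width must both be >= 64 px ",
         "(texture windows undefined below that)")
  if (is.integer(pixels) || max(pixels) > 1 + 1e-9) {
    depth <- if (max(pixels) > 255) 65535 else 255
    pixels <- pixels / depth
  }
  storage.mode(pixels) <- "double"
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
        scale <= 0)
      stop("scale must be a single positive number (um per pixel)")
  }
  structure(list(pixels = pixels, scale = scale,
                 condition = as.character(condition),
                 timepoint = as.character(timepoint)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px", nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$scale)) cat(sprintf(", %.4g um/px", x$scale))
  if (!is.na(x$condition)) cat(", condition:", x$condition)
  if (!is.na(x$timepoint)) cat(", timepoint:", x$timepoint)
  cat("\n")
  invisible(x)
}

# Accept a micrograph or a bare matrix anywhere an image is expected.
as_micrograph <- function(img) {
  if (inherits(img, "micrograph")) img else micrograph(img)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' 8- and 16-bit grayscale images are read and normalised to `[0, 1]`. RGB
#' input is accepted and converted to luminance (Rec. 601 weights) with a
#' warning.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams micrograph
#' @return A [micrograph] object.
#' @export
read_micrograph <- function(path, scale = NULL, condition = NA_character_,
                            timepoint = NA_character_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (TIFF or PNG expected): ",
         path))
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    warning("RGB(A) image converted to grayscale by luminance: ", path)
    if (nch >= 3L) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  micrograph(px, scale = scale, condition = condition, timepoint = timepoint)
}

#' Write a micrograph to disk
#'
#' TIFF output is written as 16-bit grayscale; PNG as 16-bit where supported.
#'
#' @param img A [micrograph] or numeric matrix in `[0, 1]`.
#' @param path Output path; format chosen from the extension (`.tif`/`.tiff`
#'   or `.png`).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  px <- as_micrograph(img)$pixels
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop("unsupported output format '.", ext, "'"))
  invisible(path)
}
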