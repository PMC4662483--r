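# Shared fixtures are generated in code; no image files ship with the tests.

iou <- function(a, b) sum(a & b) / sum(a | b)

# A small, fast default spec for unit tests (acceptance checks use the
# full-size generator defaults).
small_spec <- function(...) {
  args <- modifyList(list(height = 256L, width = 320L, wound_width = 60,
                          seed = 7L), list(...))
  do.call(scratch_spec, args)
}

# Rectangular wound mask: full-height band over the given columns.
rect_mask <- function(h, w, cols) {
  m <- matrix(FALSE, h, w)
  m[, cols] <- TRUE
  m
}

# 90-degree counterclockwise rotation of a matrix image.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Bilinear rotation of an image about its center by `deg` degrees, cropped
# to a centered window so no out-of-frame padding enters the result.
rotate_crop <- function(px, deg, crop_h, crop_w) {
  h <- nrow(px); w <- ncol(px)
  th <- deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  rows <- (1:crop_h) - (crop_h + 1) / 2
  cols <- (1:crop_w) - (crop_w + 1) / 2
  rg <- matrix(rows, crop_h, crop_w)
  cg <- matrix(cols, crop_h, crop_w, byrow = TRUE)
  src_r <- cr + cos(th) * rg - sin(th) * cg
  src_c <- cc + sin(th) * rg + cos(th) * cg
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  stopifnot(all(r0 >= 1), all(r0 < h), all(c0 >= 1), all(c0 < w))
  idx <- function(r, c) px[cbind(as.vector(r), as.vector(c))]
  out <- (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c0 + 1) +
    fr * (1 - fc) * idx(r0 + 1, c0) + fr * fc * idx(r0 + 1, c0 + 1)
  matrix(out, crop_h, crop_w)
}
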