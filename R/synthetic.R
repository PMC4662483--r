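#' Specify a synthetic scratch-assay image
#'
#' Describes a phase-contrast-like scratch image: a granular, high-texture
#' cell monolayer crossed by a smooth, low-texture wound band of known width,
#' orientation and position. The generator produces the image together with
#' its exact analytic ground truth, so every downstream measurement stage can
#' be validated without a real micrograph.
#'
#' @param height,width Image dimensions in pixels (each `>= 64`).
#' @param wound_width Wound band width in pixels (`>= 0`; `0` gives a fully
#'   closed, all-cell image).
#' @param angle Wound main-axis orientation in degrees from vertical
#'   (the row axis), in `[-90, 90)`. `0` means the scratch runs along rows.
#' @param center_offset Signed offset of the band centerline from the image
#'   center, in pixels, measured perpendicular to the wound axis.
#' @param profile Width profile along the axis: `"constant"` or
#'   `"linear_taper"` (from `wound_width` at the axial start of the frame to
#'   `end_width` at its end).
#' @param end_width End width in pixels for `profile = "linear_taper"`.
#' @param texture_contrast Cell-region texture amplitude (intensity units on
#'   the `[0, 1]` scale, `>= 0`).
#' @param noise_sigma Additive Gaussian noise standard deviation (intensity
#'   units, `>= 0`), applied to the whole frame.
#' @param seed Integer seed; one seed drives one pseudo-random stream and
#'   makes generation bit-reproducible.
#' @return An object of class `scratch_spec` (a validated list).
#' @seealso [generate_scratch_image()], [generate_timecourse_pair()]
#' @export
scratch_spec <- function(height = 600L, width = 800L, wound_width = 150,
                         angle = 0, center_offset = 0,
                         profile = c("constant", "linear_taper"),
                         end_width = NULL, texture_contrast = 0.2,
                         noise_sigma = 0.01, seed = 1L) {
  profile <- match.arg(profile)
  if (!is.numeric(height) || !is.numeric(width) ||
      height < 64 || width < 64)
    stop("image dimensions must be >= 64 px")
  if (wound_width < 0) stop("wound_width must be >= 0")
  if (angle < -90 || angle >= 90)
    stop("angle must lie in [-90, 90) degrees from vertical")
  if (texture_contrast < 0) stop("texture_contrast must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (profile == "linear_taper") {
    if (is.null(end_width) || end_width < 0)
      stop("linear_taper requires end_width >= 0")
  } else {
    end_width <- wound_width
  }
  spec <- structure(list(
    height = as.integer(height), width = as.integer(width),
    wound_width = as.numeric(wound_width), angle = as.numeric(angle),
    center_offset = as.numeric(center_offset), profile = profile,
    end_width = as.numeric(end_width),
    texture_contrast = as.numeric(texture_contrast),
    noise_sigma = as.numeric(noise_sigma), seed = as.integer(seed)
  ), class = "scratch_spec")
  check_band_fit(spec)
  spec
}

# Axial/perpendicular frame of the band. angle measured from the row axis
# (vertical in image terms); d is the unit axis direction, n its normal.
band_frame <- function(spec) {
  th <- spec$angle * pi / 180
  list(d = c(cos(th), sin(th)), n = c(-sin(th), cos(th)),
       center = c((spec$height + 1) / 2,
                  (spec$width + 1) / 2) + spec$center_offset * c(-sin(th),
                                                                 cos(th)))
}

# Corner projections onto the band normal; the band fits iff cell tissue
# remains on both sides of it within the frame.
check_band_fit <- function(spec) {
  if (spec$wound_width == 0 && spec$end_width == 0) return(invisible(TRUE))
  fr <- band_frame(spec)
  corners <- rbind(c(1, 1), c(1, spec$width),
                   c(spec$height, 1), c(spec$height, spec$width))
  offs <- (corners[, 1] - fr$center[1]) * fr$n[1] +
          (corners[, 2] - fr$center[2]) * fr$n[2]
  half <- max(spec$wound_width, spec$end_width) / 2
  margin <- 2
  if (min(offs) > -(half + margin) || max(offs) < half + margin)
    stop("wound band does not fit inside the image for this geometry")
  invisible(TRUE)
}

# True band half-width as a function of axial position s (s measured from the
# projection of the band center, in pixels). For the taper, the width ramps
# linearly across the axial span of the frame.
band_width_fun <- function(spec) {
  if (spec$profile == "constant") {
    w <- spec$wound_width
    function(s) rep(w, length(s))
  } else {
    fr <- band_frame(spec)
    corners <- rbind(c(1, 1), c(1, spec$width),
                     c(spec$height, 1), c(spec$height, spec$width))
    sp <- (corners[, 1] - fr$center[1]) * fr$d[1] +
          (corners[, 2] - fr$center[2]) * fr$d[2]
    s0 <- min(sp); s1 <- max(sp)
    w0 <- spec$wound_width; w1 <- spec$end_width
    function(s) {
      f <- pmin(pmax((s - s0) / (s1 - s0), 0), 1)
      w0 + (w1 - w0) * f
    }
  }
}

# Deterministic texture fields for a spec: blob-plus-speckle granulation.
# Blobs are Gaussian-filtered white noise thresholded into cell-like
# granules; speckle is an iid floor that keeps local variance spatially
# homogeneous. All three fields come from one seeded stream.
texture_fields <- function(spec) {
  h <- spec$height; w <- spec$width
  withr::with_seed(spec$seed, {
    raw <- matrix(rnorm(h * w), h, w)
    speckle <- matrix(rnorm(h * w), h, w)
    noise <- matrix(rnorm(h * w), h, w)
  })
  gs <- EBImage::gblur(raw, sigma = 2)
  gs <- (gs - mean(gs)) / sd(gs)
  blobs <- (gs > 0.3) * 1
  blobs <- (blobs - mean(blobs)) / max(sd(blobs), 1e-12)
  tex <- 0.45 * blobs + 0.55 * speckle
  list(tex = tex, noise = noise)
}

#' Generate a synthetic scratch image with ground truth
#'
#' Renders a high-texture cell monolayer (granule blobs over a speckle floor,
#' amplitude `texture_contrast`) with a smooth wound band, plus additive
#' Gaussian noise. Identical specs (including `seed`) give bit-identical
#' output. The ground-truth wound mask is exactly the set of pixels whose
#' centers lie strictly inside the analytic band.
#'
#' @param spec A [scratch_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{A [micrograph].}
#'     \item{truth}{A list: `wound_mask` (logical matrix), `axis_angle`
#'       (degrees from vertical), `width_at(s)` (true band width at axial
#'       position `s`, pixels, `s` measured from the band-center projection),
#'       and the generating `spec`.}
#'   }
#' @examples
#' out <- generate_scratch_image(scratch_spec(128, 160, wound_width = 40,
#'                                            seed = 7))
#' mean(out$truth$wound_mask)
#' @export
generate_scratch_image <- function(spec) {
  stopifnot(inherits(spec, "scratch_spec"))
  check_band_fit(spec)
  fr <- band_frame(spec)
  h <- spec$height; w <- spec$width
  rr <- matrix(seq_len(h), h, w) - fr$center[1]
  cc <- matrix(rep(seq_len(w), each = h), h, w) - fr$center[2]
  s <- rr * fr$d[1] + cc * fr$d[2]
  t_off <- rr * fr$n[1] + cc * fr$n[2]
  wfun <- band_width_fun(spec)
  wound <- abs(t_off) < wfun(s) / 2

  fields <- texture_fields(spec)
  base <- 0.45
  img <- base + (!wound) * (spec$texture_contrast * fields$tex) +
    spec$noise_sigma * fields$noise
  img <- pmin(pmax(img, 0), 1)

  truth <- list(wound_mask = wound, axis_angle = spec$angle,
                width_at = wfun, spec = spec)
  list(image = micrograph(img), truth = truth)
}

#' Generate a t0/t1 timecourse pair with known closure
#'
#' Produces two images sharing one texture and noise realisation (same seed
#' stream), differing only in the wound band: the second image's width is
#' reduced by `closure_px`, emulating gap closure between the two imaging
#' timepoints of a scratch assay.
#'
#' @param spec_t0 A [scratch_spec()] for the initial image.
#' @param closure_px Closure in pixels, `0 <= closure_px <= wound_width`.
#'   For a tapered band both end widths shrink by `closure_px` (floored at
#'   0).
#' @return A list with elements `t0` and `t1`, each as returned by
#'   [generate_scratch_image()].
#' @export
generate_timecourse_pair <- function(spec_t0, closure_px) {
  stopifnot(inherits(spec_t0, "scratch_spec"))
  if (closure_px < 0) stop("closure_px must be >= 0")
  if (closure_px > spec_t0$wound_width)
    stop("closure_px exceeds the initial wound width")
  spec_t1 <- spec_t0
  spec_t1$wound_width <- max(spec_t0$wound_width - closure_px, 0)
  spec_t1$end_width <- max(spec_t0$end_width - closure_px, 0)
  list(t0 = generate_scratch_image(spec_t0),
       t1 = generate_scratch_image(spec_t1))
}

#' Write a synthetic image with its ground truth to disk
#'
#' Writes the image as 16-bit grayscale TIFF, the ground-truth wound mask as
#' an 8-bit TIFF, and a JSON sidecar with the generating parameters.
#'
#' @param sim Output of [generate_scratch_image()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; writes `<stem>.tif`, `<stem>_mask.tif`,
#'   `<stem>.json`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(sim, dir, stem = "scratch") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(stem, ".tif"))
  mask_path <- file.path(dir, paste0(stem, "_mask.tif"))
  json_path <- file.path(dir, paste0(stem, ".json"))
  write_micrograph(sim$image, img_path)
  tiff::writeTIFF(sim$truth$wound_mask * 1, mask_path, bits.per.sample = 8L)
  spec <- sim$truth$spec
  jsonlite::write_json(
    list(axis_angle = spec$angle, wound_width = spec$wound_width,
         width_profile = spec$profile, end_width = spec$end_width,
         center_offset = spec$center_offset, height = spec$height,
         width = spec$width, texture_contrast = spec$texture_contrast,
         noise_sigma = spec$noise_sigma, seed = spec$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = mask_path, sidecar = json_path))
}
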