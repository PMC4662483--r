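---
title: "Measuring scratch-assay migration with woundquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring scratch-assay migration with woundquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundquant)
```

## The assay and the measurement problem

In a wound-healing (scratch) assay a confluent cell monolayer is mechanically
scratched with a pipette tip and the denuded gap is imaged by phase-contrast
microscopy at two or more timepoints, typically 0 h and 24 h. The biological
readout is how fast cells migrate back into the gap. Under phase contrast the
monolayer appears granular — cells produce strong local intensity variation —
while the cell-free scratch is nearly smooth. woundquant turns that appearance
difference into a measurement in three steps:

1. **Segmentation.** The image is split into cell and wounded areas from a
   local-texture map.
2. **Contour extraction.** The boundary between the compacted cell layer and
   the wound is traced at subpixel precision and split into the two sides of
   the gap.
3. **Width measurement.** N lines (default 5), equally spaced along the wound
   and perpendicular to its main axis, are intersected with the two contours;
   the gap width is the distance between the intersections, and the per-image
   summary is the mean over lines.

On top of the imaging pipeline the package provides the assay arithmetic:
the relative migration distance
$100\,(A-B)/(a-b)$, where $A$/$B$ are the treated wound widths before/after
incubation and $a$/$b$ the matched control widths; the caliper tumour volume
$V = L W^2/2$; and normalisation of any readout to its control,
$100\,x/x_{\mathrm{ctrl}}$. The printed migration formula is evaluated with
the denominator grouped, $(A-B)/(a-b)$: the alternative literal reading
$100(A-B)/a - b$ mixes a percentage with a length and contradicts the
definition of the quantity as closure relative to control.

## Segmentation model

The texture statistic is the moving-window variance of intensity (window
default 15 px, odd). Windowed variance is, to first order, linear in the
fraction of the window covered by textured cells: across a straight
cell/wound boundary it falls from $\sigma^2_{\mathrm{cell}} +
\sigma^2_{\mathrm{noise}}$ to $\sigma^2_{\mathrm{noise}}$ along a ramp one
window wide, crossing the *midpoint of the two levels exactly at the
boundary*. The implementation exploits this: an initial Otsu split of the
variance map identifies the two populations, and the working threshold is
then refined to the midpoint of the two class means. Thresholding at the
Otsu value directly would bias the boundary up to several pixels into the
wound (the criterion optimises class separation, not boundary position); the
midpoint refinement removes that bias independently of the noise level,
which is why the same procedure holds for noiseless and noisy images.

Cleanup is standard mathematical morphology: opening then closing with a
disk of radius 5 px, retention of the largest connected low-texture
component (a scratch assay has one wound; smaller components are kept in the
diagnostics), and hole filling. The cell region is defined as the exact
complement, so the split is always a partition.

Three outcomes are distinguished deliberately:

* a **wound** — a low-texture component covering at least
  `min_wound_area_frac` (default 2%) of the frame;
* an **empty wound** (fully closed monolayer) — no such component, but the
  frame shows correlated cell texture. This is a valid measurement of width
  0, not an error;
* a **degenerate image** — no bimodal variance split *and* no correlated
  texture (a constant frame, or smooth background whose only variation is
  white sensor noise; lag-1 spatial autocorrelation below 0.2). Here the
  cell/wound split is undefined and the package raises an error rather than
  returning an arbitrary partition.

Otsu's threshold is computed on a 256-bin histogram with ties in the
between-class variance criterion broken toward the lowest candidate
threshold, making the result deterministic on multimodal histograms.

## Geometry: axis, contours, measurement lines

The wound **main axis** is the principal eigenvector of the second central
moments of the wound pixel coordinates — parameter-free and exact for a
straight band. If the two principal moments differ by less than 5% the
region is effectively isotropic, no main axis exists, and the package
errors instead of measuring along an arbitrary direction.

**Contours** are extracted as the 0.5 level set of the binary mask with
linear interpolation (so a straight boundary between pixel columns $c$ and
$c+1$ sits at $c + 0.5$; pixel centers are at integer 1-based (row, col)
coordinates and a pixel occupies the half-open square $[r-0.5, r+0.5)
\times [c-0.5, c+0.5)$). Points are assigned to the two sides of the gap by
the sign of their perpendicular offset from the axis and ordered by axial
projection; points with equal projection are merged by averaging so each
side is strictly monotone and can be intersected with a perpendicular line
by interpolation in the projection coordinate.

**Measurement lines.** N is user-defined (default 5, the assay's usual
choice); placement is automatic at the interior fractions $k/(N+1)$ of the
axial extent, which spaces the lines equally while keeping them off the
wound's axial tips. Explicit positions may be supplied instead
(`quantify_image(..., positions = )`), covering workflows where lines are
chosen manually per image. A position at which a contour side is absent is
reported as width 0 with a `flag_closed` marker — a closed gap is a zero
width, not missing data — and enters the mean.

One placement detail matters for oblique wounds: near the frame corners of
a tilted band one boundary leaves the image before the other, so the gap
there is *censored by the frame*, not closed by cells. `quantify_image()`
therefore clips the line-placement extent to the axial span on which both
contours are present before applying the $k/(N+1)$ rule. Without the clip,
end lines on strongly tilted wounds would report spurious zero widths and
drag the per-image mean far from the true width.

Widths convert to physical units exactly as `width_um = width_px * scale`
when a µm-per-pixel scale is known; without a scale the µm columns are
absent (`NA`), never 0.

## The synthetic generator as ground truth

No public scratch-assay images with exact ground truth exist, so validation
uses a generator whose geometry is analytic: a straight wound band of known
width, orientation (degrees from vertical, i.e. from the row axis), and
perpendicular offset, with an optional linear taper; the ground-truth mask
is exactly the set of pixels whose centers lie strictly inside the band,
and the true width is available at any axial position. Cell texture is
blob-plus-speckle granulation: Gaussian-filtered white noise (sigma 2 px)
thresholded into cell-scale granules (45% weight) over an iid speckle floor
(55% weight), scaled by `texture_contrast` and laid over a uniform
background; the speckle-heavy mix keeps the windowed variance of the cell
region spatially homogeneous, which is what the real compacted monolayer
looks like to the texture statistic. Additive Gaussian noise covers the
whole frame. One integer seed drives a single documented stream, so equal
specs give bit-identical images; a timecourse pair reuses the same fields
and differs only in the band, emulating the same field of view photographed
at 0 h and 24 h.

Defaults — 600 × 800 px frames, intensities on a normalised [0, 1] scale
written as 16-bit TIFF, background level 0.45, `texture_contrast` 0.2,
`noise_sigma` 0.01 — are the package's own choices of a realistic regime
(no resolution, magnification or bit depth is standard for this assay), and
the validation suite states them explicitly rather than treating them as
universal.

What the generator does **not** emulate: curved or branched scratches,
illumination gradients, phase-contrast halo artifacts, debris in the gap,
and cell-scale migration dynamics (closure is a rigid narrowing of the
band). Passing the synthetic suite therefore demonstrates that the
geometry and measurement chain are correct and unbiased on straight-band
images with texture/smooth contrast; it does not certify performance on
pathological real-world images, which should be spot-checked with the QC
overlays (`overlay: true` in the batch config).

## Validation and problem sizes

The test suite regenerates everything it measures:

* width recovery over 20 seeded 600 × 800 images per noise level (widths
  uniform in [40, 200] px, angles uniform in [−45°, 45°]): mean absolute
  error of the per-image mean width ≤ 2 px at default noise and ≤ 1 px
  noiseless (measured ≈ 0.6–0.7 px for both);
* segmentation IoU against the analytic mask ≥ 0.95 noiseless and ≥ 0.90 at
  default noise (measured ≈ 0.98);
* rotation checks: a 90° rotation changes the mean width by < 1%, a
  bilinearly resampled 15° rotation by < 2%;
* strict monotonicity of measured width in imposed closure, with full
  closure measuring exactly 0;
* byte-identical batch CSVs on re-run, and exact (1e−9) agreement of the
  assay formulas with hand-computed values.

`scripts/acceptance.R` re-runs the same computations end-to-end from a
command-line seed and writes the resulting numbers as JSON.

## Numerical choices and edge cases

* Variance map: box filtering with replicate borders; values clamped at 0
  against floating-point cancellation.
* Otsu tie-break: lowest maximising threshold (deterministic).
* Boundary convention: mask pixels own half-open squares, so contour
  coordinates are exact half-integers on straight edges; measured widths of
  a w-pixel rectangular band are exactly w.
* Degenerate control (a = b) in the migration formula is an error, never
  ±Inf or 0; widened wounds (negative closures) return a value with a
  warning so sign semantics stay visible.
* Wounds may touch the two frame borders along their axis (a scratch
  usually spans the frame); only a boundary that cannot be split into two
  nonempty sides is an error.
* Isotropy (5% moment gap) and autocorrelation (0.2) cutoffs are guards
  against undefined geometry, not tuning parameters; results are insensitive
  to them away from the degenerate cases they detect.

## Limitations

Single straight wound per image; pairwise timepoints (no trajectory
modelling); no fluorescence support; the texture statistic assumes the
wound interior is markedly smoother than the monolayer, so heavy debris in
the gap will bias the wound area low. Replicate-level statistics
(e.g. t-tests across wells) are intentionally out of scope: the package
reports per-pair values and leaves aggregation to the analyst.
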