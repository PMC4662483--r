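test_that("measurement lines are placed at interior equal fractions", {
  expect_equal(place_measurement_lines(c(0, 600), 5),
               c(100, 200, 300, 400, 500))
  expect_equal(place_measurement_lines(c(0, 600), 1), 300)
  expect_error(place_measurement_lines(c(0, 600), 0), "n_lines")
  # exact arithmetic spacing for arbitrary extents
  for (ext in list(c(-321.5, 488.25), c(3, 5))) {
    for (n in c(2L, 5L, 9L)) {
      p <- place_measurement_lines(ext, n)
      expect_length(p, n)
      gaps <- diff(c(ext[1], p, ext[2]))
      expect_equal(max(gaps) - min(gaps), 0, tolerance = 1e-12)
      expect_true(all(p > ext[1] & p < ext[2]))
    }
  }
})

test_that("a constant-width rectangular wound measures its exact width", {
  mask <- rect_mask(300, 400, 101:200)
  axis <- estimate_axis(mask)
  ct <- extract_contours(mask, axis)
  pos <- place_measurement_lines(axis, 5)
  wp <- measure_widths(ct, axis, pos)
  expect_s3_class(wp, "width_profile")
  expect_equal(wp$lines$width_px, rep(100, 5), tolerance = 1e-9)
  expect_equal(wp$mean_width_px, 100, tolerance = 1e-9)
  expect_equal(wp$mean_width_px, mean(wp$lines$width_px), tolerance = 1e-12)
  # endpoints lie on the perpendicular through each position
  st_a <- woundquant:::axis_coords(as.matrix(wp$lines[, c("a_row", "a_col")]),
                                   axis)
  st_b <- woundquant:::axis_coords(as.matrix(wp$lines[, c("b_row", "b_col")]),
                                   axis)
  expect_lt(max(abs(st_a[, "s"] - pos)), 0.5)
  expect_lt(max(abs(st_b[, "s"] - pos)), 0.5)
})

test_that("a linear taper measures its analytic width at the midpoint", {
  sp <- scratch_spec(600, 800, wound_width = 50, profile = "linear_taper",
                     end_width = 150, noise_sigma = 0, seed = 17L)
  sim <- generate_scratch_image(sp)
  mask <- sim$truth$wound_mask
  axis <- estimate_axis(mask)
  ct <- extract_contours(mask, axis)
  # the frame's axial midpoint in centroid-relative coordinates; the taper
  # crosses (50 + 150) / 2 = 100 px exactly there
  s_mid <- sum((c((600 + 1) / 2, (800 + 1) / 2) - axis$centroid) *
               axis$direction)
  wp <- measure_widths(ct, axis, s_mid)
  expect_equal(wp$lines$width_px, 100, tolerance = 1)
})

test_that("positions outside a side's span are flagged closed, not dropped", {
  mask <- rect_mask(300, 400, 101:200)
  mask[1:49, ] <- FALSE
  mask[251:300, ] <- FALSE
  axis <- estimate_axis(mask)
  ct <- extract_contours(mask, axis)
  wp <- measure_widths(ct, axis, c(0, 140))
  expect_equal(nrow(wp$lines), 2L)
  expect_false(wp$lines$flag_closed[1])
  expect_true(wp$lines$flag_closed[2])
  expect_equal(wp$lines$width_px[2], 0)
  expect_equal(wp$mean_width_px, mean(wp$lines$width_px))
})

test_that("physical units scale exactly and are absent without a scale", {
  mask <- rect_mask(300, 400, 101:200)
  axis <- estimate_axis(mask)
  ct <- extract_contours(mask, axis)
  pos <- place_measurement_lines(axis, 5)
  wp_px <- measure_widths(ct, axis, pos)
  expect_true(all(is.na(wp_px$lines$width_um)))
  expect_true(is.na(wp_px$mean_width_um))
  wp_um <- measure_widths(ct, axis, pos, scale = 1.3)
  expect_identical(wp_um$lines$width_um, wp_um$lines$width_px * 1.3)
  expect_identical(wp_um$mean_width_um, wp_um$mean_width_px * 1.3)
})

test_that("the full pipeline recovers synthetic wound widths", {
  sp <- scratch_spec(wound_width = 100, noise_sigma = 0, seed = 23L)
  wp <- quantify_image(generate_scratch_image(sp)$image)
  expect_equal(wp$mean_width_px, 100, tolerance = 1 / 100)
  expect_equal(wp$n_lines, 5L)
})

test_that("a fully closed image quantifies to zero width, all lines flagged", {
  sim <- generate_scratch_image(small_spec(wound_width = 0))
  wp <- quantify_image(sim$image)
  expect_equal(wp$mean_width_px, 0)
  expect_true(all(wp$lines$flag_closed))
  expect_equal(nrow(wp$lines), 5L)
})

test_that("width estimates are invariant under 90-degree rotation", {
  sim <- generate_scratch_image(small_spec(seed = 12L, angle = 10,
                                           wound_width = 70))
  w1 <- quantify_image(sim$image)$mean_width_px
  w2 <- quantify_image(rot90(sim$image$pixels))$mean_width_px
  expect_lt(abs(w1 - w2) / w1, 0.01)
})

test_that("width estimates survive arbitrary-angle resampling", {
  sim <- generate_scratch_image(scratch_spec(wound_width = 90, seed = 33L))
  w1 <- quantify_image(sim$image)$mean_width_px
  rot <- rotate_crop(sim$image$pixels, 15, 380, 380)
  w2 <- quantify_image(rot)$mean_width_px
  expect_lt(abs(w1 - w2) / w1, 0.02)
})

test_that("measured widths decrease monotonically with closure", {
  sp <- scratch_spec(wound_width = 120, seed = 3L)
  widths <- sapply(c(0, 20, 40, 80), function(cl) {
    pair <- generate_timecourse_pair(sp, cl)
    quantify_image(pair$t1$image)$mean_width_px
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1], 120, tolerance = 2 / 120)
  expect_equal(widths[3], 80, tolerance = 2 / 80)
})
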