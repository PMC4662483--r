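test_that("relative migration matches hand-computed values", {
  # treated closed 300 px vs control 200 px
  expect_equal(relative_migration(A = 500, B = 200, a = 500, b = 300), 150,
               tolerance = 1e-9)
  # equal closure is exactly 100%
  expect_identical(relative_migration(A = 480, B = 260, a = 410, b = 190),
                   100)
  # treated did not close at all
  expect_equal(relative_migration(A = 300, B = 300, a = 400, b = 250), 0,
               tolerance = 1e-9)
})

test_that("degenerate migration inputs raise the specified errors", {
  expect_error(relative_migration(500, 200, 400, 400), "a == b")
  expect_error(relative_migration(-1, 0, 400, 300), ">= 0")
  expect_error(relative_migration(NA, 0, 400, 300), "finite")
  expect_warning(relative_migration(200, 260, 400, 300), "widened")
  # both wounds widened: a value (ratio of widenings) with warnings, not an
  # error
  warns <- capture_warnings(val <- relative_migration(200, 260, 300, 340))
  expect_true(any(grepl("both wounds widened", warns)))
  expect_equal(val, 100 * (-60) / (-40), tolerance = 1e-12)
})

test_that("relative migration is monotone in the treated widths", {
  As <- seq(100, 500, by = 50)
  for (B in c(50, 90)) {
    vals <- sapply(As, relative_migration, B = B, a = 400, b = 100)
    expect_true(all(diff(vals) > 0))
  }
  Bs <- seq(10, 300, by = 29)
  vals <- sapply(Bs, function(B) relative_migration(400, B, 400, 100))
  expect_true(all(diff(vals) < 0))
})

test_that("relative migration is unit-independent", {
  for (k in c(0.5, 1.3, 65535)) {
    expect_equal(relative_migration(500 * k, 200 * k, 500 * k, 300 * k),
                 relative_migration(500, 200, 500, 300),
                 tolerance = 1e-12)
  }
})

test_that("caliper tumour volume matches the ellipsoid formula", {
  expect_equal(tumour_volume(4, 3), 18, tolerance = 1e-9)
  expect_equal(tumour_volume(2, 2), 4, tolerance = 1e-9)
  expect_error(tumour_volume(0, 3), "positive")
  expect_error(tumour_volume(4, -1), "positive")
})

test_that("tumour volume is linear in length, quadratic in width", {
  L <- seq(1, 10, by = 1); W <- seq(0.5, 5, by = 0.5)
  vL <- sapply(L, tumour_volume, W = 3)
  vW <- sapply(W, function(w) tumour_volume(4, w))
  expect_true(all(diff(vL) > 0))
  expect_true(all(diff(vW) > 0))
  # second finite differences: zero in L, constant positive in W
  expect_equal(diff(diff(vL)), rep(0, length(L) - 2), tolerance = 1e-12)
  d2w <- diff(diff(vW))
  expect_equal(d2w, rep(d2w[1], length(d2w)), tolerance = 1e-12)
  expect_gt(d2w[1], 0)
})

test_that("normalisation to control is exact and round-trips", {
  expect_equal(normalize_to_control(30, 60), 50, tolerance = 1e-9)
  expect_equal(normalize_to_control(0.37, 0.37), 100, tolerance = 1e-9)
  expect_error(normalize_to_control(30, 0), "> 0")
  expect_error(normalize_to_control(-5, 60), ">= 0")
  set.seed(2)
  for (i in 1:20) {
    x <- runif(1, 0, 50); ctl <- runif(1, 1e-3, 50)
    expect_equal(normalize_to_control(x, ctl) * ctl / 100, x,
                 tolerance = 1e-12)
  }
})

test_that("migration_result wires measured width profiles into the formula", {
  mk <- function(widths) {
    structure(list(lines = data.frame(width_px = widths),
                   mean_width_px = mean(widths), n_lines = length(widths)),
              class = "width_profile")
  }
  res <- migration_result(mk(c(500, 500)), mk(c(200, 200)),
                          mk(c(500, 500)), mk(c(300, 300)))
  expect_equal(res$relative_migration_pct, 150, tolerance = 1e-9)
  expect_equal(res$closure_treated, 300)
  expect_equal(res$closure_control, 200)
})
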