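#' Relative migration distance
#'
#' The treated condition's gap closure expressed as a percentage of the
#' control condition's closure over the same interval:
#' `100 * (A - B) / (a - b)`, where `A`/`B` are the treated wound widths
#' before/after incubation and `a`/`b` the control widths. All four widths
#' must share one unit (px or um); the percentage is invariant to a common
#' rescaling.
#'
#' @param A Treated width before incubation (`>= 0`).
#' @param B Treated width after incubation (`>= 0`).
#' @param a Control width before incubation (`>= 0`).
#' @param b Control width after incubation (`>= 0`).
#' @return The relative migration distance in percent.
#' @details `a == b` (the control did not move) leaves the quantity
#'   undefined and raises an error, never infinity or 0. A widened wound
#'   (`B > A` or `b > a`) is allowed with a warning; if both closures are
#'   negative the ratio of the two widenings is returned, also with a
#'   warning, so the sign semantics stay explicit.
#' @examples
#' relative_migration(A = 500, B = 200, a = 500, b = 300)  # 150
#' @export
relative_migration <- function(A, B, a, b) {
  vals <- c(A = A, B = B, a = a, b = b)
  if (!all(is.finite(vals))) stop("widths must be finite numbers")
  if (any(vals < 0)) stop("widths must be >= 0")
  if (a == b)
    stop("control closure is zero (a == b): relative migration undefined")
  if (B > A)
    warning("treated wound widened (B > A)")
  if (b > a)
    warning("control wound widened (b > a)")
  if (A - B < 0 && a - b < 0)
    warning("both wounds widened; returning the ratio of widenings")
  100 * (A - B) / (a - b)
}

#' Build a migration result from two measured width profiles per condition
#'
#' Convenience wrapper taking the per-image mean widths of a
#' treated/control, before/after quadruple of [quantify_image()] profiles
#' and applying [relative_migration()].
#'
#' @param treated_t0,treated_t1,control_t0,control_t1 `width_profile`
#'   objects (or plain numbers) for the four images.
#' @return A list of class `migration_result` with the four widths `A`,
#'   `B`, `a`, `b`, the two closures, and `relative_migration_pct`.
#' @export
migration_result <- function(treated_t0, treated_t1, control_t0,
                             control_t1) {
  mw <- function(x) if (inherits(x, "width_profile")) x$mean_width_px else
    as.numeric(x)
  A <- mw(treated_t0); B <- mw(treated_t1)
  a <- mw(control_t0); b <- mw(control_t1)
  structure(list(A = A, B = B, a = a, b = b,
                 closure_treated = A - B, closure_control = a - b,
                 relative_migration_pct = relative_migration(A, B, a, b)),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf(
    "<migration_result> treated %.1f -> %.1f, control %.1f -> %.1f: %.1f%% of control closure\n",
    x$A, x$B, x$a, x$b, x$relative_migration_pct))
  invisible(x)
}

#' Caliper tumour volume
#'
#' Volume of a subcutaneous/orthotopic tumour estimated from external
#' caliper measurements by the standard ellipsoid approximation
#' `V = L * W^2 / 2`.
#'
#' @param L Tumour length in mm (`> 0`; the longer dimension).
#' @param W Tumour width in mm (`> 0`).
#' @return Volume in mm^3.
#' @examples
#' tumour_volume(4, 3)  # 18
#' @export
tumour_volume <- function(L, W) {
  if (!is.finite(L) || !is.finite(W) || L <= 0 || W <= 0)
    stop("tumour dimensions must be positive")
  L * W^2 / 2
}

#' Normalise a measurement to its control
#'
#' Expresses a treated measurement as a percentage of the matched control:
#' `100 * value / control`. Used e.g. for invasion (% of cell invasion
#' normalised to the control condition), biomass or proliferation readouts.
#'
#' @param value Treated measurement (`>= 0`).
#' @param control Control measurement (`> 0`).
#' @return Percent of control.
#' @examples
#' normalize_to_control(30, 60)  # 50
#' @export
normalize_to_control <- function(value, control) {
  if (!is.finite(value) || value < 0) stop("value must be >= 0")
  if (!is.finite(control) || control <= 0)
    stop("control must be > 0")
  100 * value / control
}
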