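#' Fit a gas-chromatography methane calibration curve
#'
#' Ordinary least squares of percent methane on peak area over the standard
#' mixtures, giving the prediction equation `%CH4 = intercept + slope * area`.
#' The fit must explain the standards nearly perfectly: a coefficient of
#' determination at or below `r_squared_min` (default 0.985) signals a failed
#' calibration and raises an error (or a warning with `strict = FALSE`).
#'
#' @param standards Data frame with columns `ch4_percent` and `area`, one row
#'   per injection; at least two distinct concentration levels.
#' @param r_squared_min Minimum acceptable R-squared (exclusive).
#' @param strict Raise an error (default) rather than a warning when the fit
#'   quality bound is violated.
#' @return A `gc_calibration`: list with `standards`, `slope`, `intercept`,
#'   `r_squared`, `n_levels`.
#' @export
fit_calibration <- function(standards, r_squared_min = 0.985, strict = TRUE) {
  if (!all(c("ch4_percent", "area") %in% names(standards))) {
    stop_format("`standards` needs columns `ch4_percent` and `area`")
  }
  if (length(unique(standards$ch4_percent)) < 2) {
    stop_validation("at least two distinct standard levels are required")
  }
  if (length(unique(standards$area)) < 2) {
    stop_calibration("all peak areas are identical; calibration fit is singular")
  }
  fit <- stats::lm(ch4_percent ~ area, data = standards)
  # R^2 computed directly so an exact-line calibration does not warn
  sst <- sum((standards$ch4_percent - mean(standards$ch4_percent))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  if (r2 <= r_squared_min) {
    msg <- sprintf("calibration R-squared %.4f does not exceed the required %.3f",
                   r2, r_squared_min)
    if (strict) stop_calibration(msg) else rlang::warn(msg)
  }
  structure(
    list(standards = tibble::as_tibble(standards),
         slope = unname(coef(fit)[["area"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         n_levels = length(unique(standards$ch4_percent))),
    class = "gc_calibration")
}

#' @export
print.gc_calibration <- function(x, ...) {
  cat(sprintf(
    "<gc_calibration> %%CH4 = %.5g + %.5g * area (R^2 = %.4f, %d levels)\n",
    x$intercept, x$slope, x$r_squared, x$n_levels))
  invisible(x)
}

#' Predict methane concentration from a peak area
#'
#' Applies the calibration prediction equation and clips the result to
#' \[0, 100\] percent; whether clipping occurred is recorded in the `clipped`
#' attribute rather than raised as an error.
#'
#' @param area Peak area(s).
#' @param cal A [fit_calibration()] result.
#' @return Percent methane, with logical attribute `clipped`.
#' @export
predict_ch4_percent <- function(area, cal) {
  stopifnot(inherits(cal, "gc_calibration"))
  raw <- cal$intercept + cal$slope * area
  out <- pmin(100, pmax(0, raw))
  attr(out, "clipped") <- raw < 0 | raw > 100
  out
}

#' Methane yield from total gas production and concentration
#'
#' `yield = TGP * %CH4 / 100`, in mL CH4 at STP per g incubated DM. Yield is
#' computed per trial and then averaged for reporting, which is not the same
#' as multiplying the average TGP by the average concentration; the per-trial
#' mean is the headline number.
#'
#' @param tgp_24 Total gas production at the end of fermentation
#'   (mL STP/g DM); non-negative.
#' @param ch4_percent Methane concentration in the collected gas (percent).
#' @return Methane yield in mL STP per g DM.
#' @export
ch4_yield <- function(tgp_24, ch4_percent) {
  if (any(tgp_24 < 0, na.rm = TRUE) || any(ch4_percent < 0, na.rm = TRUE)) {
    stop_validation("gas production and concentration must be non-negative")
  }
  tgp_24 * ch4_percent / 100
}
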