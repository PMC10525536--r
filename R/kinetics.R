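#' Cumulative gas production curve
#'
#' A `gas_curve` holds blank-corrected cumulative gas volume (mL at STP per g
#' incubated DM) on a time grid in minutes, for a single bottle or for a
#' trial mean. Curves for trial means may carry a pointwise standard error
#' (`sem`), filled in by [average_curves()].
#'
#' @param time_min Time grid in minutes since incubation start; strictly
#'   increasing, starting at or after 0.
#' @param ml_per_g Cumulative gas at STP in mL per g incubated DM at each
#'   grid point.
#' @param bottle_id,trial_id Optional labels.
#' @param sem Optional pointwise standard error of the mean (same length as
#'   `time_min`), used for trial-mean curves.
#' @return A `gas_curve` object.
#' @export
gas_curve <- function(time_min, ml_per_g, bottle_id = NA_character_,
                      trial_id = NA_character_, sem = NULL) {
  if (length(time_min) != length(ml_per_g)) {
    stop_validation("`time_min` and `ml_per_g` must have the same length")
  }
  if (length(time_min) > 1 && any(diff(time_min) <= 0)) {
    stop_validation("`time_min` must be strictly increasing")
  }
  if (!is.null(sem) && length(sem) != length(time_min)) {
    stop_validation("`sem` must match the grid length")
  }
  structure(
    list(bottle_id = bottle_id, trial_id = trial_id,
         time_min = as.numeric(time_min), ml_per_g = as.numeric(ml_per_g),
         sem = sem),
    class = "gas_curve")
}

#' @export
print.gas_curve <- function(x, ...) {
  cat(sprintf("<gas_curve> %s%s: %d points, %.1f-%.1f min, end %.2f mL/g\n",
              ifelse(is.na(x$trial_id), "", paste0(x$trial_id, "/")),
              ifelse(is.na(x$bottle_id), "?", x$bottle_id),
              length(x$time_min), min(x$time_min), max(x$time_min),
              tail(x$ml_per_g, 1)))
  invisible(x)
}

#' @export
as_tibble.gas_curve <- function(x, ...) {
  out <- tibble::tibble(bottle_id = x$bottle_id, trial_id = x$trial_id,
                        time_min = x$time_min, ml_per_g = x$ml_per_g)
  if (!is.null(x$sem)) out$sem <- x$sem
  out
}

#' Total gas production at a given hour
#'
#' Reads cumulative gas production off a curve at an arbitrary hour, linearly
#' interpolating between the recording grid points; a query landing exactly
#' on a grid point returns the recorded value.
#'
#' @param curve A [gas_curve()].
#' @param hour Hours since incubation start, within the recorded span.
#' @return Cumulative gas in mL STP per g DM.
#' @export
tgp_at <- function(curve, hour) {
  stopifnot(inherits(curve, "gas_curve"))
  minutes <- hour * 60
  if (any(minutes < min(curve$time_min)) || any(minutes > max(curve$time_min))) {
    stop_validation(sprintf(
      "hour %s is outside the recorded span [%g, %g] h",
      paste(hour, collapse = ", "),
      min(curve$time_min) / 60, max(curve$time_min) / 60))
  }
  interp_series(curve$time_min, curve$ml_per_g, minutes, "gas curve")
}

#' Kinetic curve parameters of a gas production curve
#'
#' Summarises a cumulative curve nonparametrically, without fitting any
#' model:
#' * `tgp_end`: cumulative gas at the end of fermentation (`end_hour`);
#' * `half_max` ("H"): exactly half of `tgp_end`;
#' * `half_time_h` ("H1"): the earliest time, in hours, at which the
#'   (linearly interpolated) curve reaches `half_max` - reported at sub-grid
#'   resolution;
#' * `vmax`: the maximum rate of production, where the rate over each
#'   recording interval is the slope between consecutive grid points in
#'   mL/g/h;
#' * `tmax_h`: the left endpoint, in hours, of the earliest interval
#'   attaining `vmax` (grid resolution; ties break to the earliest).
#'
#' Cumulative gas at each requested hour is also returned (columns
#' `tgp_<hour>h`).
#'
#' @param curve A [gas_curve()] spanning at least `end_hour`.
#' @param end_hour End of fermentation in hours (default 24).
#' @param hours Hours at which to report total gas production.
#' @return A one-row tibble.
#' @export
curve_parameters <- function(curve, end_hour = 24, hours = c(3, 6, 9, 12, 24)) {
  stopifnot(inherits(curve, "gas_curve"))
  if (length(curve$time_min) < 2) {
    stop_validation("curve must have at least two grid points")
  }
  end_min <- end_hour * 60
  eps <- 1e-8 * max(1, end_min)
  if (max(curve$time_min) < end_min - eps) {
    stop_validation(sprintf("curve ends at %.2f h but end_hour = %g h",
                            max(curve$time_min) / 60, end_hour))
  }
  # truncate to the analysis window, appending an interpolated endpoint if
  # the grid does not land (within float dust) on end_hour
  keep <- curve$time_min <= end_min + eps
  t_min <- curve$time_min[keep]
  v <- curve$ml_per_g[keep]
  if (tail(t_min, 1) < end_min - eps) {
    t_min <- c(t_min, end_min)
    v <- c(v, interp_series(curve$time_min, curve$ml_per_g, end_min))
  }
  t_h <- t_min / 60

  tgp_end <- tail(v, 1)
  half_max <- tgp_end / 2

  # earliest (interpolated) crossing of the half-maximum
  i <- which(v >= half_max)[1]
  half_time_h <- if (is.na(i)) {
    NA_real_
  } else if (i == 1 || v[i] == half_max) {
    t_h[i]
  } else {
    t_h[i - 1] + (half_max - v[i - 1]) / (v[i] - v[i - 1]) * (t_h[i] - t_h[i - 1])
  }

  rates <- diff(v) / diff(t_h)
  vmax <- max(rates)
  # earliest maximal-rate interval; ties are compared with a relative
  # tolerance so float dust on an exactly constant slope cannot hide a tie
  j <- which(rates >= vmax - 1e-9 * max(1, abs(vmax)))[1]
  tmax_h <- t_h[j]

  tgp_cols <- if (length(hours) > 0) {
    setNames(as.list(tgp_at(curve, hours)), paste0("tgp_", hours, "h"))
  } else list()
  tibble::as_tibble(c(
    list(bottle_id = curve$bottle_id, trial_id = curve$trial_id),
    tgp_cols,
    list(tgp_end = tgp_end, half_max = half_max, half_time_h = half_time_h,
         vmax = vmax, tmax_h = tmax_h)))
}

#' Average gas curves pointwise
#'
#' Interpolates every curve onto the grid of the first and returns the
#' pointwise arithmetic mean together with the pointwise standard error of
#' the mean (for plotting mean curves with error bars).
#'
#' @param curves A non-empty list of [gas_curve()] objects.
#' @param trial_id Label for the averaged curve.
#' @return A [gas_curve()] whose `sem` field holds the pointwise SEM (zero
#'   when a single curve is supplied).
#' @export
average_curves <- function(curves, trial_id = NA_character_) {
  if (length(curves) == 0) stop_validation("cannot average an empty list of curves")
  stopifnot(all(vapply(curves, inherits, logical(1), "gas_curve")))
  grid <- curves[[1]]$time_min
  mat <- vapply(curves, function(cv) {
    interp_series(cv$time_min, cv$ml_per_g, grid, "gas curve")
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n <- ncol(mat)
  means <- rowMeans(mat)
  sem <- if (n > 1) apply(mat, 1, stats::sd) / sqrt(n) else rep(0, length(grid))
  gas_curve(grid, means, bottle_id = NA_character_, trial_id = trial_id,
            sem = sem)
}
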