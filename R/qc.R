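#' Technical-replicate deviation filter
#'
#' Bottles fermenting the same substrate in one trial are technical
#' replicates; a bottle is excluded from the trial average when its total
#' gas production evaluated at `at_hour` deviates from the group mean by
#' more than `threshold` (default >10% at 12 h). The group mean is computed
#' once over all candidate bottles (single pass); an iterative variant that
#' recomputes the mean after each exclusion is available for sensitivity
#' analysis.
#'
#' A single bottle is always included (the rule is vacuous without a
#' comparison) and flagged as such. When exactly two bottles disagree by
#' more than the threshold, both carry the same deviation and both are
#' excluded: the trial is unusable for that substrate and downstream code
#' must treat its average as missing.
#'
#' @param curves A non-empty list of [gas_curve()] objects (one per bottle).
#' @param threshold Maximum allowed fractional deviation (default 0.10).
#' @param at_hour Hour at which the deviation is evaluated (default 12).
#' @param iterative Recompute the mean after each exclusion (default FALSE).
#' @return A list with `included` (the retained curves) and `decisions`, a
#'   tibble with one row per bottle: `bottle_id`, `included`,
#'   `deviation_at_12h`, `reason`.
#' @export
filter_technical_replicates <- function(curves, threshold = 0.10, at_hour = 12,
                                        iterative = FALSE) {
  if (length(curves) == 0) stop_validation("no curves supplied")
  stopifnot(all(vapply(curves, inherits, logical(1), "gas_curve")))
  ids <- vapply(curves, function(cv) cv$bottle_id, character(1))
  tgp <- vapply(curves, tgp_at, numeric(1), hour = at_hour)

  if (length(curves) == 1) {
    decisions <- tibble::tibble(bottle_id = ids, included = TRUE,
                                deviation_at_12h = 0,
                                reason = "single replicate; no comparison possible")
    return(list(included = curves, decisions = decisions))
  }

  active <- rep(TRUE, length(curves))
  repeat {
    ref <- mean(tgp[active])
    if (ref == 0 && any(tgp[active] != 0)) {
      stop_qc("group mean at the QC hour is zero with nonzero curves; deviation undefined")
    }
    deviation <- if (ref == 0) rep(0, length(tgp)) else abs(tgp - ref) / abs(ref)
    exclude_now <- active & deviation > threshold
    if (!iterative || !any(exclude_now) || !any(active & !exclude_now)) {
      active <- active & !exclude_now
      break
    }
    active <- active & !exclude_now
  }

  decisions <- tibble::tibble(
    bottle_id = ids,
    included = active,
    deviation_at_12h = deviation,
    reason = dplyr::case_when(
      active ~ "within deviation threshold",
      TRUE ~ sprintf("deviation %.1f%% at %g h exceeds %.0f%%",
                     100 * deviation, at_hour, 100 * threshold)))
  list(included = curves[active], decisions = decisions)
}

#' Average gas-chromatography analytical replicates
#'
#' Each gas bag is injected at least twice; the analytical replicates are
#' averaged only if every replicate's peak area lies within `threshold`
#' (default 10%) of their mean. Otherwise a QC error listing the areas is
#' raised, prompting re-injection.
#'
#' @param areas Numeric vector of peak areas, length >= 2.
#' @param threshold Maximum allowed fractional deviation from the mean.
#' @return The arithmetic mean area.
#' @export
average_gc_replicates <- function(areas, threshold = 0.10) {
  if (length(areas) < 2) {
    stop_validation("at least two analytical replicates are required")
  }
  m <- mean(areas)
  if (m == 0) {
    if (all(areas == 0)) return(0)
    stop_qc("mean peak area is zero with nonzero replicates; deviation undefined")
  }
  deviation <- abs(areas - m) / abs(m)
  if (any(deviation > threshold)) {
    stop_qc(sprintf(
      "analytical replicates deviate by more than %.0f%% (areas: %s; deviations: %s%%); re-inject",
      100 * threshold, paste(signif(areas, 6), collapse = ", "),
      paste(signif(100 * deviation, 3), collapse = ", ")))
  }
  m
}
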