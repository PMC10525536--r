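#' Unbiased sample standard deviation
#'
#' Standard deviation with the n-1 denominator, the estimator underlying the
#' repeatability coefficient of variation.
#'
#' @param values Numeric vector, length >= 2.
#' @return The unbiased SD.
#' @export
unbiased_sd <- function(values) {
  if (length(values) < 2) stop_validation("at least two values are required")
  stats::sd(values)
}

#' Repeatability coefficient of variation
#'
#' `CV_RF = 100 * sd / mean`, with the unbiased SD across fermentation
#' trials. The trials are the replication unit: each value should be one
#' trial's mean over its included technical replicates.
#'
#' @param values Per-trial parameter values, length >= 2 with nonzero mean.
#' @return CV in percent.
#' @export
cv_rf <- function(values) {
  if (length(values) < 2) stop_validation("at least two values are required")
  m <- mean(values)
  if (m == 0) stop_validation("mean is zero; the coefficient of variation is undefined")
  100 * unbiased_sd(values) / m
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite approximation, appropriate
#' for the unbalanced numbers of fermentations per donor type. When both
#' groups have zero variance, the test statistic is taken as 0 with p = 1 if
#' the means agree, and as infinite with p = 0 otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_validation("each group needs at least two values")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    return(list(t = if (same) 0 else Inf * sign(mean(group_a) - mean(group_b)),
                df = length(group_a) + length(group_b) - 2,
                p = if (same) 1 else 0,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Fixed-effects trial-by-donor model with reduction
#'
#' Fits the fixed-effects linear model
#' `value = mu + trial + donor + trial:donor + error`
#' for one response, then reduces it by removing non-significant terms at
#' level `alpha`. Because every fermentation trial uses a single donor type,
#' trial is nested in donor: the interaction is structurally inestimable and
#' the trial term measures within-donor trial-to-trial differences. With one
#' value per trial the trial term is saturated as well and the model reduces
#' to the donor effect alone (with a message in `notes`).
#'
#' In the (non-nested) case where the interaction is estimable and
#' significant, the data are split by donor type and the trial effect is
#' re-tested within each type.
#'
#' A Welch t-test comparing donor types on the per-trial means is always
#' reported alongside, as the robust check for the unbalanced design.
#'
#' @param data Data frame with columns `trial_id`, `donor_type`, `value`
#'   (one row per bottle or per trial).
#' @param alpha Significance level for model reduction (default 0.05).
#' @return A `trial_donor_fit`: list with p-values (`p_interaction`,
#'   `p_trial`, `p_donor`), the retained terms (`final_terms`), per-donor
#'   split results (`split`, when the interaction is significant), the Welch
#'   test (`welch`) and bookkeeping notes.
#' @export
fit_trial_donor_model <- function(data, alpha = 0.05) {
  req <- c("trial_id", "donor_type", "value")
  if (!all(req %in% names(data))) {
    stop_format(sprintf("`data` needs columns %s", paste(req, collapse = ", ")))
  }
  d <- data.frame(trial = factor(data$trial_id),
                  donor = factor(data$donor_type),
                  value = as.numeric(data$value))
  if (nlevels(d$donor) < 2) stop_validation("both donor types must be present")
  counts <- table(unique(d[c("trial", "donor")])$donor)
  if (any(counts < 2)) stop_validation("at least two trials per donor type are required")

  notes <- character()
  reps <- anyDuplicated(d$trial) > 0
  # nested design: every trial belongs to exactly one donor type
  nested <- all(rowSums(table(d$trial, d$donor) > 0) == 1)

  clean_p <- function(p) if (is.null(p) || length(p) == 0 || is.nan(p)) NA_real_ else p
  # anova warns on essentially perfect fits; those degenerate p-values are
  # already mapped to NA by clean_p
  quiet_anova <- function(m) suppressWarnings(anova(m))

  p_interaction <- NA_real_
  split <- NULL
  if (!nested && reps) {
    m_full <- stats::lm(value ~ donor * trial, data = d)
    an <- quiet_anova(m_full)
    p_interaction <- clean_p(an["donor:trial", "Pr(>F)"])
  } else {
    notes <- c(notes, "interaction inestimable: trials are nested in donor type")
  }

  if (!is.na(p_interaction) && p_interaction < alpha) {
    # significant interaction: split by donor type and re-test trial effect
    split <- dplyr::bind_rows(lapply(levels(d$donor), function(g) {
      dg <- d[d$donor == g, , drop = FALSE]
      pg <- clean_p(quiet_anova(stats::lm(value ~ trial, data = dg))["trial", "Pr(>F)"])
      tibble::tibble(donor_type = g, p_trial = pg)
    }))
    final_terms <- c("donor_type", "trial_id", "donor_type:trial_id")
    p_trial <- NA_real_
    p_donor <- clean_p(quiet_anova(stats::lm(value ~ donor + trial, data = d))["donor", "Pr(>F)"])
  } else {
    p_trial <- NA_real_
    trial_kept <- FALSE
    if (reps) {
      m_add <- stats::lm(value ~ donor + trial, data = d)
      if (stats::df.residual(m_add) > 0) {
        an_add <- quiet_anova(m_add)
        p_trial <- clean_p(an_add["trial", "Pr(>F)"])
        trial_kept <- !is.na(p_trial) && p_trial < alpha
        if (trial_kept) p_donor <- clean_p(an_add["donor", "Pr(>F)"])
      } else {
        notes <- c(notes, "one observation per cell: trial term saturated, reduced to donor effect")
      }
    } else {
      notes <- c(notes, "one value per trial: trial term saturated, reduced to donor effect")
    }
    if (!trial_kept) {
      p_donor <- clean_p(quiet_anova(stats::lm(value ~ donor, data = d))["donor", "Pr(>F)"])
    }
    final_terms <- c(if (!is.na(p_donor) && p_donor < alpha) "donor_type",
                     if (trial_kept) "trial_id")
    if (length(final_terms) == 0) final_terms <- "(intercept)"
  }

  # per-(trial, donor) cell means; under nesting these are the per-trial means
  cell <- stats::aggregate(value ~ trial + donor, data = d, FUN = mean)
  groups <- split(cell$value, cell$donor)
  welch <- if (all(lengths(groups) >= 2)) do.call(welch_test, unname(groups[1:2])) else NULL

  structure(
    list(n = nrow(d), alpha = alpha, nested = nested,
         replicates_within_trial = reps,
         p_interaction = p_interaction, p_trial = p_trial, p_donor = p_donor,
         final_terms = final_terms, split = split, welch = welch,
         notes = notes),
    class = "trial_donor_fit")
}

#' @export
print.trial_donor_fit <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "-" else sprintf("%.4g", p)
  cat(sprintf(
    "<trial_donor_fit> n = %d | p(interaction) = %s, p(trial) = %s, p(donor) = %s\n",
    x$n, fmt(x$p_interaction), fmt(x$p_trial), fmt(x$p_donor)))
  cat("  retained terms:", paste(x$final_terms, collapse = " + "), "\n")
  if (!is.null(x$welch)) {
    cat(sprintf("  Welch on per-trial means: t = %.3f, df = %.2f, p = %.4g\n",
                x$welch$t, x$welch$df, x$welch$p))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Repeatability report across fermentation trials
#'
#' For each parameter, summarises the per-trial values by donor type
#' (n, mean, SEM, unbiased SD, CV_RF in percent) and overall. The printed
#' overall repeatability of the source tables is not uniquely defined when
#' donor-type means differ, so two overall estimators are reported:
#' * `cv_all_trial_means`: CV over all per-trial values pooled across donor
#'   types (donor differences inflate this one);
#' * `cv_all_within_type`: pooled within-type SD (n-1 weights) over the
#'   grand mean of trial values (pure repeatability, free of the donor
#'   contrast).
#'
#' @param per_trial Data frame with columns `trial_id`, `donor_type`, and
#'   one column per parameter.
#' @param parameters Character vector of parameter column names; defaults to
#'   every numeric column except the identifiers.
#' @return A tibble with one row per parameter x donor type plus the overall
#'   columns repeated on each row of that parameter.
#' @export
repeatability_report <- function(per_trial, parameters = NULL) {
  if (!all(c("trial_id", "donor_type") %in% names(per_trial))) {
    stop_format("`per_trial` needs columns `trial_id` and `donor_type`")
  }
  if (is.null(parameters)) {
    parameters <- setdiff(names(per_trial)[vapply(per_trial, is.numeric, logical(1))],
                          c("trial_id", "donor_type"))
  }
  rows <- lapply(parameters, function(p) {
    vals <- per_trial[[p]]
    ok <- is.finite(vals)
    by_type <- lapply(split(vals[ok], per_trial$donor_type[ok]), function(v) {
      n <- length(v)
      list(n = n, mean = mean(v),
           sd = if (n >= 2) unbiased_sd(v) else NA_real_,
           sem = if (n >= 2) unbiased_sd(v) / sqrt(n) else NA_real_,
           cv = if (n >= 2 && mean(v) != 0) cv_rf(v) else NA_real_)
    })
    all_vals <- vals[ok]
    cv_all <- if (length(all_vals) >= 2 && mean(all_vals) != 0) cv_rf(all_vals) else NA_real_
    sds <- vapply(by_type, `[[`, numeric(1), "sd")
    ns <- vapply(by_type, `[[`, numeric(1), "n")
    pooled_sd <- if (all(ns >= 2)) {
      sqrt(sum((ns - 1) * sds^2) / sum(ns - 1))
    } else NA_real_
    cv_within <- if (!is.na(pooled_sd) && mean(all_vals) != 0) {
      100 * pooled_sd / mean(all_vals)
    } else NA_real_
    dplyr::bind_rows(lapply(names(by_type), function(g) {
      s <- by_type[[g]]
      tibble::tibble(parameter = p, donor_type = g, n = s$n, mean = s$mean,
                     sem = s$sem, sd = s$sd, cv_rf = s$cv,
                     cv_all_trial_means = cv_all,
                     cv_all_within_type = cv_within)
    }))
  })
  dplyr::bind_rows(rows)
}
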