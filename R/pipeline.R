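#' Analyse one fermentation trial
#'
#' Runs the per-trial analysis chain on already-loaded inputs: builds the
#' mean blank profile, blank-corrects every substrate bottle, converts to
#' gas curves (mL STP per g DM), applies the technical-replicate QC filter,
#' extracts kinetic parameters per bottle and averages them across the
#' included replicates, fits the trial's GC calibration and predicts
#' methane concentration and yield, and computes baseline-corrected
#' dry-matter degradation.
#'
#' @param meta A [read_trial_meta()] result.
#' @param runs Pressure runs for this trial, as from [read_pressure_log()].
#' @param bottles Data frame `bottle_id`, `role`, `substrate_dm_g` for this
#'   trial.
#' @param residues Data frame `bottle_id`, `empty_bag_g`, `bag_after_g`.
#' @param gc_standards Data frame `ch4_percent`, `area` for this trial.
#' @param gc_bags Data frame `bottle_id`, `area` (one row per injection).
#' @param qc_threshold,qc_hour Technical-replicate filter settings
#'   (default >10% deviation at 12 h excludes a bottle).
#' @param end_hour End of fermentation, hours (default 24).
#' @param tgp_hours Hours at which total gas production is reported.
#' @param use_blank Optional single blank bottle id to use instead of the
#'   mean blank profile.
#' @return A list with `per_bottle` (tibble), `trial` (one-row tibble),
#'   `mean_curve` (a [gas_curve()]), `profile`, `calibration`.
#' @export
analyze_trial <- function(meta, runs, bottles, residues,
                          gc_standards = NULL, gc_bags = NULL,
                          qc_threshold = 0.10, qc_hour = 12,
                          end_hour = 24, tgp_hours = c(3, 6, 9, 12, 24),
                          use_blank = NULL) {
  stopifnot(inherits(meta, "trial_meta"))
  info <- dplyr::left_join(runs, bottles, by = "bottle_id")
  if (any(is.na(info$role))) {
    stop_validation(sprintf(
      "trial '%s': bottle(s) %s have pressure data but no bottle metadata",
      meta$trial_id, paste(info$bottle_id[is.na(info$role)], collapse = ", ")))
  }
  blanks_tbl <- info[info$role == "blank", ]
  samples_tbl <- info[info$role == "sample", ]
  if (nrow(blanks_tbl) == 0) {
    stop_config(sprintf("trial '%s' has no blank bottles", meta$trial_id))
  }
  if (nrow(samples_tbl) == 0) {
    stop_validation(sprintf("trial '%s' has no substrate bottles", meta$trial_id))
  }

  physics <- physics_config(headspace_ml = meta$headspace_ml,
                            incubation_temp_C = meta$incubation_temp_c,
                            ambient_pressure_kPa = meta$ambient_pressure_kpa)

  blank_series <- setNames(blanks_tbl$series, blanks_tbl$bottle_id)
  profile <- build_blank_profile(blank_series, use_blank = use_blank)

  curves <- vector("list", nrow(samples_tbl))
  n_negative <- integer(nrow(samples_tbl))
  for (i in seq_len(nrow(samples_tbl))) {
    corrected <- correct_sample(samples_tbl$series[[i]], profile)
    n_negative[i] <- attr(corrected, "n_negative")
    curves[[i]] <- to_gas_curve(corrected, samples_tbl$substrate_dm_g[i],
                                physics, bottle_id = samples_tbl$bottle_id[i],
                                trial_id = meta$trial_id)
  }

  qc <- filter_technical_replicates(curves, threshold = qc_threshold,
                                    at_hour = qc_hour)

  params <- dplyr::bind_rows(lapply(curves, curve_parameters,
                                    end_hour = end_hour, hours = tgp_hours))
  params$trial_id <- meta$trial_id

  # dry-matter degradation with baseline biomass correction
  res <- dplyr::mutate(residues, residue_g = .data$bag_after_g - .data$empty_bag_g)
  bb <- blank_biomass(res$residue_g[res$bottle_id %in% blanks_tbl$bottle_id])
  res_samples <- res[res$bottle_id %in% samples_tbl$bottle_id, ]
  ddm_tbl <- dplyr::left_join(
    samples_tbl[, c("bottle_id", "substrate_dm_g")],
    res_samples[, c("bottle_id", "residue_g")], by = "bottle_id")
  ddm_tbl$ddm <- as.numeric(compute_ddm(ddm_tbl$residue_g, bb, ddm_tbl$substrate_dm_g))

  # methane: trial calibration, per-bottle bag concentration
  calibration <- NULL
  ch4_tbl <- tibble::tibble(bottle_id = character(), ch4_percent = numeric())
  if (!is.null(gc_standards) && nrow(gc_standards) > 0) {
    calibration <- fit_calibration(gc_standards)
    if (!is.null(gc_bags) && nrow(gc_bags) > 0) {
      ch4_tbl <- gc_bags |>
        dplyr::group_by(.data$bottle_id) |>
        dplyr::summarise(mean_area = average_gc_replicates(.data$area),
                         .groups = "drop") |>
        dplyr::mutate(ch4_percent = as.numeric(
          predict_ch4_percent(.data$mean_area, calibration))) |>
        dplyr::select("bottle_id", "ch4_percent")
    }
  }

  per_bottle <- params |>
    dplyr::left_join(qc$decisions, by = "bottle_id") |>
    dplyr::left_join(ddm_tbl[, c("bottle_id", "residue_g", "ddm")], by = "bottle_id") |>
    dplyr::left_join(ch4_tbl, by = "bottle_id") |>
    dplyr::mutate(role = "sample", donor_type = meta$donor_type,
                  n_negative_corrected = n_negative,
                  substrate_dm_g = samples_tbl$substrate_dm_g)

  included <- per_bottle$included
  trial_mean <- function(x) if (any(included)) mean(x[included]) else NA_real_
  numeric_params <- setdiff(names(params)[vapply(params, is.numeric, logical(1))],
                            character())
  trial <- tibble::as_tibble(c(
    list(trial_id = meta$trial_id, donor_type = meta$donor_type,
         n_bottles = nrow(samples_tbl), n_included = sum(included)),
    setNames(lapply(numeric_params, function(p) trial_mean(per_bottle[[p]])),
             numeric_params)))
  trial$ddm <- trial_mean(per_bottle$ddm)
  trial$ch4_percent <- if (nrow(ch4_tbl) > 0) mean(per_bottle$ch4_percent[included], na.rm = TRUE) else NA_real_
  trial$ch4_yield <- ch4_yield(trial$tgp_end, trial$ch4_percent)
  trial$ph_pre <- if (length(meta$rumen_ph_pre) > 0) mean(meta$rumen_ph_pre) else NA_real_
  trial$ph_post <- if (length(meta$filtrate_ph_post) > 0) mean(meta$filtrate_ph_post) else NA_real_
  trial$blank_biomass_g <- bb
  trial$blank_peak_psi <- profile$peak_psi
  trial$blank_peak_time_min <- profile$peak_time_min
  trial$calibration_r_squared <- if (is.null(calibration)) NA_real_ else calibration$r_squared

  mean_curve <- if (any(included)) {
    average_curves(curves[included], trial_id = meta$trial_id)
  } else NULL

  list(per_bottle = per_bottle, trial = trial, mean_curve = mean_curve,
       profile = profile, calibration = calibration)
}

#' Run the full analysis pipeline on a study directory
#'
#' Executes the stage order of the analysis on a directory laid out as
#' written by [simulate_study()] (or assembled by hand in the same format):
#' reading \ifelse{html}{\out{&rarr;}}{->} blank correction
#' \ifelse{html}{\out{&rarr;}}{->} gas conversion
#' \ifelse{html}{\out{&rarr;}}{->} QC \ifelse{html}{\out{&rarr;}}{->}
#' kinetics \ifelse{html}{\out{&rarr;}}{->} methane
#' \ifelse{html}{\out{&rarr;}}{->} degradation
#' \ifelse{html}{\out{&rarr;}}{->} repeatability statistics. The analysis is
#' deterministic: two runs on the same inputs produce identical outputs.
#'
#' The statistics layer computes, for each reported parameter, per-donor
#' repeatability (mean, SEM, unbiased SD, CV_RF) plus two overall CV
#' estimators, the fixed-effects trial-by-donor model with reduction, and a
#' Welch t-test between donor types on per-trial values. Bottle-level
#' parameters are modelled on per-bottle values (so the trial term is
#' estimable); trial-level parameters (methane, pH) on per-trial values.
#'
#' @param input_dir Study directory containing `manifest.csv`,
#'   `pressure/`, `meta/`, `bottles.csv`, `residues.csv`,
#'   `gc_standards.csv`, `gc_bags.csv`.
#' @param output_dir Optional directory; when given, [write_report()] is
#'   called on the results.
#' @param alpha Significance level for model reduction (default 0.05).
#' @param qc_threshold,qc_hour Technical-replicate filter settings.
#' @param end_hour,tgp_hours Kinetics settings.
#' @return A list with `per_bottle`, `per_trial`, `repeatability`,
#'   `model_fits`, `mean_curves`, `summary`, `settings`.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL, alpha = 0.05,
                         qc_threshold = 0.10, qc_hour = 12,
                         end_hour = 24, tgp_hours = c(3, 6, 9, 12, 24)) {
  manifest_path <- file.path(input_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop_io(sprintf("'%s' does not contain a manifest.csv", input_dir))
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  read_table <- function(name, required = TRUE) {
    p <- file.path(input_dir, name)
    if (!file.exists(p)) {
      if (required) stop_io(sprintf("required input '%s' is missing", p))
      return(NULL)
    }
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  bottles <- read_table("bottles.csv")
  residues <- read_table("residues.csv")
  gc_standards <- read_table("gc_standards.csv", required = FALSE)
  gc_bags <- read_table("gc_bags.csv", required = FALSE)

  results <- lapply(seq_len(nrow(manifest)), function(i) {
    tid <- manifest$trial_id[i]
    stage <- function(expr, file) {
      tryCatch(expr, error = function(e) {
        ivgpr_abort(sprintf("trial '%s' (%s): %s", tid, file, conditionMessage(e)),
                    class = class(e)[1])
      })
    }
    meta <- stage(read_trial_meta(file.path(input_dir, manifest$meta_file[i])),
                  manifest$meta_file[i])
    runs <- stage(read_pressure_log(file.path(input_dir, manifest$pressure_file[i])),
                  manifest$pressure_file[i])
    analyze_trial(
      meta, runs,
      bottles[bottles$trial_id == tid, ],
      residues[residues$trial_id == tid, ],
      if (!is.null(gc_standards)) gc_standards[gc_standards$trial_id == tid, ],
      if (!is.null(gc_bags)) gc_bags[gc_bags$trial_id == tid, ],
      qc_threshold = qc_threshold, qc_hour = qc_hour,
      end_hour = end_hour, tgp_hours = tgp_hours)
  })

  per_bottle <- dplyr::bind_rows(lapply(results, `[[`, "per_bottle"))
  per_trial <- dplyr::bind_rows(lapply(results, `[[`, "trial"))
  mean_curves <- setNames(lapply(results, `[[`, "mean_curve"), per_trial$trial_id)

  kinetic_params <- c(paste0("tgp_", tgp_hours, "h"),
                      "tgp_end", "half_max", "half_time_h", "vmax", "tmax_h")
  trial_level_params <- c("ch4_percent", "ch4_yield", "ph_pre", "ph_post")
  all_params <- c(kinetic_params, "ddm", trial_level_params)

  repeatability <- repeatability_report(per_trial, intersect(all_params, names(per_trial)))

  both_types <- length(unique(per_trial$donor_type)) == 2 &&
    all(table(per_trial$donor_type) >= 2)
  model_fits <- if (both_types) {
    fits <- lapply(intersect(all_params, names(per_trial)), function(p) {
      data <- if (p %in% c(kinetic_params, "ddm") && p %in% names(per_bottle)) {
        tibble::tibble(trial_id = per_bottle$trial_id,
                       donor_type = per_bottle$donor_type,
                       value = per_bottle[[p]])[per_bottle$included, ]
      } else {
        tibble::tibble(trial_id = per_trial$trial_id,
                       donor_type = per_trial$donor_type,
                       value = per_trial[[p]])
      }
      data <- data[is.finite(data$value), ]
      tryCatch(fit_trial_donor_model(data, alpha = alpha),
               error = function(e) NULL)
    })
    setNames(fits, intersect(all_params, names(per_trial)))
  } else list()

  settings <- list(alpha = alpha, qc_threshold = qc_threshold, qc_hour = qc_hour,
                   end_hour = end_hour, tgp_hours = tgp_hours,
                   headspace_ml = unique(vapply(
                     seq_len(nrow(manifest)), function(i) {
                       read_trial_meta(file.path(input_dir, manifest$meta_file[i]))$headspace_ml
                     }, numeric(1))),
                   stp_temp_K = 273.15, stp_pressure_kPa = 101.325)

  summary <- list(
    n_trials = nrow(per_trial),
    donor_counts = as.list(table(per_trial$donor_type)),
    settings = settings,
    repeatability = repeatability,
    model_fits = lapply(model_fits, function(f) {
      if (is.null(f)) return(NULL)
      list(p_interaction = f$p_interaction, p_trial = f$p_trial,
           p_donor = f$p_donor, final_terms = f$final_terms,
           welch = f$welch)
    }))

  out <- list(per_bottle = per_bottle, per_trial = per_trial,
              repeatability = repeatability, model_fits = model_fits,
              mean_curves = mean_curves, summary = summary,
              settings = settings)
  if (!is.null(output_dir)) {
    write_report(list(per_bottle = per_bottle, per_trial = per_trial,
                      summary = summary), output_dir)
  }
  out
}

#' Generate a synthetic study on disk
#'
#' Thin wrapper around [simulate_study()] for the simulate-then-analyse
#' workflow.
#'
#' @inheritParams simulate_study
#' @param ... Passed to [simulate_study()].
#' @return See [simulate_study()].
#' @export
run_simulate <- function(out_dir, seed = 1, ...) {
  simulate_study(out_dir, seed = seed, ...)
}

#' Plot mean gas production curves by donor type
#'
#' Figure-style summary: the average blank-corrected total gas production
#' curve per donor type with SEM ribbons. Requires ggplot2.
#'
#' @param per_trial_curves Named list of trial-mean [gas_curve()]s, as in
#'   the `mean_curves` element of [run_pipeline()] output.
#' @param donor_types Named character vector mapping trial id to donor type.
#' @return A ggplot object.
#' @export
plot_mean_curves <- function(per_trial_curves, donor_types) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("ggplot2 is required for plotting")
  }
  keep <- !vapply(per_trial_curves, is.null, logical(1))
  df <- dplyr::bind_rows(lapply(names(per_trial_curves)[keep], function(tid) {
    cv <- per_trial_curves[[tid]]
    tibble::tibble(trial_id = tid, donor_type = donor_types[[tid]],
                   time_h = cv$time_min / 60, ml_per_g = cv$ml_per_g)
  }))
  df <- df |>
    dplyr::group_by(.data$donor_type, .data$time_h) |>
    dplyr::summarise(mean = mean(.data$ml_per_g),
                     sem = stats::sd(.data$ml_per_g) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$mean,
                                   colour = .data$donor_type,
                                   fill = .data$donor_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "TGP (mL STP / g DM)",
                  colour = "Donor type", fill = "Donor type") +
    ggplot2::theme_minimal()
}
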