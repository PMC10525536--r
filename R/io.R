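#' Read a canonical bottle pressure log
#'
#' Reads a delimited pressure log with one row per (bottle, time point). The
#' canonical columns are `bottle_id`, `time_min`, `abs_pressure_psi`
#' (optional) and `cum_pressure_psi`; exports using other column names are
#' accepted through `dialect`, a named map from canonical names to the
#' file's names.
#'
#' Each bottle's series is sorted by time and validated: times must be
#' strictly increasing (no duplicates) and the cumulative pressure
#' non-decreasing. A decreasing cumulative value is reported with the bottle
#' and time at which it occurs.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector, e.g.
#'   `c(bottle_id = "Bottle", time_min = "T")`.
#' @return A tibble with one row per bottle: `bottle_id` and `series` (a
#'   list-column of tibbles `time_min`, `abs_pressure_psi`,
#'   `cum_pressure_psi`).
#' @examples
#' log <- system.file("extdata", "example_pressure_log.csv", package = "ivgpr")
#' read_pressure_log(log)
#' @export
read_pressure_log <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_io(sprintf("pressure log '%s' does not exist", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    for (canonical in names(dialect)) {
      if (dialect[[canonical]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[canonical]]] <- canonical
      }
    }
  }
  required <- c("bottle_id", "time_min", "cum_pressure_psi")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_format(sprintf("pressure log '%s' is missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  if (!"abs_pressure_psi" %in% names(raw)) raw$abs_pressure_psi <- NA_real_
  raw <- dplyr::arrange(raw, .data$bottle_id, .data$time_min)

  runs <- raw |>
    dplyr::group_by(.data$bottle_id) |>
    tidyr::nest(series = c("time_min", "abs_pressure_psi", "cum_pressure_psi")) |>
    dplyr::ungroup()

  for (i in seq_len(nrow(runs))) {
    s <- runs$series[[i]]
    if (anyDuplicated(s$time_min) > 0) {
      stop_validation(sprintf("bottle '%s': duplicated time points", runs$bottle_id[i]))
    }
    drop <- which(diff(s$cum_pressure_psi) < 0)
    if (length(drop) > 0) {
      stop_validation(sprintf(
        "bottle '%s': cumulative pressure decreases at time %g min",
        runs$bottle_id[i], s$time_min[drop[1] + 1]))
    }
  }
  runs
}

#' Read trial metadata
#'
#' Reads a YAML key-value file describing one fermentation trial. The donor
#' type is mandatory and must be `RF_T` or `RF_A`; the physics constants
#' default to the apparatus values (39.5 degC incubation, 101.325 kPa
#' ambient, 10 mL headspace) when unspecified. pH readings must lie in
#' \[4, 9\].
#'
#' @param path Path to a YAML file.
#' @return A `trial_meta` list with `trial_id`, `donor_type`,
#'   `rumen_ph_pre`, `filtrate_ph_post`, `incubation_temp_c`,
#'   `ambient_pressure_kpa`, `headspace_ml`.
#' @export
read_trial_meta <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("metadata file '%s' does not exist", path))
  meta <- yaml::read_yaml(path)
  if (is.null(meta$donor_type)) {
    stop_validation(sprintf("metadata '%s' does not specify donor_type", path))
  }
  if (!meta$donor_type %in% c("RF_T", "RF_A")) {
    stop_validation(sprintf("unknown donor_type '%s' (expected RF_T or RF_A)",
                            meta$donor_type))
  }
  defaults <- list(incubation_temp_c = 39.5, ambient_pressure_kpa = 101.325,
                   headspace_ml = 10, rumen_ph_pre = numeric(),
                   filtrate_ph_post = numeric())
  for (key in names(defaults)) {
    if (is.null(meta[[key]])) meta[[key]] <- defaults[[key]]
  }
  ph <- c(meta$rumen_ph_pre, meta$filtrate_ph_post)
  if (length(ph) > 0 && (any(ph < 4) || any(ph > 9))) {
    stop_validation(sprintf("metadata '%s': pH values outside [4, 9]", path))
  }
  structure(meta, class = "trial_meta")
}

#' Write the pipeline report
#'
#' Writes the tidy result tables and a structured summary: `per_bottle.csv`,
#' `per_trial.csv` and `summary.json` under `dir`. Numbers are serialised at
#' full precision so that a written report re-reads to the same values.
#'
#' @param results A list with elements `per_bottle` (data frame), `per_trial`
#'   (data frame) and `summary` (list).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_io(sprintf("cannot create output directory '%s'", dir))
  paths <- c(per_bottle = file.path(dir, "per_bottle.csv"),
             per_trial = file.path(dir, "per_trial.csv"),
             summary = file.path(dir, "summary.json"))
  readr::write_csv(tibble::as_tibble(results$per_bottle), paths[["per_bottle"]])
  readr::write_csv(tibble::as_tibble(results$per_trial), paths[["per_trial"]])
  jsonlite::write_json(results$summary, paths[["summary"]],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}

#' Re-read a written pipeline report
#'
#' Inverse of [write_report()], used for round-trip checks and downstream
#' consumption of saved runs.
#'
#' @param dir Directory previously written by [write_report()].
#' @return A list with `per_bottle`, `per_trial` and `summary`.
#' @export
read_report <- function(dir) {
  paths <- file.path(dir, c("per_bottle.csv", "per_trial.csv", "summary.json"))
  if (!all(file.exists(paths))) {
    stop_io(sprintf("'%s' does not contain a complete report", dir))
  }
  list(per_bottle = readr::read_csv(paths[1], show_col_types = FALSE, progress = FALSE),
       per_trial = readr::read_csv(paths[2], show_col_types = FALSE, progress = FALSE),
       summary = jsonlite::read_json(paths[3], simplifyVector = TRUE))
}
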