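#' Physics settings for pressure-to-volume conversion
#'
#' Bundles the constants needed to convert headspace gauge pressure (psi) into
#' gas volume at standard temperature and pressure (STP) via the ideal gas
#' law. Because the moles of gas released are computed at incubation
#' temperature and then re-expressed at STP, the gas constant cancels and the
#' conversion is a single linear factor (see [psi_to_ml_stp()]).
#'
#' The default headspace is the nominal 100 mL bottle minus the 90 mL of
#' buffered rumen fluid. Real bottles exceed their nominal volume, so
#' `headspace_ml` should be set to the measured value whenever it is known;
#' every report records the value used.
#'
#' @param headspace_ml Bottle headspace volume in mL (default 10).
#' @param incubation_temp_C Incubation temperature in degrees Celsius
#'   (default 39.5).
#' @param ambient_pressure_kPa Ambient pressure in kPa that gauge readings are
#'   measured against (default 101.325). Recorded for provenance; gauge
#'   pressure is already a difference, so it does not enter the conversion.
#' @param stp_temp_K Standard temperature in Kelvin (default 273.15).
#' @param stp_pressure_kPa Standard pressure in kPa (default 101.325).
#' @param psi_to_kPa Conversion factor from psi to kPa (6.894757).
#' @return A `physics_config` object (a validated list).
#' @examples
#' cfg <- physics_config()
#' psi_to_ml_stp(1, cfg) # about 0.59 mL STP per psi in a 10 mL headspace
#' @export
physics_config <- function(headspace_ml = 10,
                           incubation_temp_C = 39.5,
                           ambient_pressure_kPa = 101.325,
                           stp_temp_K = 273.15,
                           stp_pressure_kPa = 101.325,
                           psi_to_kPa = 6.894757) {
  if (!is.numeric(headspace_ml) || length(headspace_ml) != 1 || headspace_ml <= 0) {
    stop_config("`headspace_ml` must be a single positive number")
  }
  if (incubation_temp_C <= -273.15) {
    stop_config("`incubation_temp_C` must be above absolute zero")
  }
  if (stp_temp_K <= 0 || stp_pressure_kPa <= 0 || ambient_pressure_kPa <= 0 ||
      psi_to_kPa <= 0) {
    stop_config("pressures, temperatures and conversion factors must be positive")
  }
  structure(
    list(headspace_ml = headspace_ml,
         incubation_temp_C = incubation_temp_C,
         ambient_pressure_kPa = ambient_pressure_kPa,
         stp_temp_K = stp_temp_K,
         stp_pressure_kPa = stp_pressure_kPa,
         psi_to_kPa = psi_to_kPa),
    class = "physics_config")
}

# mL of gas at STP corresponding to 1 psi of gauge pressure in the headspace:
# n = P_gauge * V_headspace / (R * T_inc); V_stp = n * R * T_stp / P_stp.
ml_per_psi <- function(cfg) {
  cfg$psi_to_kPa * cfg$headspace_ml * cfg$stp_temp_K /
    ((cfg$incubation_temp_C + 273.15) * cfg$stp_pressure_kPa)
}

#' Convert gauge pressure to gas volume at STP
#'
#' Applies the ideal gas law to the bottle headspace: the moles of gas behind
#' a cumulative gauge pressure are `n = P * V_headspace / (R * T_incubation)`
#' and their volume at STP is `n * R * T_STP / P_STP`. The result is linear in
#' pressure and zero at zero.
#'
#' @param cum_psi Cumulative gauge pressure(s) in psi. May be a vector.
#' @param cfg A [physics_config()].
#' @return Gas volume(s) in mL at STP.
#' @seealso [ml_stp_to_psi()] for the exact inverse.
#' @export
psi_to_ml_stp <- function(cum_psi, cfg = physics_config()) {
  stopifnot(inherits(cfg, "physics_config"))
  cum_psi * ml_per_psi(cfg)
}

#' Convert a gas volume at STP back to gauge pressure
#'
#' Exact inverse of [psi_to_ml_stp()]; used by the simulator and for
#' round-trip checks.
#'
#' @inheritParams psi_to_ml_stp
#' @param ml_stp Gas volume(s) in mL at STP.
#' @return Gauge pressure(s) in psi.
#' @export
ml_stp_to_psi <- function(ml_stp, cfg = physics_config()) {
  stopifnot(inherits(cfg, "physics_config"))
  ml_stp / ml_per_psi(cfg)
}

#' Build a gas curve from a blank-corrected pressure series
#'
#' Converts a blank-corrected cumulative pressure series to cumulative gas
#' volume at STP normalised per gram of incubated dry matter:
#' `mL gas / g DM = V / g DM`.
#'
#' @param corrected A data frame with columns `time_min` and `corrected_psi`,
#'   as returned by [correct_sample()].
#' @param substrate_dm_g Grams of incubated dry matter; must be positive
#'   (blank bottles are never converted to per-gram curves).
#' @param cfg A [physics_config()].
#' @param bottle_id,trial_id Optional labels carried on the curve.
#' @return A [gas_curve()] object.
#' @export
to_gas_curve <- function(corrected, substrate_dm_g, cfg = physics_config(),
                         bottle_id = NA_character_, trial_id = NA_character_) {
  if (!is.numeric(substrate_dm_g) || length(substrate_dm_g) != 1 ||
      !is.finite(substrate_dm_g) || substrate_dm_g <= 0) {
    stop_validation("`substrate_dm_g` must be a single positive number (blanks have no gas curve)")
  }
  if (!all(c("time_min", "corrected_psi") %in% names(corrected))) {
    stop_format("`corrected` must have columns `time_min` and `corrected_psi`")
  }
  gas_curve(time_min = corrected$time_min,
            ml_per_g = psi_to_ml_stp(corrected$corrected_psi, cfg) / substrate_dm_g,
            bottle_id = bottle_id, trial_id = trial_id)
}

#' @export
print.physics_config <- function(x, ...) {
  cat(sprintf(
    "<physics_config> headspace %g mL, incubation %g degC, STP %g K / %g kPa (%.4f mL STP per psi)\n",
    x$headspace_ml, x$incubation_temp_C, x$stp_temp_K, x$stp_pressure_kPa,
    ml_per_psi(x)))
  invisible(x)
}
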