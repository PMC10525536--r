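#' Degraded dry matter with baseline biomass correction
#'
#' Fraction of incubated dry matter degraded during fermentation:
#' `dDM = 1 - (residue - blank biomass) / sample DM`.
#' The residue filtered from blank bottles is minimum microbial biomass
#' grown from the rumen fluid itself, and is subtracted from each sample's
#' undegraded residue before dividing.
#'
#' Weighing noise can push dDM outside \[0, 1\]; such values are returned
#' unchanged (truncation would bias repeatability statistics) and flagged in
#' the `out_of_range` attribute.
#'
#' @param residue_g Dried residue mass per bottle (bag after fermentation
#'   minus empty bag), grams; non-negative.
#' @param blank_biomass_g Mean blank-bottle residue, grams; non-negative.
#' @param sample_dm_g Incubated dry matter, grams; positive.
#' @return dDM as a fraction, with logical attribute `out_of_range`.
#' @export
compute_ddm <- function(residue_g, blank_biomass_g, sample_dm_g) {
  if (any(!is.finite(sample_dm_g)) || any(sample_dm_g <= 0)) {
    stop_validation("`sample_dm_g` must be positive")
  }
  if (any(residue_g < 0) || any(blank_biomass_g < 0)) {
    stop_validation("weights must be non-negative")
  }
  ddm <- 1 - (residue_g - blank_biomass_g) / sample_dm_g
  attr(ddm, "out_of_range") <- ddm < 0 | ddm > 1
  ddm
}

#' Mean blank-bottle residue (baseline microbial biomass)
#'
#' @param residues_g Residue masses of the trial's blank bottles, grams.
#' @return Their arithmetic mean; with a single blank, that blank's residue.
#' @export
blank_biomass <- function(residues_g) {
  if (length(residues_g) == 0) stop_config("at least one blank residue is required")
  mean(residues_g)
}
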