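#' Stable integer seed from labels
#'
#' Derives a deterministic sub-seed from an integer seed and arbitrary
#' labels, so each bottle (or other unit) gets its own reproducible random
#' stream: adding bottles to a simulated trial never perturbs the draws of
#' existing bottles.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
stable_seed <- function(seed, ...) {
  s <- paste(c(as.character(seed), vapply(list(...), as.character, character(1))),
             collapse = "/")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Configuration of one synthetic fermentation trial
#'
#' Bundles everything the generator needs to emulate one 24 h closed-bottle
#' fermentation: the substrate gas curve for the donor type, the blank
#' (baseline) gas model, bottle counts and masses, ground-truth methane and
#' degradation values, measurement-noise levels and the apparatus physics
#' (10-min recording grid, 0.75 psi vent threshold).
#'
#' Defaults represent the study conditions: 3 substrate bottles and 2 blanks
#' per trial, 0.5 g (+/- 10 mg weighed) dry matter per substrate bottle,
#' donor-type curve shapes and methane/degradation/pH levels at the per-type
#' study means, pressure-sensor noise at the per-reading accuracy of the
#' module (0.1% of a sub-threshold gauge reading, ~0.002 psi), 2 mg weighing
#' noise and 2% GC peak-area noise.
#'
#' @param donor_type `"RF_T"` (fasted heifers) or `"RF_A"` (lactating cows).
#' @param curve A [curve_model()]; defaults to [default_curve()] for the
#'   donor type.
#' @param blank A [blank_model()].
#' @param n_sample_bottles,n_blank_bottles Bottle counts (default 3 and 2).
#' @param substrate_dm_g Nominal incubated dry matter per substrate bottle,
#'   g (default 0.5).
#' @param dm_tolerance_g Half-width of the uniform weighing tolerance on the
#'   incubated mass, g (default 0.010).
#' @param blank_biomass_g True baseline microbial biomass recovered in a
#'   blank residue, g (default 0.05).
#' @param true_ch4_percent True methane concentration of the produced gas.
#' @param true_ddm True degraded dry-matter fraction.
#' @param ph_pre_mean,ph_pre_animal_sd Donor rumen-fluid pH before buffering:
#'   mean and animal-to-animal SD.
#' @param n_donor_animals Donor animals sampled per trial (default 2).
#' @param ph_post_mean,ph_post_sd Filtrate pH after fermentation: mean and
#'   bottle-to-bottle SD.
#' @param noise List with `pressure_sd_psi`, `weighing_sd_g`, `gc_area_cv`.
#' @param gc List with `slope_area_per_pct`, `intercept_area`,
#'   `n_replicates`, `standard_levels` (percent methane of the standard
#'   mixtures).
#' @param empty_bag_g Empty filter-bag mass, g.
#' @param physics A [physics_config()].
#' @param vent_threshold_psi Gauge pressure at which the module vents
#'   (default 0.75).
#' @param grid_interval_min Recording interval, minutes (default 10).
#' @param duration_h Fermentation length, hours (default 24).
#' @return A `trial_config` object.
#' @export
trial_config <- function(donor_type = c("RF_T", "RF_A"),
                         curve = NULL,
                         blank = blank_model(),
                         n_sample_bottles = 3,
                         n_blank_bottles = 2,
                         substrate_dm_g = 0.5,
                         dm_tolerance_g = 0.010,
                         blank_biomass_g = 0.05,
                         true_ch4_percent = NULL,
                         true_ddm = NULL,
                         ph_pre_mean = NULL,
                         ph_pre_animal_sd = 0.02,
                         n_donor_animals = 2,
                         ph_post_mean = NULL,
                         ph_post_sd = 0.01,
                         noise = list(pressure_sd_psi = 0.002,
                                      weighing_sd_g = 0.002,
                                      gc_area_cv = 0.02),
                         gc = list(slope_area_per_pct = 10,
                                   intercept_area = 0,
                                   n_replicates = 2,
                                   standard_levels = c(1, 2.5, 5, 10, 15, 25)),
                         empty_bag_g = 0.5,
                         physics = physics_config(),
                         vent_threshold_psi = 0.75,
                         grid_interval_min = 10,
                         duration_h = 24) {
  donor_type <- match.arg(donor_type)
  if (is.null(curve)) curve <- default_curve(donor_type)
  if (is.null(true_ch4_percent)) true_ch4_percent <- if (donor_type == "RF_T") 9.2 else 9.9
  if (is.null(true_ddm)) true_ddm <- if (donor_type == "RF_T") 0.609 else 0.587
  if (is.null(ph_pre_mean)) ph_pre_mean <- if (donor_type == "RF_T") 7.00 else 5.90
  if (is.null(ph_post_mean)) ph_post_mean <- if (donor_type == "RF_T") 6.85 else 6.71
  if (vent_threshold_psi <= 0) stop_config("`vent_threshold_psi` must be positive")
  sds <- unlist(noise)
  if (any(sds < 0)) stop_config("noise SDs must be non-negative")
  structure(
    list(donor_type = donor_type, curve = curve, blank = blank,
         n_sample_bottles = n_sample_bottles, n_blank_bottles = n_blank_bottles,
         substrate_dm_g = substrate_dm_g, dm_tolerance_g = dm_tolerance_g,
         blank_biomass_g = blank_biomass_g,
         true_ch4_percent = true_ch4_percent, true_ddm = true_ddm,
         ph_pre_mean = ph_pre_mean, ph_pre_animal_sd = ph_pre_animal_sd,
         n_donor_animals = n_donor_animals,
         ph_post_mean = ph_post_mean, ph_post_sd = ph_post_sd,
         noise = noise, gc = gc, empty_bag_g = empty_bag_g,
         physics = physics, vent_threshold_psi = vent_threshold_psi,
         grid_interval_min = grid_interval_min, duration_h = duration_h),
    class = "trial_config")
}

#' Turn off all measurement noise in a trial configuration
#'
#' @param cfg A [trial_config()].
#' @return The configuration with every noise SD and the weighing tolerance
#'   set to zero.
#' @export
noise_free <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  cfg$noise <- list(pressure_sd_psi = 0, weighing_sd_g = 0, gc_area_cv = 0)
  cfg$dm_tolerance_g <- 0
  cfg$ph_pre_animal_sd <- 0
  cfg$ph_post_sd <- 0
  cfg
}

#' Between-trial variation defaults
#'
#' Trial-to-trial perturbations of the generator's per-type means,
#' representing biological variation of the rumen-fluid inoculum across
#' fermentation trials. Values were chosen once so that the simulated
#' repeatability coefficients fall in the low single digits for lactating
#' cows and are a few-fold larger (and largest early in fermentation) for
#' fasted heifers, without targeting any specific printed value.
#'
#' @return Named list (`RF_T`, `RF_A`) of lists with `asymptote_cv`,
#'   `rate_cv`, `ch4_sd`, `ddm_sd`, `ph_pre_sd`, `ph_post_sd`.
#' @export
between_trial_defaults <- function() {
  list(
    RF_T = list(asymptote_cv = 0.02, rate_cv = 0.05, ch4_sd = 0.30,
                ddm_sd = 0.003, ph_pre_sd = 0.015, ph_post_sd = 0.003),
    RF_A = list(asymptote_cv = 0.01, rate_cv = 0.02, ch4_sd = 0.15,
                ddm_sd = 0.003, ph_pre_sd = 0.008, ph_post_sd = 0.003))
}

# Apply one trial's between-trial draws to a base configuration.
perturb_config <- function(cfg, bt, seed, trial_id) {
  withr::with_seed(stable_seed(seed, trial_id, "trial"), {
    cfg$curve$A <- cfg$curve$A * (1 + rnorm(1, 0, bt$asymptote_cv))
    if (cfg$curve$family == "sigmoid") {
      cfg$curve$C <- cfg$curve$C * (1 + rnorm(1, 0, bt$rate_cv))
    } else {
      cfg$curve$k <- cfg$curve$k * (1 + rnorm(1, 0, bt$rate_cv))
    }
    cfg$true_ch4_percent <- max(0.1, cfg$true_ch4_percent + rnorm(1, 0, bt$ch4_sd))
    cfg$true_ddm <- cfg$true_ddm + rnorm(1, 0, bt$ddm_sd)
    cfg$ph_pre_mean <- cfg$ph_pre_mean + rnorm(1, 0, bt$ph_pre_sd)
    cfg$ph_post_mean <- cfg$ph_post_mean + rnorm(1, 0, bt$ph_post_sd)
    cfg
  })
}

#' Simulate one fermentation bottle
#'
#' Generates a bottle's pressure record from its true gas curve. The true
#' cumulative gas (substrate curve scaled by the weighed dry matter plus the
#' baseline blank gas for substrate bottles; baseline gas alone for blanks)
#' is converted to headspace gauge pressure through the inverse ideal-gas
#' conversion. Whenever the instantaneous gauge pressure reaches the vent
#' threshold at a recording step, the module vents: the released amount is
#' added to the gas bag and to the cumulative register, and the
#' instantaneous pressure drops to zero. Gaussian sensor noise is added to
#' the recorded pressures and the cumulative record is forced non-decreasing
#' (as the logging software does). Venting conserves gas exactly: the
#' cumulative register always equals released plus current gas.
#'
#' The returned ground truth includes the weighed mass, total vented
#' pressure, final instantaneous pressure and the noise-free cumulative gas.
#'
#' @param cfg A [trial_config()].
#' @param role `"sample"` or `"blank"`.
#' @param bottle_id,trial_id Labels.
#' @param seed Base integer seed (the bottle's stream is derived from
#'   `(seed, trial_id, bottle_id)` via [stable_seed()]).
#' @return A list: `series` (tibble `time_min`, `abs_pressure_psi`,
#'   `cum_pressure_psi`), `role`, `dm_g`, `residue_g`, `bag_areas` (samples
#'   only), `vent_total_psi`, `final_inst_psi`, `n_vents`, `true_total_ml`.
#' @export
simulate_bottle <- function(cfg, role = c("sample", "blank"),
                            bottle_id = "S1", trial_id = "T01", seed = 1) {
  stopifnot(inherits(cfg, "trial_config"))
  role <- match.arg(role)
  withr::with_seed(stable_seed(seed, trial_id, bottle_id), {
    grid <- seq(0, cfg$duration_h * 60, by = cfg$grid_interval_min)
    t_h <- grid / 60
    dm <- if (role == "sample") {
      cfg$substrate_dm_g +
        if (cfg$dm_tolerance_g > 0) runif(1, -cfg$dm_tolerance_g, cfg$dm_tolerance_g) else 0
    } else 0
    baseline_ml <- blank_value(cfg$blank, t_h)
    total_ml <- if (role == "sample") {
      dm * curve_value(cfg$curve, t_h) + baseline_ml
    } else baseline_ml
    g_psi <- ml_stp_to_psi(total_ml, cfg$physics)

    vented <- 0
    inst <- numeric(length(grid))
    n_vents <- 0L
    for (i in seq_along(grid)) {
      cur <- g_psi[i] - vented
      if (cur >= cfg$vent_threshold_psi) {
        vented <- vented + cur
        n_vents <- n_vents + 1L
        cur <- 0
      }
      inst[i] <- cur
    }

    sd_p <- cfg$noise$pressure_sd_psi
    cum_rec <- g_psi
    abs_rec <- inst
    if (sd_p > 0) {
      cum_rec <- cum_rec + rnorm(length(grid), 0, sd_p)
      abs_rec <- abs_rec + rnorm(length(grid), 0, sd_p)
    }
    cum_rec[1] <- 0 # register starts at zero
    cum_rec <- cummax(cum_rec)

    residue <- (if (role == "sample") (1 - cfg$true_ddm) * dm else 0) +
      cfg$blank_biomass_g +
      if (cfg$noise$weighing_sd_g > 0) rnorm(1, 0, cfg$noise$weighing_sd_g) else 0
    residue <- max(0, residue)

    bag_areas <- NULL
    if (role == "sample") {
      true_area <- cfg$gc$intercept_area +
        cfg$gc$slope_area_per_pct * cfg$true_ch4_percent
      mult <- if (cfg$noise$gc_area_cv > 0) {
        1 + rnorm(cfg$gc$n_replicates, 0, cfg$noise$gc_area_cv)
      } else rep(1, cfg$gc$n_replicates)
      bag_areas <- true_area * mult
    }

    list(series = tibble::tibble(time_min = grid,
                                 abs_pressure_psi = abs_rec,
                                 cum_pressure_psi = cum_rec),
         role = role, bottle_id = bottle_id, trial_id = trial_id,
         dm_g = dm, residue_g = residue, bag_areas = bag_areas,
         vent_total_psi = vented, final_inst_psi = inst[length(inst)],
         n_vents = n_vents, true_total_ml = total_ml)
  })
}

# Analytic expected pipeline output for one trial: the blank-corrected
# per-gram curve each sample bottle should yield in the noise-free limit,
# summarised with the same nonparametric definitions the analysis uses.
trial_truth <- function(cfg, dms, trial_id) {
  grid <- seq(0, cfg$duration_h * 60, by = cfg$grid_interval_min)
  t_h <- grid / 60
  bl <- blank_value(cfg$blank, t_h)
  pk <- which.max(cummax(bl)) # recorded blank peaks where the true blank does
  peak <- bl[pk]
  per_bottle <- lapply(dms, function(dm) {
    corr <- ifelse(seq_along(grid) <= pk, bl, peak)
    gas_curve(grid, curve_value(cfg$curve, t_h) + (bl - corr) / dm,
              trial_id = trial_id)
  })
  params <- dplyr::bind_rows(lapply(per_bottle, curve_parameters,
                                    end_hour = cfg$duration_h))
  out <- tibble::as_tibble(as.list(colMeans(
    params[vapply(params, is.numeric, logical(1))])))
  out$trial_id <- trial_id
  out$donor_type <- cfg$donor_type
  out$ch4_percent <- cfg$true_ch4_percent
  out$ch4_yield <- out$tgp_end * cfg$true_ch4_percent / 100
  out$ddm <- cfg$true_ddm
  out$ph_pre <- cfg$ph_pre_mean
  out$ph_post <- cfg$ph_post_mean
  dplyr::relocate(out, "trial_id", "donor_type")
}

#' Simulate one complete fermentation trial
#'
#' Generates all bottles of a trial plus the trial's metadata (donor pH
#' draws), GC standard-curve injections and ground truth. Randomness is
#' fully determined by `seed` and the trial/bottle labels.
#'
#' @param cfg A [trial_config()].
#' @param trial_id Trial label.
#' @param seed Base integer seed.
#' @return A list with `trial_id`, `donor_type`, `meta` (list for the YAML
#'   metadata file), `pressure` (long tibble over all bottles), `bottles`,
#'   `residues`, `gc_standards`, `gc_bags` (tibbles), and `truth` (one-row
#'   tibble of expected pipeline output).
#' @export
simulate_trial <- function(cfg, trial_id = "T01", seed = 1) {
  stopifnot(inherits(cfg, "trial_config"))
  ids <- c(paste0(trial_id, "_S", seq_len(cfg$n_sample_bottles)),
           paste0(trial_id, "_B", seq_len(cfg$n_blank_bottles)))
  roles <- rep(c("sample", "blank"),
               c(cfg$n_sample_bottles, cfg$n_blank_bottles))
  bottles <- purrr::map2(ids, roles, function(id, role) {
    simulate_bottle(cfg, role, bottle_id = id, trial_id = trial_id, seed = seed)
  })

  pressure <- dplyr::bind_rows(lapply(bottles, function(b) {
    dplyr::mutate(b$series, bottle_id = b$bottle_id, .before = 1)
  }))
  bottle_tbl <- tibble::tibble(
    trial_id = trial_id,
    bottle_id = ids,
    role = roles,
    substrate_dm_g = vapply(bottles, `[[`, numeric(1), "dm_g"))
  residues <- tibble::tibble(
    trial_id = trial_id,
    bottle_id = ids,
    empty_bag_g = cfg$empty_bag_g,
    bag_after_g = cfg$empty_bag_g + vapply(bottles, `[[`, numeric(1), "residue_g"))
  gc_bags <- dplyr::bind_rows(lapply(bottles, function(b) {
    if (is.null(b$bag_areas)) return(NULL)
    tibble::tibble(trial_id = trial_id, bottle_id = b$bottle_id,
                   replicate = seq_along(b$bag_areas), area = b$bag_areas)
  }))

  meta <- withr::with_seed(stable_seed(seed, trial_id, "meta"), {
    list(trial_id = trial_id,
         donor_type = cfg$donor_type,
         rumen_ph_pre = as.numeric(
           cfg$ph_pre_mean + rnorm(cfg$n_donor_animals, 0, cfg$ph_pre_animal_sd)),
         filtrate_ph_post = as.numeric(
           cfg$ph_post_mean + rnorm(cfg$n_sample_bottles, 0, cfg$ph_post_sd)),
         incubation_temp_c = cfg$physics$incubation_temp_C,
         ambient_pressure_kpa = cfg$physics$ambient_pressure_kPa,
         headspace_ml = cfg$physics$headspace_ml)
  })

  gc_standards <- withr::with_seed(stable_seed(seed, trial_id, "gc"), {
    lv <- cfg$gc$standard_levels
    reps <- cfg$gc$n_replicates
    pct <- rep(lv, each = reps)
    true_area <- cfg$gc$intercept_area + cfg$gc$slope_area_per_pct * pct
    mult <- if (cfg$noise$gc_area_cv > 0) {
      1 + rnorm(length(pct), 0, cfg$noise$gc_area_cv)
    } else rep(1, length(pct))
    tibble::tibble(trial_id = trial_id, ch4_percent = pct,
                   replicate = rep(seq_len(reps), times = length(lv)),
                   area = true_area * mult)
  })

  dms <- bottle_tbl$substrate_dm_g[bottle_tbl$role == "sample"]
  truth <- trial_truth(cfg, dms, trial_id)

  list(trial_id = trial_id, donor_type = cfg$donor_type, meta = meta,
       pressure = pressure, bottles = bottle_tbl, residues = residues,
       gc_standards = gc_standards, gc_bags = gc_bags, truth = truth)
}

#' Simulate a complete repeatability study and write its input files
#'
#' Generates the unbalanced two-donor study design - by default 5 trials
#' with fasted-heifer fluid (RF_T) and 12 with lactating-cow fluid (RF_A) -
#' applying between-trial variation on top of the per-type base
#' configurations, and writes the canonical input files that
#' [run_pipeline()] reads: per-trial pressure logs and metadata plus the
#' study-level bottle, residue and GC tables. Ground truth goes to a
#' separate file the pipeline never reads.
#'
#' @param out_dir Directory to write into (created if missing).
#' @param seed Base integer seed; all randomness derives from it.
#' @param rf_t_trials,rf_a_trials Trial counts per donor type (default 5
#'   and 12).
#' @param base_configs Named list (`RF_T`, `RF_A`) of [trial_config()]s.
#' @param between_trial Named list of between-trial variation settings; see
#'   [between_trial_defaults()].
#' @return Invisibly, a list with `dir`, `manifest` (tibble) and
#'   `ground_truth` (tibble).
#' @export
simulate_study <- function(out_dir, seed = 1,
                           rf_t_trials = 5, rf_a_trials = 12,
                           base_configs = list(RF_T = trial_config("RF_T"),
                                               RF_A = trial_config("RF_A")),
                           between_trial = between_trial_defaults()) {
  dir.create(file.path(out_dir, "pressure"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "meta"), recursive = TRUE, showWarnings = FALSE)
  plan <- tibble::tibble(
    trial_id = c(sprintf("T%02d", seq_len(rf_t_trials)),
                 sprintf("A%02d", seq_len(rf_a_trials))),
    donor_type = rep(c("RF_T", "RF_A"), c(rf_t_trials, rf_a_trials)))

  trials <- purrr::pmap(plan, function(trial_id, donor_type) {
    cfg <- perturb_config(base_configs[[donor_type]],
                          between_trial[[donor_type]], seed, trial_id)
    simulate_trial(cfg, trial_id = trial_id, seed = seed)
  })

  manifest <- tibble::tibble(
    trial_id = plan$trial_id,
    donor_type = plan$donor_type,
    pressure_file = file.path("pressure", paste0(plan$trial_id, ".csv")),
    meta_file = file.path("meta", paste0(plan$trial_id, ".yaml")))

  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    readr::write_csv(tr$pressure, file.path(out_dir, manifest$pressure_file[i]))
    yaml::write_yaml(tr$meta, file.path(out_dir, manifest$meta_file[i]),
                     precision = 15)
  }
  collect <- function(name) dplyr::bind_rows(lapply(trials, `[[`, name))
  readr::write_csv(collect("bottles"), file.path(out_dir, "bottles.csv"))
  readr::write_csv(collect("residues"), file.path(out_dir, "residues.csv"))
  readr::write_csv(collect("gc_standards"), file.path(out_dir, "gc_standards.csv"))
  readr::write_csv(collect("gc_bags"), file.path(out_dir, "gc_bags.csv"))
  ground_truth <- collect("truth")
  readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  invisible(list(dir = out_dir, manifest = manifest, ground_truth = ground_truth))
}
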