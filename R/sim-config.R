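#' Treatments of the 2 x 2 heat-by-drought factorial
#'
#' The experimental design crosses two temperature levels (average vs high)
#' with two watering levels (average vs low), giving four treatment cells:
#' `control` (avg temperature, avg watering), `heat` (high temperature),
#' `drought` (low watering), and `heat_drought` (both stressors).
#'
#' @return Character vector of the four treatment labels, in fixed order.
#' @export
treatment_levels <- function() c("control", "heat", "drought", "heat_drought")

#' Map a treatment to its fitness measure
#'
#' Fitness proxies differ across treatment cells: flowering propensity is
#' informative only where plants actually flower (benign conditions),
#' survival discriminates under single stress, and longevity (days until
#' death or harvest) is the only graded measure left when most plants die
#' under combined stress. The mapping is fixed: `control` -> `flowered`,
#' `heat` -> `survived`, `drought` -> `survived`,
#' `heat_drought` -> `longevity`.
#'
#' @param treatment One of [treatment_levels()].
#' @return One of `"flowered"`, `"survived"`, `"longevity"`.
#' @export
fitness_measure_for_treatment <- function(treatment) {
  treatment <- match.arg(treatment, treatment_levels())
  switch(treatment,
    control      = "flowered",
    heat         = "survived",
    drought      = "survived",
    heat_drought = "longevity"
  )
}

trait_names <- function() {
  c("size", "x_mid", "growth_rate", "SLA", "LDMC", "root_shoot")
}

log10_traits <- function() c("growth_rate", "root_shoot", "SLA", "LDMC")

default_growth_params <- function() {
  # Per-treatment three-parameter logistic truth: asymptote A (mm^2),
  # inflection day x_mid, scale (days). Means follow the factorial pattern
  # of smaller, earlier-peaking rosettes under stress, worst under the
  # combination; sds give realistic between-plant spread.
  list(
    control      = list(A = c(1465, 180), x_mid = c(27.1, 2.0), scal = c(4.0, 0.5)),
    heat         = list(A = c(1256, 170), x_mid = c(25.6, 2.0), scal = c(3.8, 0.5)),
    drought      = list(A = c(1091, 160), x_mid = c(25.7, 2.0), scal = c(3.8, 0.5)),
    heat_drought = list(A = c(820, 140),  x_mid = c(21.9, 2.0), scal = c(3.4, 0.5))
  )
}

default_mortality <- function() {
  # Probability of dying before harvest. Single stress roughly quadruples
  # baseline mortality; combined stress is worse than additive on the
  # logit scale (interaction well below zero).
  c(control = 0.03, heat = 0.13, drought = 0.16, heat_drought = 0.93)
}

default_trait_targets <- function() {
  # Target means of the harvest-derived functional traits per treatment:
  # SLA mm^2/mg, LDMC mg/g, root:shoot dimensionless. Stress lowers LDMC
  # and raises root:shoot; combined stress markedly raises SLA.
  list(
    control      = list(SLA = 11.0, LDMC = 288, root_shoot = 1.35),
    heat         = list(SLA = 12.9, LDMC = 251, root_shoot = 1.55),
    drought      = list(SLA = 9.3,  LDMC = 263, root_shoot = 1.51),
    heat_drought = list(SLA = 37.2, LDMC = 229, root_shoot = 1.78)
  )
}

default_flowering_intercept <- function() {
  # Logit-scale flowering propensity per treatment: common under benign
  # watering, rare under heat, absent-to-rare under combined stress.
  c(control = 0.9, heat = -4.0, drought = 0.2, heat_drought = -6.0)
}

#' Configuration of a synthetic factorial stress experiment
#'
#' Bundles every knob of the synthetic-data generator: the hierarchical
#' design (populations, seed families nested in populations, blocks,
#' 54-pot trays with every second pot used), per-treatment growth-curve
#' parameter distributions, observation noise, per-treatment mortality,
#' harvest trait targets with family-level variance, and the selection
#' coefficients under which fitness is generated.
#'
#' @param n_populations Number of populations (default 5; the first is
#'   treated as the large central population, the last two as southern
#'   range-edge populations).
#' @param families_per_population Seed families per population. Either a
#'   single count or a vector of length `n_populations`. The default gives
#'   the central population many more families than the edges, mirroring a
#'   design in which only the central population supports selection
#'   analysis.
#' @param blocks_per_treatment Spatial blocks per treatment cell, each with
#'   one replicate seed per family (default 5).
#' @param growth Per-treatment list of three-parameter logistic truth
#'   distributions, each entry `list(A = c(mean, sd), x_mid = c(mean, sd),
#'   scal = c(mean, sd))` (units mm^2, days, days).
#' @param noise_sd Gaussian observation noise on rosette area (mm^2).
#' @param imaging_interval Days between consecutive images (default 3.5,
#'   i.e. twice weekly).
#' @param duration Days from germination to harvest (default 70).
#' @param mortality Named per-treatment probability of death before
#'   harvest.
#' @param southern_combined_logit Additive offset on the survival logit for
#'   southern populations in the combined-stress cell (positive = better
#'   survival; default 2.5). Encodes local adaptation of the warm-edge
#'   populations.
#' @param trait_targets Per-treatment target means for SLA (mm^2/mg),
#'   LDMC (mg/g) and root:shoot.
#' @param family_sd_log10 Family-level random-effect sd of the functional
#'   traits on the log10 scale (default 0.05).
#' @param trait_noise_log10 Residual plant-level sd of the functional
#'   traits on the log10 scale (default 0.05).
#' @param family_growth_sd Family-level random-effect sd on the growth
#'   asymptote, as a fraction of the treatment mean (default 0.05).
#' @param selection_beta Named numeric vector of selection coefficients on
#'   the six standardized traits (`size`, `x_mid`, `growth_rate`, `SLA`,
#'   `LDMC`, `root_shoot`). Applied on the logit scale for binary fitness
#'   and, scaled by `longevity_sd`, on the mean of longevity. Default all
#'   zero (no selection).
#' @param flowering_intercept Named per-treatment logit-scale intercept of
#'   flowering propensity.
#' @param longevity_sd Residual sd of longevity (days, default 8).
#' @param weight_floor_mg Lower floor for generated dry weights (mg,
#'   default 0.1) so ratios stay positive and log-transformable.
#' @param tray_rows,tray_cols Tray grid (default 6 x 9 = 54 pots).
#' @param cell_px Side length of one pot cell in pixels in rendered images
#'   (default 40).
#' @param scale_mm_per_px Image calibration, millimetres per pixel
#'   (default 1.25).
#' @param growth_model Generating growth model, one of the seven candidate
#'   model names (default `"logistic3"`). Non-logistic generators reuse
#'   the logistic parameter draws mapped onto the target model's natural
#'   parameters, for model-selection power experiments.
#' @param seed Integer RNG seed; all generator output is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_experiment()], [simulate_growth_series()],
#'   [simulate_harvest_and_fitness()]
#' @export
sim_config <- function(n_populations = 5,
                       families_per_population = c(20, 3, 3, 3, 3),
                       blocks_per_treatment = 5,
                       growth = default_growth_params(),
                       noise_sd = 30,
                       imaging_interval = 3.5,
                       duration = 70,
                       mortality = default_mortality(),
                       southern_combined_logit = 2.5,
                       trait_targets = default_trait_targets(),
                       family_sd_log10 = 0.05,
                       trait_noise_log10 = 0.05,
                       family_growth_sd = 0.05,
                       selection_beta = c(size = 0, x_mid = 0, growth_rate = 0,
                                          SLA = 0, LDMC = 0, root_shoot = 0),
                       flowering_intercept = default_flowering_intercept(),
                       longevity_sd = 8,
                       weight_floor_mg = 0.1,
                       tray_rows = 6, tray_cols = 9,
                       cell_px = 40, scale_mm_per_px = 1.25,
                       growth_model = "logistic3",
                       seed = 1L) {
  if (length(families_per_population) == 1) {
    families_per_population <- rep(families_per_population, n_populations)
  }
  cfg <- structure(list(
    n_populations = as.integer(n_populations),
    families_per_population = as.integer(families_per_population),
    blocks_per_treatment = as.integer(blocks_per_treatment),
    treatments = treatment_levels(),
    growth = growth,
    noise_sd = noise_sd,
    imaging_interval = imaging_interval,
    duration = duration,
    mortality = mortality,
    southern_combined_logit = southern_combined_logit,
    trait_targets = trait_targets,
    family_sd_log10 = family_sd_log10,
    trait_noise_log10 = trait_noise_log10,
    family_growth_sd = family_growth_sd,
    selection_beta = selection_beta,
    flowering_intercept = flowering_intercept,
    longevity_sd = longevity_sd,
    weight_floor_mg = weight_floor_mg,
    tray_rows = as.integer(tray_rows),
    tray_cols = as.integer(tray_cols),
    cell_px = as.integer(cell_px),
    scale_mm_per_px = scale_mm_per_px,
    growth_model = growth_model,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_populations < 1) stopf("need at least one population")
  if (length(cfg$families_per_population) != cfg$n_populations) {
    stopf("families_per_population must have length 1 or n_populations")
  }
  if (any(cfg$families_per_population < 1)) {
    stopf("every population needs at least one family")
  }
  if (cfg$blocks_per_treatment < 1) stopf("need at least one block per treatment")
  if (!identical(sort(cfg$treatments), sort(treatment_levels()))) {
    stopf("treatments must be the four cells of the 2x2 factorial")
  }
  for (tr in cfg$treatments) {
    g <- cfg$growth[[tr]]
    if (is.null(g)) stopf("growth parameters missing for treatment '%s'", tr)
    for (p in c("A", "x_mid", "scal")) {
      if (length(g[[p]]) != 2 || g[[p]][2] < 0) {
        stopf("growth$%s$%s must be c(mean, sd) with sd >= 0", tr, p)
      }
    }
    if (g$A[1] <= 0 || g$scal[1] <= 0) stopf("growth means A and scal must be > 0")
  }
  if (cfg$noise_sd < 0 || cfg$family_sd_log10 < 0 || cfg$trait_noise_log10 < 0 ||
      cfg$family_growth_sd < 0 || cfg$longevity_sd < 0) {
    stopf("all standard deviations must be >= 0")
  }
  if (cfg$imaging_interval <= 0) stopf("imaging_interval must be > 0")
  if (cfg$duration <= 0) stopf("duration must be > 0")
  m <- cfg$mortality[treatment_levels()]
  if (anyNA(m) || any(m < 0 | m > 1)) {
    stopf("mortality must give a probability in [0, 1] for each treatment")
  }
  if (!cfg$growth_model %in% growth_model_names()) {
    stopf("unknown growth model '%s'", cfg$growth_model)
  }
  if (!all(trait_names() %in% names(cfg$selection_beta))) {
    stopf("selection_beta must name all six traits")
  }
  if (cfg$scale_mm_per_px <= 0) stopf("scale_mm_per_px must be > 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  n_fam <- sum(x$families_per_population)
  cat("<sim_config>\n")
  cat(sprintf("  %d populations, %d families total, %d blocks/treatment\n",
              x$n_populations, n_fam, x$blocks_per_treatment))
  cat(sprintf("  %d plants across the 2x2 factorial\n",
              n_fam * x$blocks_per_treatment * 4L))
  cat(sprintf("  growth model: %s; imaging every %.1f d for %.0f d; noise sd %.1f mm^2\n",
              x$growth_model, x$imaging_interval, x$duration, x$noise_sd))
  cat(sprintf("  mortality: %s\n",
              paste(sprintf("%s %.2f", names(x$mortality), x$mortality),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
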