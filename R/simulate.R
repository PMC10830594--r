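# Synthetic factorial stress experiments with known ground truth.
#
# The generator reproduces the structure of a greenhouse study: a 2x2
# heat-by-drought factorial, populations with seed families nested inside
# them, spatial blocks holding one replicate seed per family, 54-pot trays
# of which every second pot is used, sigmoid rosette growth imaged twice
# weekly, stress-dependent mortality that is worse than additive under
# combined stress, harvest weights consistent with target functional
# traits, and fitness generated under known selection coefficients.

pop_labels <- function(n) {
  if (n == 5) c("C", "NE", "NW", "SE", "SW") else paste0("P", seq_len(n))
}

# Southern (warm range-edge) populations: the last two labels.
southern_pops <- function(pops) utils::tail(pops, 2)

#' Simulate the design and ground truth of a factorial stress experiment
#'
#' Lays out every plant of the experiment (population, family nested in
#' population, treatment, block, tray, pot on the every-second-pot
#' checkerboard), draws each plant's true growth-curve parameters and
#' true functional trait values, and draws survival and day of death.
#' Mortality follows the per-treatment probabilities in the
#' configuration on the logit scale, with the southern populations given
#' a survival advantage in the combined-stress cell, and with the
#' configured selection coefficients shifting the survival logit in
#' treatments whose fitness measure is survival. The day of death of
#' non-survivors is drawn from a geometric hazard over imaging steps,
#' except under combined stress where it is Gaussian around a linear
#' predictor so that longevity carries the configured selection signal.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_experiment`: a list with
#'   `plants` (design + fate skeleton, one row per plant),
#'   `truth` (true growth parameters and pre-noise trait values), and
#'   `config`. Identical configurations (including seed) give identical
#'   output.
#' @export
simulate_experiment <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  pops <- pop_labels(config$n_populations)
  fams <- unlist(lapply(seq_along(pops), function(i) {
    paste0(pops[i], "_f", seq_len(config$families_per_population[i]))
  }))
  fam_pop <- rep(pops, config$families_per_population)

  design <- expand.grid(
    family = fams, block = seq_len(config$blocks_per_treatment),
    treatment = treatment_levels(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  design$population <- fam_pop[match(design$family, fams)]
  design <- design[order(design$treatment, design$block, design$family), ]
  design$plant <- seq_len(nrow(design))

  # Tray/pot assignment: within treatment x block, plants fill trays of
  # usable (checkerboard) pots in randomized order.
  layout <- pot_layout(config$tray_rows, config$tray_cols, config$cell_px)
  used_pots <- layout$cells$pot[layout$cells$used]
  design$tray <- NA_character_
  design$pot <- NA_integer_
  for (key in unique(paste(design$treatment, design$block))) {
    idx <- which(paste(design$treatment, design$block) == key)
    ord <- with_seed(substream_seed(config$seed, 900000 + idx[1]), sample(idx))
    n_tray <- ceiling(length(ord) / length(used_pots))
    slots <- rep(seq_len(n_tray), each = length(used_pots))[seq_along(ord)]
    design$tray[ord] <- paste0(gsub(" ", "_b", key), "_t", slots)
    design$pot[ord] <- rep(used_pots, n_tray)[seq_along(ord)]
  }

  # Family-level random effects, one draw per family shared across
  # treatments: a multiplicative effect on the growth asymptote and
  # log10-scale shifts of the three functional traits.
  fam_eff <- with_seed(substream_seed(config$seed, 1), {
    data.frame(
      family = fams,
      gA = stats::rnorm(length(fams), 0, config$family_growth_sd),
      SLA = stats::rnorm(length(fams), 0, config$family_sd_log10),
      LDMC = stats::rnorm(length(fams), 0, config$family_sd_log10),
      root_shoot = stats::rnorm(length(fams), 0, config$family_sd_log10)
    )
  })

  n <- nrow(design)
  truth <- data.frame(plant = design$plant, A = NA_real_, x_mid = NA_real_,
                      scal = NA_real_)
  germ <- integer(n)
  for (i in seq_len(n)) {
    g <- config$growth[[design$treatment[i]]]
    fe <- fam_eff[fam_eff$family == design$family[i], ]
    draws <- with_seed(substream_seed(config$seed, design$plant[i]), {
      c(A = stats::rnorm(1, g$A[1], g$A[2]) * (1 + fe$gA),
        x_mid = stats::rnorm(1, g$x_mid[1], g$x_mid[2]),
        scal = stats::rnorm(1, g$scal[1], g$scal[2]),
        germ = stats::rpois(1, 5))
    })
    truth$A[i] <- max(draws[["A"]], 10)
    truth$x_mid[i] <- max(draws[["x_mid"]], 1)
    truth$scal[i] <- max(draws[["scal"]], 0.5)
    germ[i] <- min(draws[["germ"]], 14L)
  }
  design$germ_day <- germ

  # True (pre-noise) trait values: growth traits from the curve
  # parameters, functional traits from the per-treatment targets shifted
  # by the family effects on the log10 scale.
  truth$size <- truth$A
  truth$growth_rate <- truth$A / (4 * truth$scal)
  for (tn in c("SLA", "LDMC", "root_shoot")) {
    tgt <- vapply(design$treatment,
                  function(tr) config$trait_targets[[tr]][[tn]], numeric(1))
    truth[[tn]] <- tgt * 10^fam_eff[[tn]][match(design$family, fams)]
  }

  # Survival: per-treatment mortality on the logit scale, a southern
  # advantage under combined stress, and the selection coefficients
  # applied to within-treatment standardized true traits when the
  # treatment's fitness measure is survival.
  design$survived <- NA
  design$death_day <- NA_real_
  n_steps <- max(floor(config$duration / config$imaging_interval), 1)
  for (tr in treatment_levels()) {
    idx <- which(design$treatment == tr)
    z <- sapply(trait_names(), function(tn) {
      v <- if (tn == "x_mid") truth$x_mid[idx] else truth[[tn]][idx]
      z <- zscore(v); z[is.na(z)] <- 0; z
    })
    lp <- rep(logit(1 - config$mortality[[tr]]), length(idx))
    if (tr == "heat_drought") {
      lp <- lp + ifelse(design$population[idx] %in% southern_pops(pop_labels(config$n_populations)),
                        config$southern_combined_logit, 0)
    }
    if (fitness_measure_for_treatment(tr) == "survived") {
      lp <- lp + drop(z %*% config$selection_beta[trait_names()])
    }
    p_surv <- inv_logit(lp)
    bz <- drop(z %*% config$selection_beta[trait_names()])
    for (k in seq_along(idx)) {
      i <- idx[k]
      draws <- with_seed(substream_seed(config$seed, 300000 + design$plant[i]), {
        u <- stats::runif(1)
        step <- 1 + stats::rgeom(1, prob = max(config$mortality[[tr]], 0.02) / n_steps)
        gaus <- stats::rnorm(1)
        c(u = u, step = step, gaus = gaus)
      })
      design$survived[i] <- draws[["u"]] < p_surv[k]
      if (!design$survived[i]) {
        if (fitness_measure_for_treatment(tr) == "longevity") {
          # graded death time carrying the selection signal
          mu <- config$duration / 3 + config$longevity_sd * bz[k]
          design$death_day[i] <- min(max(mu + config$longevity_sd * draws[["gaus"]],
                                         config$imaging_interval), config$duration)
        } else {
          design$death_day[i] <- min(draws[["step"]], n_steps) * config$imaging_interval
        }
      }
    }
  }
  design$longevity <- ifelse(design$survived, config$duration, design$death_day)

  cols <- c("plant", "population", "family", "treatment", "block", "tray",
            "pot", "germ_day", "survived", "death_day", "longevity")
  structure(list(plants = design[, cols], truth = truth, config = config,
                 layout = layout),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d plants, %d populations, seed %d\n",
              nrow(x$plants), x$config$n_populations, x$config$seed))
  print(table(x$plants$treatment, x$plants$survived))
  invisible(x)
}

#' Simulate rosette area time series
#'
#' Evaluates the generating growth model on the twice-weekly imaging grid,
#' adds Gaussian observation noise, clips at zero (a rosette cannot have
#' negative area), and truncates each series at the plant's day of death.
#'
#' @param state One or more rows of the `truth` table from
#'   [simulate_experiment()] (needs columns `plant`, `A`, `x_mid`,
#'   `scal`), or any data frame with those columns. A `death_day` column
#'   (or one merged from the experiment's `plants` table via
#'   `death_day`) truncates the series.
#' @param config A [sim_config()]; supplies imaging interval, duration,
#'   observation noise, generating model and seed.
#' @param death_day Optional numeric vector (one per row of `state`)
#'   overriding/absent death days; `NA` means the plant lived to harvest.
#' @return Long-format data frame `plant`, `day`, `area_mm2`.
#' @export
simulate_growth_series <- function(state, config = sim_config(),
                                   death_day = NULL) {
  if (config$imaging_interval <= 0) stopf("imaging interval must be > 0")
  state <- as.data.frame(state)
  if (is.null(death_day)) {
    death_day <- if ("death_day" %in% names(state)) state$death_day
                 else rep(NA_real_, nrow(state))
  }
  days <- seq(0, config$duration, by = config$imaging_interval)
  out <- vector("list", nrow(state))
  for (i in seq_len(nrow(state))) {
    d <- if (is.na(death_day[i])) days else days[days <= death_day[i]]
    pars <- growth_truth_params(config$growth_model, state$A[i],
                                state$x_mid[i], state$scal[i], config$duration)
    mu <- growth_model_mean(config$growth_model, d, pars)
    noise <- if (config$noise_sd > 0) {
      with_seed(substream_seed(config$seed, 600000 + state$plant[i]),
                stats::rnorm(length(d), 0, config$noise_sd))
    } else 0
    out[[i]] <- data.frame(plant = state$plant[i], day = d,
                           area_mm2 = pmax(mu + noise, 0))
  }
  do.call(rbind, out)
}

#' Simulate harvest weights and fitness outcomes
#'
#' For surviving plants, generates fresh and dry weights of living
#' leaves, roots and inflorescences consistent with the configured target
#' SLA, LDMC and root:shoot (family effects are already part of the true
#' trait values; plant-level log10-scale noise is added here). Dry
#' weights are floored at the configured minimum so downstream ratios
#' remain positive. Plants that died before harvest have no living-leaf
#' measurements (`NA` weights), mirroring a real harvest. Flowering is
#' drawn Bernoulli with success probability the inverse logit of the
#' treatment's flowering intercept plus the selection coefficients on
#' standardized true traits (in the treatment whose fitness measure is
#' flowering); dead plants do not flower. Longevity is days until death
#' or harvest.
#'
#' @param sim A `sim_experiment` from [simulate_experiment()].
#' @param config A [sim_config()]; defaults to the one inside `sim`.
#' @return Data frame, one row per plant: `plant`, `rosette_area_mm2`,
#'   `leaf_fresh_g`, `leaf_dry_mg`, `dead_leaf_dry_mg`, `root_dry_mg`,
#'   `infl_dry_mg`, `flowered`, `survived`, `longevity_days`.
#' @export
simulate_harvest_and_fitness <- function(sim, config = sim$config) {
  plants <- sim$plants
  truth <- sim$truth
  stopifnot(all(is.finite(truth$A)))
  n <- nrow(plants)
  out <- data.frame(plant = plants$plant, rosette_area_mm2 = NA_real_,
                    leaf_fresh_g = NA_real_, leaf_dry_mg = NA_real_,
                    dead_leaf_dry_mg = 0, root_dry_mg = NA_real_,
                    infl_dry_mg = NA_real_, flowered = 0L,
                    survived = as.integer(plants$survived),
                    longevity_days = plants$longevity)

  # flowering probability per treatment (selection acts where the
  # fitness measure is flowering propensity)
  p_flower <- numeric(n)
  for (tr in treatment_levels()) {
    idx <- which(plants$treatment == tr)
    lp <- rep(config$flowering_intercept[[tr]], length(idx))
    if (fitness_measure_for_treatment(tr) == "flowered") {
      z <- sapply(trait_names(), function(tn) {
        z <- zscore(truth[[tn]][idx]); z[is.na(z)] <- 0; z
      })
      lp <- lp + drop(z %*% config$selection_beta[trait_names()])
    }
    p_flower[idx] <- inv_logit(lp)
  }

  for (i in seq_len(n)) {
    draws <- with_seed(substream_seed(config$seed, 450000 + plants$plant[i]), {
      list(noise = stats::rnorm(4, 0, config$trait_noise_log10),
           area_jit = stats::rnorm(1, 0, 0.02),
           u_flower = stats::runif(1))
    })
    if (plants$survived[i]) {
      area <- truth$A[i] * (1 + draws$area_jit)
      sla <- truth$SLA[i] * 10^draws$noise[1]
      ldmc <- truth$LDMC[i] * 10^draws$noise[2]
      rs <- truth$root_shoot[i] * 10^draws$noise[3]
      leaf_dry <- max(area / sla, config$weight_floor_mg)     # mg
      leaf_fresh <- leaf_dry / ldmc                           # g (LDMC mg/g)
      flowered <- draws$u_flower < p_flower[i]
      infl <- if (flowered) max(0.2 * leaf_dry * 10^draws$noise[4],
                                config$weight_floor_mg) else 0
      root <- max(rs * (leaf_dry + infl), config$weight_floor_mg)
      out$rosette_area_mm2[i] <- area
      out$leaf_fresh_g[i] <- leaf_fresh
      out$leaf_dry_mg[i] <- leaf_dry
      out$root_dry_mg[i] <- root
      out$infl_dry_mg[i] <- infl
      out$flowered[i] <- as.integer(flowered)
    }
  }
  out
}

#' Run the full synthetic study
#'
#' Convenience wrapper: design + truth, growth series for every plant,
#' and harvest/fitness outcomes, all from one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `plants`, `truth`, `areas`, `harvest`, `config`,
#'   `layout`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_experiment(config)
  truth_dd <- merge(sim$truth, sim$plants[, c("plant", "death_day")],
                    by = "plant")
  areas <- simulate_growth_series(truth_dd, config)
  harvest <- simulate_harvest_and_fitness(sim, config)
  list(plants = sim$plants, truth = sim$truth, areas = areas,
       harvest = harvest, config = config, layout = sim$layout)
}

#' Write a synthetic study to disk
#'
#' Writes `plants.csv`, `areas.csv`, `truth.csv`, `harvest.csv` and
#' `layout.yaml` into `dir`; optionally renders per-tray PNG images for
#' the requested imaging days.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param image_days Numeric vector of days to render as tray PNGs
#'   (default none; rendering every tray and day is slow and large).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir, image_days = numeric(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$plants, file.path(dir, "plants.csv"), row.names = FALSE)
  utils::write.csv(study$areas, file.path(dir, "areas.csv"), row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(study$harvest, file.path(dir, "harvest.csv"), row.names = FALSE)
  write_pot_layout(study$layout, file.path(dir, "layout.yaml"))
  scale <- study$config$scale_mm_per_px
  for (d in image_days) {
    for (tray in unique(study$plants$tray)) {
      pl <- study$plants[study$plants$tray == tray, ]
      ar <- merge(pl[, c("plant", "pot")], study$areas[study$areas$day == d, ],
                  by = "plant")
      rend <- render_tray_image(ar[, c("pot", "area_mm2")], study$layout, scale)
      write_tray_image(rend$image,
                       file.path(dir, sprintf("tray_%s_day%03.0f.png", tray, d)))
    }
  }
  invisible(dir)
}
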