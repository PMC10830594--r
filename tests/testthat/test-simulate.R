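# Synthetic-data generator: design structure, determinism, growth
# series, harvest consistency.

test_that("experiment design has the right size, nesting and pot rule", {
  cfg <- tiny_config()
  sim <- simulate_experiment(cfg)
  # 5 populations x 3 families x 4 treatments x 3 blocks
  expect_equal(nrow(sim$plants), 5 * 3 * 4 * 3)
  # family nested in exactly one population
  fam_pop <- unique(sim$plants[, c("family", "population")])
  expect_equal(anyDuplicated(fam_pop$family), 0)
  # every plant fully assigned
  expect_false(anyNA(sim$plants$tray))
  expect_false(anyNA(sim$plants$pot))
  # 54-pot tray, every second pot: at most 27 plants per tray and all
  # pots on the checkerboard
  per_tray <- table(sim$plants$tray)
  expect_true(all(per_tray <= 27))
  lay <- pot_layout(6, 9)
  expect_true(all(sim$plants$pot %in% lay$cells$pot[lay$cells$used]))
  # no pot double-booked within a tray
  expect_equal(anyDuplicated(sim$plants[, c("tray", "pot")]), 0)
})

test_that("identical configurations reproduce identical output", {
  s1 <- simulate_study(tiny_config())
  s2 <- simulate_study(tiny_config())
  expect_identical(s1$plants, s2$plants)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$areas, s2$areas)
  expect_identical(s1$harvest, s2$harvest)
})

test_that("per-plant substreams make subsets reproducible", {
  cfg <- tiny_config()
  sim <- simulate_experiment(cfg)
  full <- simulate_growth_series(sim$truth, cfg)
  one <- simulate_growth_series(sim$truth[17, , drop = FALSE], cfg)
  expect_equal(full[full$plant == sim$truth$plant[17], ], one,
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(families_per_population = 0), "family")
  expect_error(sim_config(blocks_per_treatment = 0), "block")
  expect_error(sim_config(noise_sd = -1), "deviation")
  expect_error(sim_config(imaging_interval = 0), "imaging_interval")
  expect_error(sim_config(mortality = c(control = -0.1, heat = 0.1,
                                        drought = 0.1, heat_drought = 0.5)),
               "probability")
})

test_that("growth series follow the logistic curve, censoring and clipping", {
  state <- data.frame(plant = 1, A = 1500, x_mid = 27, scal = 4)
  cfg <- sim_config(noise_sd = 0, imaging_interval = 27, duration = 54)
  s <- simulate_growth_series(state, cfg)
  # logistic midpoint: area at the inflection day equals A/2
  expect_equal(s$area_mm2[s$day == 27], 750)
  # censoring at death day
  cfg3 <- sim_config(noise_sd = 0, imaging_interval = 3, duration = 30)
  s3 <- simulate_growth_series(state, cfg3, death_day = 10)
  expect_true(all(s3$day <= 10))
  expect_equal(max(s3$day), 9)
  # areas never negative even with heavy noise
  cfgN <- sim_config(noise_sd = 500, imaging_interval = 3, duration = 30)
  sN <- simulate_growth_series(state, cfgN)
  expect_true(all(sN$area_mm2 >= 0))
})

test_that("noisy series are unbiased around the true curve", {
  # 200 plants, same truth, noise sd 50: per-day mean within 3 standard
  # errors of the generating curve
  n <- 200
  state <- data.frame(plant = seq_len(n), A = 1500, x_mid = 27, scal = 4)
  cfg <- sim_config(noise_sd = 50, imaging_interval = 7, duration = 56,
                    seed = 99)
  s <- simulate_growth_series(state, cfg)
  for (d in unique(s$day)) {
    mu_true <- 1500 / (1 + exp((27 - d) / 4))
    if (mu_true < 3 * 50) next  # zero-clipping biases the low tail up
    obs <- s$area_mm2[s$day == d]
    se <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - mu_true), 3 * se + 1e-9)
  }
})

test_that("harvest weights invert the target traits when variances are zero", {
  cfg <- tiny_config(family_sd_log10 = 0, trait_noise_log10 = 0)
  sim <- simulate_experiment(cfg)
  h <- simulate_harvest_and_fitness(sim)
  ok <- h$survived == 1
  expect_gt(sum(ok), 50)
  ft <- compute_functional_traits(h[ok, ])
  tr <- sim$plants$treatment[match(ft$plant, sim$plants$plant)]
  for (trt in treatment_levels()) {
    tgt <- cfg$trait_targets[[trt]]
    idx <- tr == trt
    if (!any(idx)) next
    expect_equal(ft$SLA[idx], rep(tgt$SLA, sum(idx)), tolerance = 1e-10)
    expect_equal(ft$LDMC[idx], rep(tgt$LDMC, sum(idx)), tolerance = 1e-10)
    expect_equal(ft$root_shoot[idx], rep(tgt$root_shoot, sum(idx)),
                 tolerance = 1e-10)
  }
  # shoot conservation: generated dead-leaf weight is zero, so shoot dry
  # weight equals living leaves + inflorescences
  expect_true(all(h$dead_leaf_dry_mg == 0))
})

test_that("null selection coefficients leave fitted gradients near zero", {
  cfg <- sim_config(families_per_population = c(60, 3, 3, 3, 3), seed = 5)
  sim <- simulate_experiment(cfg)
  h <- simulate_harvest_and_fitness(sim)
  idx <- sim$plants$treatment == "control"
  z <- scale(sim$truth$SLA[idx])
  fit <- fit_univariate_selection(as.numeric(z), h$flowered[idx], "binomial")
  expect_true(abs(fit$coef_x) < 3 * fit$se_x)
})

test_that("survival ordering matches the factorial stress pattern", {
  cfg <- sim_config(families_per_population = c(30, 5, 5, 5, 5), seed = 3)
  sim <- simulate_experiment(cfg)
  surv <- tapply(sim$plants$survived, sim$plants$treatment, mean)
  expect_gt(surv[["control"]], surv[["heat"]])
  expect_gt(surv[["control"]], surv[["drought"]])
  expect_gt(surv[["heat"]], surv[["heat_drought"]])
  expect_gt(surv[["drought"]], surv[["heat_drought"]])
})

test_that("written study files round-trip through CSV and YAML", {
  dir <- withr::local_tempdir()
  study <- simulate_study(sim_config(families_per_population = 2,
                                     blocks_per_treatment = 2, seed = 8))
  write_simulation(study, dir)
  expect_true(all(file.exists(file.path(dir, c("plants.csv", "areas.csv",
                                               "truth.csv", "harvest.csv",
                                               "layout.yaml")))))
  areas <- read.csv(file.path(dir, "areas.csv"))
  expect_equal(nrow(areas), nrow(study$areas))
  lay <- read_pot_layout(file.path(dir, "layout.yaml"))
  expect_equal(lay$cells$used, study$layout$cells$used)
})
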