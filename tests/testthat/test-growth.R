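# Growth-curve fitting, AIC model selection, trait extraction.

test_that("noise-free logistic data are recovered essentially exactly", {
  s <- logistic3_series()
  fit <- fit_growth_model(s, "logistic3")
  expect_true(fit$converged)
  expect_equal(unname(fit$params["A"]), 1500, tolerance = 1e-6)
  expect_equal(unname(fit$params["x_mid"]), 27, tolerance = 1e-6)
  expect_equal(unname(fit$params["scal"]), 4, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("the AIC follows the Gaussian-NLS formula", {
  # n = 10, RSS = 10 -> n*log(RSS/n) = 0, AIC = 2*(k+1)
  expect_equal(nls_aic(10, 10, 2), 6)
  expect_equal(nls_aic(10, 10, 3), 8)
  s <- logistic3_series(days = seq(0, 45, 5), noise_sd = 0)
  f <- fit_growth_model(s, "linear")
  expect_equal(f$aic, nls_aic(f$rss, f$n, 2))
})

test_that("least-squares fits beat a brute-force parameter grid", {
  s <- withr::with_seed(21, data.frame(day = 0:15,
                                       area_mm2 = 3 + 2 * (0:15) + rnorm(16, 0, 1)))
  fit <- fit_growth_model(s, "linear")
  grid <- expand.grid(a = seq(0, 6, 0.25), b = seq(1, 3, 0.1))
  grid_rss <- apply(grid, 1, function(p)
    sum((s$area_mm2 - (p[1] + p[2] * s$day))^2))
  expect_lte(fit$rss, min(grid_rss) + 1e-9)
})

test_that("each model recovers its own noise-free data", {
  days <- seq(0, 60, 3)
  cases <- list(
    exponential = list(pars = c(a = 30, b = 0.05)),
    power = list(pars = c(a = 4, b = 1.5)),
    von_bertalanffy = list(pars = c(A = 1500, k = 0.08, t0 = 2)),
    gompertz = list(pars = c(A = 1500, k = 0.15, Ti = 25))
  )
  for (m in names(cases)) {
    mu <- growth_model_mean(m, days, cases[[m]]$pars)
    fit <- fit_growth_model(data.frame(day = days, area_mm2 = mu), m)
    expect_true(fit$converged, info = m)
    expect_lt(fit$rss / sum(mu^2), 1e-10)
  }
  # power model is defined as zero at t = 0
  expect_equal(growth_model_mean("power", 0, c(a = 4, b = 1.5)), 0)
})

test_that("model selection prefers the generating model and parsimony", {
  s <- logistic3_series()
  sel <- select_best_model(s)
  expect_equal(sel$best$model, "logistic3")
  expect_gt(sel$aic_table$aic[sel$aic_table$model == "linear"] -
              sel$aic_table$aic[sel$aic_table$model == "logistic3"], 0)
  # exact straight line: linear wins over the sigmoids
  s2 <- data.frame(day = 0:12, area_mm2 = 5 + 2 * (0:12))
  expect_equal(select_best_model(s2)$best$model, "linear")
  expect_error(select_best_model(s2[1:3, ]), "at least 4")
})

test_that("growth traits come from the logistic fit with the analytic slope", {
  fit <- fit_growth_model(logistic3_series(), "logistic3")
  tr <- extract_growth_traits(fit)
  expect_equal(unname(tr["size"]), 1500, tolerance = 1e-6)
  expect_equal(unname(tr["growth_rate"]), 93.75, tolerance = 1e-6)
  # analytic slope equals the centred numerical derivative at x_mid
  h <- 1e-4
  p <- fit$params
  num <- (growth_model_mean("logistic3", p["x_mid"] + h, p) -
            growth_model_mean("logistic3", p["x_mid"] - h, p)) / (2 * h)
  expect_equal(unname(tr["growth_rate"]), unname(num), tolerance = 1e-6)
  # traits are defined only for the three-parameter logistic
  lin <- fit_growth_model(logistic3_series(), "linear")
  expect_error(extract_growth_traits(lin), "logistic")
})

test_that("fits fail cleanly with too few points", {
  s <- logistic3_series(days = c(0, 10, 20))
  expect_error(fit_growth_model(s, "logistic3"), "at least")
  flat <- data.frame(day = c(5, 5, 5, 5), area_mm2 = c(1, 2, 3, 4))
  expect_error(fit_growth_model(flat, "linear"), "distinct")
})

test_that("AIC ordering is invariant to shifting the time origin", {
  s <- logistic3_series(noise_sd = 20)
  s <- withr::with_seed(31, logistic3_series(noise_sd = 20))
  shifted <- transform(s, day = day + 5)
  shiftable <- c("linear", "logistic3", "von_bertalanffy", "gompertz")
  a1 <- select_best_model(s)$aic_table
  a2 <- select_best_model(shifted)$aic_table
  for (m in shiftable) {
    expect_equal(a1$aic[a1$model == m], a2$aic[a2$model == m],
                 tolerance = 1e-4, info = m)
  }
})

test_that("a datapoint on the fitted curve leaves the optimum unchanged", {
  s <- withr::with_seed(32, logistic3_series(noise_sd = 25))
  fit <- fit_growth_model(s, "logistic3")
  new_day <- 31.5
  new_area <- growth_model_mean("logistic3", new_day, fit$params)
  s2 <- rbind(s, data.frame(day = new_day, area_mm2 = new_area))
  fit2 <- fit_growth_model(s2, "logistic3")
  expect_equal(fit2$rss, fit$rss, tolerance = 1e-6)
})

test_that("support summary counts winners and conserves plant totals", {
  series <- lapply(1:6, function(i) {
    withr::with_seed(i, logistic3_series(A = 1200 + 50 * i, noise_sd = 10))
  })
  sels <- lapply(series, select_best_model)
  sup <- support_summary(sels)
  expect_equal(sum(sup$counts) + sup$n_unusable, length(series))
  # winner distribution matches an independent per-plant recomputation
  winners <- vapply(series, function(s) select_best_model(s)$best$model,
                    character(1))
  expect_equal(unname(sup$counts[names(sup$counts)]),
               as.integer(table(factor(winners, growth_model_names()))))
})

test_that("parameters are recovered within a few percent under 2% noise", {
  # median relative error of logistic parameters over simulated plants
  n <- 40
  errs <- sapply(seq_len(n), function(i) {
    s <- withr::with_seed(100 + i, logistic3_series(noise_sd = 30))
    f <- fit_growth_model(s, "logistic3")
    abs(f$params[c("A", "x_mid", "scal")] - c(1500, 27, 4)) / c(1500, 27, 4)
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
  expect_lt(median(errs[3, ]), 0.05)
})

test_that("the per-plant pipeline excludes unusable plants with reasons", {
  areas <- rbind(
    data.frame(plant = 1, logistic3_series()),
    data.frame(plant = 2, logistic3_series(A = 900, x_mid = 20))[1:3, ]
  )
  gt <- fit_growth_traits(areas)
  expect_equal(gt$plant, 1)
  expect_equal(gt$best_model, "logistic3")
  exc <- attr(gt, "excluded")
  expect_equal(exc$plant, 2)
  expect_match(exc$reason, "few")
})
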