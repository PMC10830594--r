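# Nonlinear growth-curve fitting, AIC model selection across the seven
# candidate models, and extraction of the three growth traits.

# RSS floor: keeps the Gaussian-NLS AIC finite on noise-free fixtures
# without affecting any comparison at realistic noise levels.
.rss_floor <- 1e-12

#' Akaike information criterion for a Gaussian nonlinear least-squares fit
#'
#' `AIC = n * log(RSS / n) + 2 * (k + 1)`: the Gaussian profile
#' log-likelihood with the error variance counted as a parameter and
#' additive constants dropped (they cancel in within-series
#' comparisons).
#'
#' @param rss Residual sum of squares (floored at a tiny positive value).
#' @param n Number of observations.
#' @param k Number of mean-function parameters.
#' @return The AIC value.
#' @export
nls_aic <- function(rss, n, k) {
  n * log(max(rss, .rss_floor) / n) + 2 * (k + 1)
}

#' Fit one growth model to an area series
#'
#' Minimizes the residual sum of squares of the model's mean function
#' over the series by Levenberg-Marquardt nonlinear least squares (the
#' linear model is solved exactly). Starting values come from simple
#' heuristics (asymptote at 1.05 x the maximum area, inflection at the
#' day nearest half-maximum, scale at a quarter of the day range); on
#' failure, three deterministic perturbations of the start are tried
#' before the fit is flagged as non-converged with an infinite AIC.
#'
#' @param series Data frame with columns `day` and `area_mm2` (one
#'   plant). Needs at least one more point than the model has parameters
#'   and at least two distinct days.
#' @param model One of [growth_model_names()].
#' @return An object of class `growth_fit`: list with `model`, `params`
#'   (named vector; for `logistic2` including the fixed `Amax`), `rss`,
#'   `n`, `k`, `aic`, `converged`.
#' @export
fit_growth_model <- function(series, model = "logistic3") {
  model <- match.arg(model, growth_model_names())
  day <- series$day
  area <- series$area_mm2
  k <- growth_model_npar(model)
  if (length(day) < k + 1) {
    stopf("series has %d points; model '%s' needs at least %d",
          length(day), model, k + 1)
  }
  if (length(unique(day)) < 2) stopf("series needs at least 2 distinct days")
  n <- length(day)

  if (model == "linear") {
    fit <- stats::lm(area ~ day)
    pars <- c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
    rss <- sum(stats::residuals(fit)^2)
    return(structure(list(model = model, params = pars, rss = rss, n = n,
                          k = k, aic = nls_aic(rss, n, k), converged = TRUE),
                     class = "growth_fit"))
  }

  start <- growth_start_values(model, day, area)
  fixed <- if (model == "logistic2") list(Amax = max(area)) else list()
  resid_fun <- function(p) {
    mu <- growth_model_mean(model, day, c(as.list(p), fixed))
    r <- area - mu
    r[!is.finite(r)] <- 1e6
    r
  }
  # heuristic start first; three deterministic perturbations only on failure
  perturb <- list(1, 0.7, 1.4, 0.9)
  best <- NULL
  for (f in perturb) {
    st <- lapply(start, function(v) v * f)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(resid_fun(ans$par)^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss)) {
      best <- list(par = unlist(ans$par), rss = rss)
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    return(structure(list(model = model, params = unlist(start), rss = NA_real_,
                          n = n, k = k, aic = Inf, converged = FALSE),
                     class = "growth_fit"))
  }
  pars <- c(best$par, unlist(fixed))
  structure(list(model = model, params = pars, rss = best$rss, n = n, k = k,
                 aic = nls_aic(best$rss, n, k), converged = TRUE),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s%s: RSS %.4g, AIC %.2f, n %d\n", x$model,
              if (x$converged) "" else " (not converged)", x$rss, x$aic, x$n))
  print(round(x$params, 4))
  invisible(x)
}

#' Fit all seven growth models and select the best by AIC
#'
#' Fits every candidate model and returns the converged fit with the
#' lowest AIC. Near-ties (|dAIC| < 1e-9) are broken in favour of fewer
#' parameters, then by the fixed model-name order.
#'
#' @param series Data frame with `day` and `area_mm2`; needs at least 4
#'   points so every model is fittable (or cleanly flagged).
#' @return List with `best` (a `growth_fit` or `NULL` if nothing
#'   converged), `fits` (all seven fits), and `aic_table` (data frame
#'   `model`, `k`, `converged`, `rss`, `aic`).
#' @export
select_best_model <- function(series) {
  if (nrow(series) < 4) stopf("need at least 4 points to compare all models")
  fits <- lapply(growth_model_names(), function(m) {
    tryCatch(fit_growth_model(series, m),
             error = function(e) structure(
               list(model = m, params = NULL, rss = NA_real_,
                    n = nrow(series), k = growth_model_npar(m), aic = Inf,
                    converged = FALSE), class = "growth_fit"))
  })
  names(fits) <- growth_model_names()
  aic_table <- data.frame(
    model = growth_model_names(),
    k = vapply(fits, `[[`, numeric(1), "k"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL
  )
  conv <- which(aic_table$converged & is.finite(aic_table$aic))
  if (!length(conv)) {
    return(list(best = NULL, fits = fits, aic_table = aic_table))
  }
  cand <- aic_table[conv, ]
  # order by AIC, break near-ties by parsimony then fixed model order
  ord <- order(cand$aic, cand$k, match(cand$model, growth_model_names()))
  cand <- cand[ord, ]
  best_row <- cand[1, ]
  for (j in seq_len(nrow(cand))[-1]) {
    if (cand$aic[j] - best_row$aic < 1e-9 &&
        (cand$k[j] < best_row$k)) best_row <- cand[j, ]
  }
  list(best = fits[[best_row$model]], fits = fits, aic_table = aic_table)
}

#' Extract the three growth traits from a three-parameter logistic fit
#'
#' From `area(t) = A / (1 + exp((x_mid - t)/scal))` the traits are the
#' asymptote (`size`, maximum rosette area in mm^2), the inflection day
#' (`x_mid`, time of fastest growth), and the slope at the inflection
#' (`growth_rate = A / (4 * scal)` in mm^2/day).
#'
#' @param fit A converged `growth_fit` with `model == "logistic3"`.
#' @return Named numeric vector `size`, `x_mid`, `growth_rate`.
#' @export
extract_growth_traits <- function(fit) {
  if (!inherits(fit, "growth_fit") || fit$model != "logistic3") {
    stopf("growth traits are defined for the three-parameter logistic fit only")
  }
  if (!fit$converged) stopf("cannot extract traits from a non-converged fit")
  p <- fit$params
  c(size = unname(p["A"]), x_mid = unname(p["x_mid"]),
    growth_rate = unname(p["A"]) / (4 * unname(p["scal"])))
}

#' Tally AIC wins across plants
#'
#' @param selections List of [select_best_model()] results (one per
#'   plant); plants with no converged model are counted as unusable.
#' @return List with `counts` (named integer vector per model, summing to
#'   the number of usable plants) and `n_unusable`.
#' @export
support_summary <- function(selections) {
  if (!length(selections)) stopf("need at least one plant")
  winners <- vapply(selections, function(s) {
    if (is.null(s$best)) NA_character_ else s$best$model
  }, character(1))
  counts <- table(factor(winners, levels = growth_model_names()))
  list(counts = as.integer(counts) |> stats::setNames(growth_model_names()),
       n_unusable = sum(is.na(winners)))
}

#' Fit growth traits for every plant in an area table
#'
#' Per-plant pipeline used after image extraction: model selection across
#' the seven candidates for reporting, plus a three-parameter logistic
#' fit from which the growth traits are taken. Plants with too few
#' observations (fewer than 5 points or fewer than 2 distinct days) or
#' without a converged logistic fit are excluded with a logged reason.
#'
#' @param areas Long-format data frame `plant`, `day`, `area_mm2`.
#' @param min_points Minimum observations per plant (default 5).
#' @return Data frame with one row per usable plant: `plant`, `size`,
#'   `x_mid`, `growth_rate`, `best_model`, and the AIC of each of the
#'   seven models (`aic_<model>`). Excluded plants are recorded in
#'   `attr(, "excluded")` (`plant`, `reason`).
#' @export
fit_growth_traits <- function(areas, min_points = 5) {
  plants <- unique(areas$plant)
  rows <- vector("list", length(plants))
  excluded <- list()
  for (i in seq_along(plants)) {
    s <- areas[areas$plant == plants[i], c("day", "area_mm2")]
    if (nrow(s) < max(min_points, 4) || length(unique(s$day)) < 2) {
      excluded[[length(excluded) + 1]] <-
        data.frame(plant = plants[i], reason = "too few observations")
      next
    }
    sel <- select_best_model(s)
    if (is.null(sel$best)) {
      excluded[[length(excluded) + 1]] <-
        data.frame(plant = plants[i], reason = "no model converged")
      next
    }
    l3 <- sel$fits$logistic3
    if (!l3$converged) {
      excluded[[length(excluded) + 1]] <-
        data.frame(plant = plants[i], reason = "logistic3 fit failed")
      next
    }
    tr <- extract_growth_traits(l3)
    aics <- stats::setNames(as.list(sel$aic_table$aic),
                            paste0("aic_", sel$aic_table$model))
    rows[[i]] <- cbind(data.frame(plant = plants[i], size = tr[["size"]],
                                  x_mid = tr[["x_mid"]],
                                  growth_rate = tr[["growth_rate"]],
                                  best_model = sel$best$model),
                       as.data.frame(aics))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else data.frame(plant = numeric(0), reason = character(0))
  out
}
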