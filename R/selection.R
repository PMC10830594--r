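# Phenotypic selection analysis: within-treatment trait standardization,
# the family-mean imputation rule for the combined-stress treatment,
# univariate selection with AIC choice between linear and
# linear+quadratic models, and multivariate linear selection gradients.
#
# Sign convention: a positive coefficient means higher trait values are
# associated with higher fitness. Quadratic coefficients are reported as
# fitted (not doubled to the Lande-Arnold gamma).

#' Standardize traits to mean 0, sd 1 within treatment
#'
#' Selection gradients are comparable across traits only on a common
#' scale; each trait is centred and scaled (sample sd, n - 1 denominator)
#' separately within each treatment. Traits with zero variance in a
#' treatment are dropped (set `NA`) there and logged.
#'
#' @param data Data frame with a `treatment` column and the trait
#'   columns.
#' @param traits Character vector of trait column names (default the six
#'   standard traits present in `data`).
#' @return `data` with the trait columns standardized;
#'   `attr(, "dropped")` lists treatment/trait pairs with zero variance.
#' @export
standardize_within_treatment <- function(data, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(data))
  if (!"treatment" %in% names(data)) stopf("data needs a 'treatment' column")
  dropped <- list()
  for (tr in unique(data$treatment)) {
    idx <- data$treatment == tr
    if (sum(idx) < 2) stopf("treatment '%s' has fewer than 2 plants", tr)
    for (tn in traits) {
      z <- zscore(data[[tn]][idx])
      if (all(is.na(z)) && any(!is.na(data[[tn]][idx]))) {
        dropped[[length(dropped) + 1]] <- c(treatment = tr, trait = tn)
      }
      data[[tn]][idx] <- z
    }
  }
  attr(data, "dropped") <- dropped
  data
}

#' Impute combined-stress functional traits from single-stress family means
#'
#' Plants that die under combined stress leave no harvest material, so
#' SLA, LDMC and root:shoot cannot be measured there for most plants.
#' The imputation rule replaces each family's combined-stress value with
#' the arithmetic mean of that family's mean under heat and its mean
#' under drought; when the family is present in only one single-stress
#' treatment, that single mean is used and the family is flagged
#' `single_source`. Families absent from both single-stress treatments
#' cannot be imputed and are excluded from the combined-stress selection
#' analysis.
#'
#' @param trait_data Data frame with `plant`, `family`, `treatment` and
#'   the trait columns (on the analysis scale).
#' @param traits Traits to impute (default `SLA`, `LDMC`, `root_shoot`).
#' @return Data frame with one row per family: `family`, one column per
#'   trait, and `single_source` (logical per trait, as
#'   `single_source_<trait>`). Families with no source data are absent.
#' @export
impute_combined_stress_traits <- function(trait_data,
                                          traits = c("SLA", "LDMC", "root_shoot")) {
  need <- c("family", "treatment", traits)
  miss <- setdiff(need, names(trait_data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  single <- trait_data[trait_data$treatment %in% c("heat", "drought"), ]
  fams <- unique(single$family)
  rows <- lapply(fams, function(f) {
    out <- data.frame(family = f)
    any_val <- FALSE
    for (tn in traits) {
      m_heat <- mean(single[[tn]][single$family == f & single$treatment == "heat"],
                     na.rm = TRUE)
      m_drought <- mean(single[[tn]][single$family == f & single$treatment == "drought"],
                        na.rm = TRUE)
      avail <- c(m_heat, m_drought)[is.finite(c(m_heat, m_drought))]
      out[[tn]] <- if (length(avail)) mean(avail) else NA_real_
      out[[paste0("single_source_", tn)]] <- length(avail) == 1
      any_val <- any_val || length(avail) > 0
    }
    if (any_val) out else NULL
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Detect (quasi-)complete separation in a fitted binomial GLM.
#' @noRd
is_separated <- function(fit) {
  mu <- stats::fitted(fit)
  all(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)) > 15)
}

#' Univariate selection analysis of one trait
#'
#' Fits two candidate models of fitness on a standardized trait `z` --
#' `W ~ z` and `W ~ z + z^2` -- and reports the coefficients of the model
#' with the lower AIC, with Wald standard errors and p-values. Binary
#' fitness (flowering, survival) uses a logit-link binomial model fitted
#' by iteratively reweighted least squares; continuous fitness
#' (longevity) uses ordinary least squares. AIC is `-2 log L + 2 p` with
#' the same convention for both candidates.
#'
#' @param z Standardized trait values.
#' @param W Fitness: 0/1 for binary measures, numeric for longevity.
#' @param family `"binomial"` or `"gaussian"`.
#' @param trait,treatment Optional labels carried into the result.
#' @return A one-row data frame of class `selection_result`: `treatment`,
#'   `trait`, `form` (`"linear"` or `"quadratic"`), `aic_linear`,
#'   `aic_quadratic`, `coef_x`, `se_x`, `p_x`, `coef_x2`, `se_x2`,
#'   `p_x2` (NA for the linear form), `estimable`.
#' @export
fit_univariate_selection <- function(z, W, family = c("binomial", "gaussian"),
                                     trait = NA_character_,
                                     treatment = NA_character_) {
  family <- match.arg(family)
  ok <- stats::complete.cases(z, W)
  z <- z[ok]; W <- W[ok]
  if (length(z) < 10) stopf("need at least 10 complete observations")
  if (family == "binomial" && length(unique(W)) < 2) {
    stopf("binary fitness must include both outcomes")
  }
  dat <- data.frame(W = W, z = z, z2 = z^2)
  fit_one <- function(fml) {
    if (family == "binomial") stats::glm(fml, data = dat, family = stats::binomial())
    else stats::lm(fml, data = dat)
  }
  m_lin <- fit_one(W ~ z)
  m_quad <- fit_one(W ~ z + z2)
  aics <- c(linear = stats::AIC(m_lin), quadratic = stats::AIC(m_quad))
  form <- names(aics)[which.min(aics)]
  chosen <- if (form == "linear") m_lin else m_quad
  estimable <- !(family == "binomial" && is_separated(chosen))
  sm <- summary(chosen)$coefficients
  res <- data.frame(
    treatment = treatment, trait = trait, form = form,
    aic_linear = aics[["linear"]], aic_quadratic = aics[["quadratic"]],
    coef_x = if (estimable) sm["z", 1] else NA_real_,
    se_x = if (estimable) sm["z", 2] else NA_real_,
    p_x = if (estimable) sm["z", 4] else NA_real_,
    coef_x2 = if (form == "quadratic" && estimable) sm["z2", 1] else NA_real_,
    se_x2 = if (form == "quadratic" && estimable) sm["z2", 2] else NA_real_,
    p_x2 = if (form == "quadratic" && estimable) sm["z2", 4] else NA_real_,
    estimable = estimable
  )
  class(res) <- c("selection_result", class(res))
  res
}

#' Multivariate linear selection gradients
#'
#' Fits a single model of fitness on all standardized traits jointly,
#' with linear terms only: `W ~ z1 + ... + zk`. The coefficients are the
#' multivariate selection gradients, isolating direct selection on each
#' trait from selection through correlated traits. Aliased (rank
#' deficient) traits are dropped with a log entry.
#'
#' @param Z Data frame or matrix of standardized traits (columns named).
#' @param W Fitness (0/1 or continuous).
#' @param family `"binomial"` or `"gaussian"`.
#' @param treatment Optional label.
#' @return Data frame with one row per retained trait: `treatment`,
#'   `trait`, `gradient`, `se`, `p`; `attr(, "dropped")` names aliased
#'   traits.
#' @export
fit_multivariate_selection <- function(Z, W, family = c("binomial", "gaussian"),
                                       treatment = NA_character_) {
  family <- match.arg(family)
  Z <- as.data.frame(Z)
  ok <- stats::complete.cases(Z) & !is.na(W)
  Z <- Z[ok, , drop = FALSE]; W <- W[ok]
  if (nrow(Z) < 10) stopf("need at least 10 complete observations")
  if (family == "binomial" && length(unique(W)) < 2) {
    stopf("binary fitness must include both outcomes")
  }
  dat <- cbind(data.frame(W = W), Z)
  fml <- stats::as.formula(paste("W ~", paste(names(Z), collapse = " + ")))
  fit <- if (family == "binomial") {
    stats::glm(fml, data = dat, family = stats::binomial())
  } else stats::lm(fml, data = dat)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  if (length(aliased)) {
    keep <- setdiff(names(Z), aliased)
    fml <- stats::as.formula(paste("W ~", paste(keep, collapse = " + ")))
    fit <- if (family == "binomial") {
      stats::glm(fml, data = dat, family = stats::binomial())
    } else stats::lm(fml, data = dat)
  }
  sm <- summary(fit)$coefficients
  rows <- setdiff(rownames(sm), "(Intercept)")
  out <- data.frame(treatment = treatment, trait = rows,
                    gradient = sm[rows, 1], se = sm[rows, 2],
                    p = sm[rows, 4], row.names = NULL)
  attr(out, "dropped") <- aliased
  out
}

#' Run the full selection analysis for one treatment
#'
#' Standardizes traits within the treatment, applies the combined-stress
#' imputation when analysing `heat_drought`, selects the fitness measure
#' for the treatment, and runs the univariate analysis per trait plus the
#' multivariate linear model.
#'
#' @param trait_data Analysis-scale trait table with `plant`, `family`,
#'   `treatment` and the six trait columns (all treatments, so that
#'   imputation can draw on the single-stress cells).
#' @param fitness Data frame with `plant`, `flowered`, `survived`,
#'   `longevity_days`.
#' @param treatment Treatment to analyse.
#' @param traits Trait set (default the six standard traits).
#' @return List with `univariate` (stacked [fit_univariate_selection()]
#'   rows), `multivariate`, `fitness_measure`, `n`.
#' @export
selection_analysis <- function(trait_data, fitness, treatment,
                               traits = trait_names()) {
  treatment <- match.arg(treatment, treatment_levels())
  measure <- fitness_measure_for_treatment(treatment)
  dat <- trait_data[trait_data$treatment == treatment, , drop = FALSE]
  if (treatment == "heat_drought") {
    imp <- impute_combined_stress_traits(trait_data)
    for (tn in intersect(c("SLA", "LDMC", "root_shoot"), traits)) {
      dat[[tn]] <- imp[[tn]][match(dat$family, imp$family)]
    }
    dat <- dat[dat$family %in% imp$family, , drop = FALSE]
  }
  dat <- standardize_within_treatment(dat, traits)
  fit_cols <- switch(measure, flowered = "flowered", survived = "survived",
                     longevity = "longevity_days")
  W <- fitness[[fit_cols]][match(dat$plant, fitness$plant)]
  fam <- if (measure == "longevity") "gaussian" else "binomial"
  uni <- do.call(rbind, lapply(traits, function(tn) {
    tryCatch(fit_univariate_selection(dat[[tn]], W, fam, trait = tn,
                                      treatment = treatment),
             error = function(e) NULL)
  }))
  multi <- tryCatch(
    fit_multivariate_selection(dat[, traits, drop = FALSE], W, fam,
                               treatment = treatment),
    error = function(e) NULL)
  list(univariate = uni, multivariate = multi, fitness_measure = measure,
       n = nrow(dat))
}
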