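# Descriptive and comparative statistics: Wilcoxon rank-sum contrasts of
# southern vs northern/central populations, per-treatment trait
# correlations, PCA on the trait correlation matrix, and a simplified
# fixed-effects factorial estimator for synthetic validation.

#' Wilcoxon rank-sum test with an exact small-sample mode
#'
#' Computes the Mann-Whitney U statistic for group `a` and a two-sided
#' p-value. In `exact` mode the null distribution of U is built by full
#' enumeration of all ways to split the observed (mid)ranks between the
#' two groups, and `p = min(1, 2 * min(P(U <= u), P(U >= u)))`. In
#' `approx` mode the normal approximation with the tie-corrected
#' variance and a 0.5 continuity correction is used. `auto` picks exact
#' when `length(a) + length(b) <= 12` and there are no ties.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `statistic` (U for group `a`), `p` (two-sided) and
#'   `mode` (the mode actually used). When all values are identical
#'   across both groups, `p = 1`.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  x <- c(a, b)
  r <- rank(x)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- as.numeric(table(x))
  has_ties <- any(ties > 1)
  if (mode == "auto") mode <- if (n <= 12 && !has_ties) "exact" else "approx"

  if (all(ties == n)) {  # every value identical across both groups
    return(list(statistic = u_obs, p = 1, mode = mode))
  }

  if (mode == "exact") {
    combos <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    # guard float midranks: compare with a small tolerance
    p_le <- mean(u_all <= u_obs + 1e-9)
    p_ge <- mean(u_all >= u_obs - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = u_obs, p = 1, mode = mode))
    zval <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(zval, 0)))
  }
  list(statistic = u_obs, p = p, mode = mode)
}

#' South-vs-north contrasts per trait and treatment
#'
#' Tests, for each trait in each treatment cell, whether plants from the
#' southern (warm range-edge) populations differ from plants of the
#' northern and central populations, by two-sided Wilcoxon rank-sum
#' tests at the plant level. Flowering is only contrasted in treatments
#' where any plant flowered; cells where either group is absent yield no
#' row (contrasts are absent, never reported as p = 1 placeholders).
#'
#' @param data Data frame with `population`, `treatment` and the trait
#'   columns (performance measures such as `survived` or `flowered` may
#'   be included as traits).
#' @param traits Character vector of columns to contrast.
#' @param southern Labels of the southern populations (default
#'   `c("SE", "SW")`).
#' @param treatments Treatments to include (default all four).
#' @param mode Passed to [wilcoxon_rank_sum()].
#' @return Data frame `trait`, `treatment`, `n_south`, `n_north`,
#'   `statistic`, `p`.
#' @export
edge_contrast_table <- function(data, traits, southern = c("SE", "SW"),
                                treatments = treatment_levels(),
                                mode = "auto") {
  stopifnot(all(c("population", "treatment") %in% names(data)))
  rows <- list()
  for (tn in traits) {
    for (tr in treatments) {
      sub <- data[data$treatment == tr & !is.na(data[[tn]]), ]
      if (tn == "flowered" && (!nrow(sub) || sum(sub$flowered) == 0)) next
      va <- sub[[tn]][sub$population %in% southern]
      vb <- sub[[tn]][!sub$population %in% southern]
      if (!length(va) || !length(vb)) next
      w <- wilcoxon_rank_sum(va, vb, mode)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tn, treatment = tr, n_south = length(va),
        n_north = length(vb), statistic = w$statistic, p = w$p)
    }
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Pairwise Pearson correlations among traits
#'
#' Pairwise-complete Pearson correlations with t-distribution p-values,
#' as used to examine trait integration within one population and
#' treatment. Constant traits get `NA` correlations for their pairs.
#'
#' @param data Data frame containing the trait columns.
#' @param traits Character vector of trait columns (default the six
#'   standard traits present).
#' @param treatment Optional label attached to the result.
#' @return Object of class `correlation_matrix`: list with symmetric
#'   matrices `r`, `p`, `n` (pairs used) and the `treatment` label.
#' @export
correlation_matrix <- function(data, traits = NULL, treatment = NA_character_) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(data))
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(!is.na(data[[traits[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(data[[traits[i]]], data[[traits[j]]])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 3) next
      xi <- data[[traits[i]]][ok]; xj <- data[[traits[j]]][ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      rij <- stats::cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tval <- rij * sqrt((nij - 2) / (1 - rij^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tval), nij - 2)
      }
    }
  }
  structure(list(r = r, p = p, n = nmat, treatment = treatment),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix>%s\n",
              if (is.na(x$treatment)) "" else paste0(" treatment ", x$treatment)))
  print(round(x$r, 3))
  invisible(x)
}

#' Principal component analysis of the trait correlation matrix
#'
#' Eigen-decomposition of the correlation matrix of standardized traits
#' over complete cases. Explained variances (eigenvalues) sum to the
#' number of retained traits; components are ordered by decreasing
#' eigenvalue; each loading vector is signed so its largest-magnitude
#' entry is positive. Constant traits are dropped with a log entry. When
#' `data` has a `treatment` column the analysis is run per treatment and
#' a named list is returned.
#'
#' @param data Data frame with the trait columns (and optionally
#'   `treatment`).
#' @param traits Trait columns (default the six standard traits present).
#' @return For a single table: list with `loadings` (traits x PCs),
#'   `scores`, `eigenvalues`, `explained` (proportions), `n`,
#'   `dropped`. With a `treatment` column: named list of such results.
#' @export
pca_per_treatment <- function(data, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(data))
  if ("treatment" %in% names(data)) {
    trs <- unique(data$treatment)
    out <- lapply(trs, function(tr) {
      pca_per_treatment(data[data$treatment == tr,
                             setdiff(names(data), "treatment"), drop = FALSE],
                        traits)
    })
    names(out) <- trs
    return(out)
  }
  X <- data[, traits, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  sds <- vapply(X, stats::sd, numeric(1))
  dropped <- traits[sds == 0 | is.na(sds)]
  keep <- setdiff(traits, dropped)
  if (nrow(X) < length(keep) + 1) stopf("need more complete cases than traits")
  Z <- scale(as.matrix(X[, keep, drop = FALSE]))
  C <- stats::cor(Z)
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(keep, paste0("PC", seq_len(ncol(V))))
  list(loadings = V, scores = Z %*% V,
       eigenvalues = eig$values,
       explained = eig$values / length(keep),
       n = nrow(Z), dropped = dropped)
}

#' Simplified factorial effect estimates
#'
#' Estimates intercept (control cell), heat and drought main effects and
#' their interaction by ordinary least squares on treatment-coded
#' indicators (logit-link binomial model for binary outcomes). The
#' interaction coefficient is the deviation of the combined-stress cell
#' from additivity of the single-stress effects. This is a fixed-effects
#' validator for synthetic experiments, not a mixed-model analysis.
#'
#' @param y Response vector.
#' @param heat,drought Logical (or 0/1) stressor indicators.
#' @param family `"gaussian"` or `"binomial"`.
#' @return Data frame `term` (`intercept`, `heat`, `drought`,
#'   `heat:drought`), `estimate`, `se`, `p`.
#' @export
factorial_effects <- function(y, heat, drought,
                              family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  heat <- as.logical(heat); drought <- as.logical(drought)
  ok <- !is.na(y) & !is.na(heat) & !is.na(drought)
  y <- y[ok]; heat <- heat[ok]; drought <- drought[ok]
  cells <- table(heat, drought)
  if (length(cells) < 4 || any(cells == 0)) {
    stopf("all four factorial cells must be non-empty (interaction non-estimable)")
  }
  dat <- data.frame(y = y, heat = heat, drought = drought)
  fit <- if (family == "binomial") {
    stats::glm(y ~ heat * drought, data = dat, family = stats::binomial())
  } else stats::lm(y ~ heat * drought, data = dat)
  sm <- summary(fit)$coefficients
  data.frame(term = c("intercept", "heat", "drought", "heat:drought"),
             estimate = sm[, 1], se = sm[, 2], p = sm[, 4],
             row.names = NULL)
}
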