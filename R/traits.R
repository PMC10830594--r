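# Harvest-derived functional traits, analysis-scale transforms, and
# correction of traits for nuisance effects (germination day, block,
# tray within block).

#' Compute SLA, LDMC and root:shoot from harvest records
#'
#' * `SLA` (specific leaf area) = rosette area (mm^2) per dry weight of
#'   living leaves (mg); dead leaves are excluded.
#' * `LDMC` (leaf dry matter content) = dry weight of living leaves (mg)
#'   per fresh weight of living leaves (g); dead leaves are excluded.
#'   Note the deliberately mixed units (mg/g).
#' * `root_shoot` = root dry weight per dry weight of all leaves and
#'   inflorescences. By default "all leaves" includes dead leaves; set
#'   `include_dead_leaves = FALSE` to restrict the shoot to living
#'   tissue.
#'
#' Records with a zero denominator get `NA` for the affected trait and
#' are listed in `attr(, "dropped")`.
#'
#' @param harvest Data frame with columns `plant`, `rosette_area_mm2`,
#'   `leaf_fresh_g`, `leaf_dry_mg`, `root_dry_mg`, `infl_dry_mg` and
#'   optionally `dead_leaf_dry_mg` (assumed 0 when missing).
#' @param include_dead_leaves Include dead-leaf dry weight in the shoot
#'   denominator of root:shoot (default TRUE).
#' @return Data frame `plant`, `SLA`, `LDMC`, `root_shoot`, with an
#'   attribute `dropped` naming plants with undefined traits.
#' @export
compute_functional_traits <- function(harvest, include_dead_leaves = TRUE) {
  need <- c("plant", "rosette_area_mm2", "leaf_fresh_g", "leaf_dry_mg",
            "root_dry_mg", "infl_dry_mg")
  miss <- setdiff(need, names(harvest))
  if (length(miss)) stopf("harvest is missing column(s): %s",
                          paste(miss, collapse = ", "))
  dead <- if ("dead_leaf_dry_mg" %in% names(harvest)) {
    ifelse(is.na(harvest$dead_leaf_dry_mg), 0, harvest$dead_leaf_dry_mg)
  } else 0
  shoot <- harvest$leaf_dry_mg + harvest$infl_dry_mg +
    if (include_dead_leaves) dead else 0

  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  out <- data.frame(
    plant = harvest$plant,
    SLA = safe_div(harvest$rosette_area_mm2, harvest$leaf_dry_mg),
    LDMC = safe_div(harvest$leaf_dry_mg, harvest$leaf_fresh_g),
    root_shoot = safe_div(harvest$root_dry_mg, shoot)
  )
  dropped <- out$plant[!stats::complete.cases(out[, c("SLA", "LDMC", "root_shoot")])]
  attr(out, "dropped") <- dropped
  out
}

#' Apply the analysis-scale transforms to a trait table
#'
#' `growth_rate`, `root_shoot`, `SLA` and `LDMC` are log10-transformed to
#' approach normality; `size` and `x_mid` stay on their natural scale.
#' Nonpositive values cannot be log-transformed and become `NA` with the
#' plant listed in `attr(, "dropped")`.
#'
#' @param traits Data frame containing any of the six trait columns.
#' @return The same data frame with the four ratio-like traits on the
#'   log10 scale.
#' @export
transform_traits <- function(traits) {
  dropped <- list()
  for (tn in intersect(log10_traits(), names(traits))) {
    bad <- !is.na(traits[[tn]]) & traits[[tn]] <= 0
    if (any(bad)) {
      dropped[[tn]] <- traits$plant[bad]
      traits[[tn]][bad] <- NA_real_
    }
    traits[[tn]] <- log10(traits[[tn]])
  }
  attr(traits, "dropped") <- dropped
  traits
}

#' Correct traits for nuisance effects
#'
#' Screens each nuisance term -- days to germination (a covariate), block,
#' and tray nested in block -- with a one-way analysis of variance, and
#' residualizes the trait against every term whose ANOVA p-value falls
#' below `alpha`, re-adding the grand mean so the trait keeps its
#' location. By default terms are handled sequentially in the order
#' listed (each step operating on the already-corrected values); with
#' `sequential = FALSE` all passing terms are removed in one joint
#' ordinary-least-squares fit.
#'
#' @param data Data frame with the trait column plus `germ_day`, `block`,
#'   and `tray` columns.
#' @param trait Name of the trait column to correct.
#' @param alpha Inclusion threshold on the per-term ANOVA p-value
#'   (default 0.05).
#' @param sequential Correct term by term (default) or jointly.
#' @return Numeric vector of corrected trait values (same length/order as
#'   `data`), with attribute `corrected_for` naming the removed terms.
#' @export
correct_for_nuisance <- function(data, trait, alpha = 0.05, sequential = TRUE) {
  need <- c(trait, "germ_day", "block", "tray")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  y <- data[[trait]]
  df <- data.frame(y = y,
                   germ_day = data$germ_day,
                   block = factor(data$block),
                   tray = factor(paste(data$block, data$tray, sep = ":")))
  terms <- c("germ_day", "block", "tray")
  usable <- vapply(terms, function(tm) {
    v <- df[[tm]][!is.na(y)]
    if (tm == "germ_day") length(unique(v)) >= 2 else nlevels(droplevels(factor(v))) >= 2
  }, logical(1))

  term_p <- function(yv, tm) {
    fit <- tryCatch(stats::lm(yv ~ df[[tm]]), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    an <- stats::anova(fit)
    an[["Pr(>F)"]][1]
  }
  residualize <- function(yv, tms) {
    fml <- stats::as.formula(paste("yv ~", paste(tms, collapse = " + ")))
    fit <- stats::lm(fml, data = df, na.action = stats::na.exclude)
    mean(yv, na.rm = TRUE) + stats::residuals(fit)
  }

  corrected_for <- character(0)
  if (sequential) {
    for (tm in terms[usable]) {
      p <- term_p(y, tm)
      if (!is.na(p) && p < alpha) {
        y <- residualize(y, tm)
        corrected_for <- c(corrected_for, tm)
      }
    }
  } else {
    keep <- terms[usable][vapply(terms[usable], function(tm) {
      p <- term_p(y, tm); !is.na(p) && p < alpha
    }, logical(1))]
    if (length(keep)) {
      y <- residualize(y, keep)
      corrected_for <- keep
    }
  }
  y <- as.numeric(y)
  attr(y, "corrected_for") <- corrected_for
  y
}

#' Assemble the analysis trait table
#'
#' Joins growth traits and functional traits, applies the log10
#' transforms, and corrects every trait for nuisance effects.
#'
#' @param growth_traits Output of [fit_growth_traits()] (or any frame
#'   with `plant`, `size`, `x_mid`, `growth_rate`).
#' @param functional Output of [compute_functional_traits()].
#' @param plants Design table with `plant`, `germ_day`, `block`, `tray`
#'   and (if present) `treatment`.
#' @param alpha Nuisance inclusion threshold (see
#'   [correct_for_nuisance()]).
#' @return Data frame `plant` plus the six traits on the analysis scale,
#'   with attribute `correction_log` (list per trait of removed terms).
#' @details Blocks and trays are nested inside treatment cells, so
#'   nuisance screening and residualization run separately within each
#'   treatment when `plants` carries a `treatment` column; correcting
#'   across treatments would absorb the treatment effects themselves.
#' @export
build_trait_table <- function(growth_traits, functional, plants, alpha = 0.05) {
  tab <- merge(growth_traits[, c("plant", "size", "x_mid", "growth_rate")],
               functional, by = "plant", all = TRUE)
  tab <- transform_traits(tab)
  keep <- intersect(c("plant", "germ_day", "block", "tray", "treatment"),
                    names(plants))
  tab <- merge(tab, plants[, keep], by = "plant")
  groups <- if ("treatment" %in% names(tab)) tab$treatment else rep(1, nrow(tab))
  log <- list()
  for (tn in intersect(trait_names(), names(tab))) {
    for (g in unique(groups)) {
      idx <- groups == g
      y <- correct_for_nuisance(tab[idx, , drop = FALSE], tn, alpha = alpha)
      log[[tn]][[as.character(g)]] <- attr(y, "corrected_for")
      tab[[tn]][idx] <- y
    }
  }
  out <- tab[, c("plant", intersect(trait_names(), names(tab)))]
  attr(out, "correction_log") <- log
  out
}
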