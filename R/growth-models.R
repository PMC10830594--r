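# The seven candidate growth models for rosette area over time.
#
# Parameterizations (t = days since germination, area in mm^2):
#   linear          a + b*t
#   exponential     a * exp(b*t)
#   power           a * t^b           (defined as 0 at t = 0 for b > 0)
#   logistic2       Amax / (1 + exp((x_mid - t)/scal)), Amax fixed at the
#                   maximum observed area (2 free parameters)
#   logistic3       A / (1 + exp((x_mid - t)/scal))
#   von_bertalanffy A * (1 - exp(-k*(t - t0)))
#   gompertz        A * exp(-exp(-k*(t - Ti)))

#' Names of the seven candidate growth models
#'
#' The fixed order doubles as the final tie-break in model selection.
#'
#' @return Character vector of length 7.
#' @export
growth_model_names <- function() {
  c("linear", "exponential", "power", "logistic2", "logistic3",
    "von_bertalanffy", "gompertz")
}

#' Evaluate a growth model's mean function
#'
#' @param model One of [growth_model_names()].
#' @param t Numeric vector of days (>= 0).
#' @param pars Named numeric vector or list of the model's parameters (see
#'   the parameterizations in the package vignette). For `logistic2` the
#'   fixed asymptote is passed as `Amax`.
#' @return Numeric vector of mean areas (mm^2).
#' @export
growth_model_mean <- function(model, t, pars) {
  p <- as.list(pars)
  switch(match.arg(model, growth_model_names()),
    linear = p$a + p$b * t,
    exponential = p$a * exp(p$b * t),
    power = ifelse(t == 0, 0, p$a * exp(p$b * log(pmax(t, .Machine$double.xmin)))),
    logistic2 = p$Amax / (1 + exp((p$x_mid - t) / p$scal)),
    logistic3 = p$A / (1 + exp((p$x_mid - t) / p$scal)),
    von_bertalanffy = p$A * (1 - exp(-p$k * (t - p$t0))),
    gompertz = p$A * exp(-exp(-p$k * (t - p$Ti)))
  )
}

# Number of free parameters per model.
#' @noRd
growth_model_npar <- function(model) {
  c(linear = 2, exponential = 2, power = 2, logistic2 = 2, logistic3 = 3,
    von_bertalanffy = 3, gompertz = 3)[[model]]
}

# Initialization heuristics from the observed series: asymptote at 1.05 x
# the maximum area, x_mid at the day nearest half-maximum, scal at a
# quarter of the observed day range.
#' @noRd
growth_start_values <- function(model, day, area) {
  amax <- max(area)
  a_hi <- 1.05 * max(amax, 1e-6)
  half <- a_hi / 2
  x_half <- day[which.min(abs(area - half))]
  scal0 <- max(diff(range(day)) / 4, 0.5)
  pos <- area > 0
  switch(model,
    linear = {
      fit <- stats::lm(area ~ day)
      list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
    },
    exponential = {
      if (sum(pos) >= 2) {
        fit <- stats::lm(log(area[pos]) ~ day[pos])
        list(a = exp(unname(stats::coef(fit)[1])),
             b = unname(stats::coef(fit)[2]))
      } else list(a = max(amax, 1) / 10, b = 0.1)
    },
    power = {
      ok <- pos & day > 0
      if (sum(ok) >= 2) {
        fit <- stats::lm(log(area[ok]) ~ log(day[ok]))
        list(a = exp(unname(stats::coef(fit)[1])),
             b = max(unname(stats::coef(fit)[2]), 1e-3))
      } else list(a = 1, b = 1)
    },
    logistic2 = list(x_mid = x_half, scal = scal0),
    logistic3 = list(A = a_hi, x_mid = x_half, scal = scal0),
    von_bertalanffy = list(A = a_hi, k = 1 / (2 * scal0),
                           t0 = x_half - 2 * scal0 * log(2)),
    gompertz = list(A = a_hi, k = 1 / scal0, Ti = x_half)
  )
}

# Map a logistic-truth parameter draw (A, x_mid, scal) onto the natural
# parameters of any generating model, preserving overall magnitude and
# timing so model-selection power experiments are comparable.
#' @noRd
growth_truth_params <- function(model, A, x_mid, scal, duration) {
  switch(model,
    linear = list(a = 0.05 * A, b = 0.9 * A / duration),
    exponential = list(a = A * exp(-3), b = 3 / duration),
    power = list(a = A / duration^1.5, b = 1.5),
    logistic2 = list(Amax = A, x_mid = x_mid, scal = scal),
    logistic3 = list(A = A, x_mid = x_mid, scal = scal),
    # t0 = 0 keeps the curve nonnegative over the whole observation
    # window; k places half-maximum at x_mid
    von_bertalanffy = list(A = A, k = log(2) / x_mid, t0 = 0),
    gompertz = list(A = A, k = 1 / scal, Ti = x_mid)
  )
}
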