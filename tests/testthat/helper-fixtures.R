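# Shared fixtures built in code.

# Noise-free three-parameter logistic series.
logistic3_series <- function(A = 1500, x_mid = 27, scal = 4,
                             days = seq(0, 60, 3), noise_sd = 0) {
  mu <- A / (1 + exp((x_mid - days) / scal))
  if (noise_sd > 0) mu <- mu + rnorm(length(days), 0, noise_sd)
  data.frame(day = days, area_mm2 = pmax(mu, 0))
}

# Tiny configuration for fast structural tests.
tiny_config <- function(...) {
  sim_config(n_populations = 5, families_per_population = 3,
             blocks_per_treatment = 3, seed = 42L, ...)
}

# A small tray with a few plants for imaging tests.
small_tray_fixture <- function(n_plants = 5, scale = 1.0, cell_px = 40,
                               areas = NULL, seed = 11) {
  lay <- pot_layout(rows = 3, cols = 4, cell_px = cell_px)
  used <- lay$cells$pot[lay$cells$used]
  if (is.null(areas)) {
    areas <- withr::with_seed(seed,
      runif(n_plants, 200, pi * (cell_px / 2 - 2)^2 * scale^2 * 0.9))
  }
  df <- data.frame(pot = used[seq_len(n_plants)], area_mm2 = areas)
  c(render_tray_image(df, lay, scale), list(layout = lay, areas = df,
                                            scale = scale))
}

# Brute-force per-pixel count of mask pixels inside one pot cell.
brute_count_cell <- function(mask, cell) {
  n <- 0L
  for (yy in (cell$y0 + 1):cell$y1) {
    for (xx in (cell$x0 + 1):cell$x1) {
      if (mask[yy, xx]) n <- n + 1L
    }
  }
  n
}
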