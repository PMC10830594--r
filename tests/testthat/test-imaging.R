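# Imaging: rendering with ground truth, colour-range segmentation with
# union semantics, per-pot counting, series assembly.

test_that("segmentation is the union of the green and red masks", {
  px <- array(0.5, dim = c(2, 2, 3))             # grey background
  px[1, 1, ] <- c(0.1, 0.8, 0.1)                 # green
  px[2, 2, ] <- c(0.9, 0.05, 0.1)                # red
  img <- tray_image(px, 1)
  mask <- segment_plant_pixels(img)
  expect_true(mask[1, 1])     # green-only pixel kept
  expect_true(mask[2, 2])     # red-only pixel kept
  expect_false(mask[1, 2])
  expect_false(mask[2, 1])
  # uniform out-of-range background: all-false mask
  bg <- tray_image(array(0.5, dim = c(4, 4, 3)), 1)
  expect_false(any(segment_plant_pixels(bg)))
  # idempotent: same image, same mask
  expect_identical(mask, segment_plant_pixels(img))
})

test_that("rendered trays carry exact ground truth", {
  lay <- pot_layout(rows = 3, cols = 4, cell_px = 40)
  # empty tray: all counts zero
  empty <- render_tray_image(data.frame(pot = integer(0),
                                        area_mm2 = numeric(0)), lay, 1)
  expect_true(all(empty$truth$pixels == 0))
  # one disk of radius 10 px: truth equals the brute-force pixel count
  r <- 10
  pot1 <- lay$cells$pot[lay$cells$used][1]
  one <- render_tray_image(data.frame(pot = pot1, area_mm2 = pi * r^2), lay, 1)
  cell <- lay$cells[lay$cells$pot == pot1, ]
  cx <- (cell$x0 + cell$x1 - 1) / 2; cy <- (cell$y0 + cell$y1 - 1) / 2
  brute <- 0L
  for (yy in cell$y0:(cell$y1 - 1)) {
    for (xx in cell$x0:(cell$x1 - 1)) {
      if ((xx - cx)^2 + (yy - cy)^2 <= r^2) brute <- brute + 1L
    }
  }
  expect_equal(one$truth$pixels[one$truth$pot == pot1], brute)
  # scale arithmetic: 100 mm^2 at 0.5 mm/px is about 400 px
  sc <- render_tray_image(data.frame(pot = pot1, area_mm2 = 100), lay, 0.5)
  drawn <- sc$truth$pixels[sc$truth$pot == pot1]
  expect_lt(abs(drawn - 400) / 400, 0.05)
  # disks overflowing their cell are refused
  expect_error(render_tray_image(data.frame(pot = pot1, area_mm2 = 5000),
                                 lay, 1), "overflow")
})

test_that("per-pot counting matches a brute-force loop and the scale law", {
  lay <- pot_layout(rows = 3, cols = 4, cell_px = 12)
  mask <- withr::with_seed(4, matrix(runif(lay$height * lay$width) < 0.3,
                                     lay$height, lay$width))
  cnt <- count_and_convert(mask, lay, 0.5)
  cells <- lay$cells[lay$cells$used, ]
  for (i in seq_len(nrow(cells))) {
    expect_equal(cnt$pixels[cnt$pot == cells$pot[i]],
                 brute_count_cell(mask, cells[i, ]))
  }
  # 400 pixels at 0.5 mm/px -> 100 mm^2
  expect_equal(cnt$area_mm2, cnt$pixels * 0.25)
  # unused pots are absent, not zero
  expect_setequal(cnt$pot, cells$pot)
  # empty pot counts zero
  m0 <- matrix(FALSE, lay$height, lay$width)
  expect_true(all(count_and_convert(m0, lay, 1)$area_mm2 == 0))
  # summing cells never double counts: total over used cells equals the
  # mask total restricted to the union of used cells
  restricted <- 0L
  for (i in seq_len(nrow(cells))) restricted <- restricted +
      brute_count_cell(mask, cells[i, ])
  expect_equal(sum(cnt$pixels), restricted)
})

test_that("layout validation catches overlap and out-of-bounds cells", {
  lay <- pot_layout(rows = 2, cols = 2, cell_px = 10)
  mask <- matrix(FALSE, lay$height, lay$width)
  bad <- lay
  bad$cells$x0[2] <- bad$cells$x0[1]   # duplicate rectangle -> overlap
  bad$cells$x1[2] <- bad$cells$x1[1]
  expect_error(count_and_convert(mask, bad, 1), "overlap")
  expect_error(count_and_convert(matrix(FALSE, 5, 5), lay, 1), "beyond")
})

test_that("widening the green hue range never decreases a pot's count", {
  fx <- small_tray_fixture(n_plants = 4)
  narrow <- segmentation_config(green_hue = c(0.30, 0.38))
  wide <- segmentation_config(green_hue = c(0.20, 0.45))
  cn <- count_and_convert(segment_plant_pixels(fx$image, narrow), fx$layout, 1)
  cw <- count_and_convert(segment_plant_pixels(fx$image, wide), fx$layout, 1)
  expect_true(all(cw$pixels >= cn$pixels))
})

test_that("render -> segment -> count recovers ground truth exactly", {
  for (seed in c(1, 2, 3)) {
    fx <- small_tray_fixture(n_plants = 6, seed = seed)
    mask <- segment_plant_pixels(fx$image)
    cnt <- count_and_convert(mask, fx$layout, fx$scale)
    m <- merge(cnt, fx$truth, by = "pot")
    expect_equal(m$pixels.x, m$pixels.y)
  }
})

test_that("area series assembly orders, gaps and censors correctly", {
  lay <- pot_layout(rows = 3, cols = 4, cell_px = 40)
  pot1 <- lay$cells$pot[lay$cells$used][1]
  mk <- function(area) render_tray_image(
    data.frame(pot = pot1, area_mm2 = area), lay, 1)$image
  imgs <- list(mk(300), mk(500))
  ser <- build_area_series(imgs, days = c(0, 7), lay)
  expect_equal(nrow(ser[ser$pot == pot1, ]), 2)
  expect_equal(ser$day[ser$pot == pot1], c(0, 7))
  expect_error(build_area_series(imgs, days = c(3, 3), lay), "duplicate")
  # a dead plant (no plant pixels) reads as zero from its death on
  imgs2 <- list(mk(300), mk(0), mk(0))
  ser2 <- build_area_series(imgs2, days = c(0, 7, 14), lay)
  s1 <- ser2[ser2$pot == pot1, ]
  expect_equal(s1$area_mm2[s1$day >= 7], c(0, 0))
})

test_that("a simulated, rendered and re-extracted series matches the truth", {
  # round trip through the image pipeline: relative error below 5% once
  # the disk radius reaches 8 px
  state <- data.frame(plant = 1, A = 1400, x_mid = 20, scal = 5)
  cfg <- sim_config(noise_sd = 0, imaging_interval = 7, duration = 42,
                    scale_mm_per_px = 1)
  truth_series <- simulate_growth_series(state, cfg)
  lay <- pot_layout(rows = 3, cols = 4, cell_px = 50)
  pot1 <- lay$cells$pot[lay$cells$used][1]
  imgs <- lapply(truth_series$area_mm2, function(a) {
    render_tray_image(data.frame(pot = pot1, area_mm2 = a), lay, 1)$image
  })
  ser <- build_area_series(imgs, truth_series$day, lay)
  got <- ser$area_mm2[ser$pot == pot1]
  r_px <- sqrt(truth_series$area_mm2 / pi)
  big <- r_px >= 8
  expect_true(any(big))
  expect_true(all(abs(got[big] - truth_series$area_mm2[big]) /
                    truth_series$area_mm2[big] < 0.05))
})

test_that("tray images survive a PNG write/read cycle", {
  fx <- small_tray_fixture(n_plants = 3)
  path <- withr::local_tempfile(fileext = ".png")
  write_tray_image(fx$image, path)
  back <- read_tray_image(path, fx$scale)
  expect_equal(dim(back$pixels), dim(fx$image$pixels))
  m1 <- segment_plant_pixels(fx$image)
  m2 <- segment_plant_pixels(back)
  expect_identical(m1, m2)
})
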