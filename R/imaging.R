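# Tray image -> per-pot rosette area. Segmentation keeps pixels whose hue
# falls in a green window or a red window (red catches anthocyanin-tinged
# stressed leaves); the two masks are merged by pixelwise union, pixels
# are summed per pot cell, and counts are converted to mm^2 with the
# tray's scalar calibration.

#' Colour-range segmentation configuration
#'
#' Plant pixels are accepted when their HSV hue lies in the green window
#' or in the red window and the pixel is saturated and bright enough to
#' be vegetation rather than background or soil. Hue is on the [0, 1]
#' circle (green near 1/3, red near 0/1).
#'
#' @param green_hue Length-2 hue window `c(low, high)` with
#'   `low <= high` (default `c(0.20, 0.45)`).
#' @param red_hue Length-2 hue window (default `c(0.88, 1.00)`).
#' @param min_saturation Minimum HSV saturation (default 0.25).
#' @param min_value Minimum HSV value (default 0.15).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(green_hue = c(0.20, 0.45),
                                red_hue = c(0.88, 1.00),
                                min_saturation = 0.25,
                                min_value = 0.15) {
  for (rng in list(green_hue, red_hue)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 1) {
      stopf("hue windows must be c(low, high) with 0 <= low <= high <= 1")
    }
  }
  if (min_saturation < 0 || min_saturation > 1 || min_value < 0 || min_value > 1) {
    stopf("min_saturation and min_value must lie in [0, 1]")
  }
  structure(list(green_hue = green_hue, red_hue = red_hue,
                 min_saturation = min_saturation, min_value = min_value),
            class = "segmentation_config")
}

#' Segment plant pixels from a tray image
#'
#' Produces the union (pixelwise OR) of a green-range mask and a
#' red-range mask, so both healthy green tissue and reddened stressed
#' tissue count as plant.
#'
#' @param image A [tray_image()].
#' @param cfg A [segmentation_config()].
#' @return Logical matrix `height x width`; `TRUE` marks plant pixels.
#' @export
segment_plant_pixels <- function(image, cfg = segmentation_config()) {
  px <- image$pixels
  d <- dim(px)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  ok_sv <- hsv[2, ] >= cfg$min_saturation & hsv[3, ] >= cfg$min_value
  in_green <- hsv[1, ] >= cfg$green_hue[1] & hsv[1, ] <= cfg$green_hue[2] & ok_sv
  in_red <- hsv[1, ] >= cfg$red_hue[1] & hsv[1, ] <= cfg$red_hue[2] & ok_sv
  matrix(in_green | in_red, nrow = d[1], ncol = d[2])
}

#' Count plant pixels per pot and convert to area
#'
#' Sums mask pixels within each used pot cell and converts the count to
#' mm^2 with the square of the scalar mm-per-pixel calibration. Unused
#' pots are absent from the result (not reported as zero).
#'
#' @param mask Logical matrix from [segment_plant_pixels()].
#' @param layout A [pot_layout()] whose cells lie within the mask.
#' @param scale_mm_per_px Millimetres per pixel.
#' @return Data frame with one row per used pot: `pot`, `row`, `col`,
#'   `pixels`, `area_mm2` (= `pixels * scale^2`).
#' @export
count_and_convert <- function(mask, layout, scale_mm_per_px) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (scale_mm_per_px <= 0) stopf("scale_mm_per_px must be > 0")
  validate_layout_against(layout, ncol(mask), nrow(mask))
  cells <- layout$cells[layout$cells$used, , drop = FALSE]
  counts <- vapply(seq_len(nrow(cells)), function(i) {
    # half-open [x0, x1) in 0-based coords -> 1-based matrix indices
    sum(mask[(cells$y0[i] + 1):cells$y1[i], (cells$x0[i] + 1):cells$x1[i]])
  }, integer(1))
  data.frame(pot = cells$pot, row = cells$row, col = cells$col,
             pixels = counts, area_mm2 = counts * scale_mm_per_px^2)
}

#' Extract per-plant area time series from a stack of tray images
#'
#' Applies segmentation and per-pot counting to each time point and
#' assembles one area series per used pot, sorted by day. Days with no
#' image leave gaps in the series rather than zeros.
#'
#' @param images List of [tray_image()]s, one per imaging day.
#' @param days Numeric vector of imaging days (same length as `images`,
#'   no duplicates).
#' @param layout A [pot_layout()], constant across time points.
#' @param cfg A [segmentation_config()].
#' @return Data frame in long format: `pot`, `day`, `area_mm2`, ordered
#'   by pot then day.
#' @export
build_area_series <- function(images, days, layout, cfg = segmentation_config()) {
  if (length(images) != length(days)) {
    stopf("need one imaging day per image (%d images, %d days)",
          length(images), length(days))
  }
  if (anyDuplicated(days)) {
    stopf("duplicate imaging day for the same tray: %s",
          paste(unique(days[duplicated(days)]), collapse = ", "))
  }
  per_day <- lapply(seq_along(images), function(i) {
    counts <- count_and_convert(segment_plant_pixels(images[[i]], cfg), layout,
                                images[[i]]$scale_mm_per_px)
    data.frame(pot = counts$pot, day = days[i], area_mm2 = counts$area_mm2)
  })
  out <- do.call(rbind, per_day)
  out[order(out$pot, out$day), , drop = FALSE]
}
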