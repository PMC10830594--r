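# Synthetic tray rendering: plants drawn as filled colour disks on a
# uniform out-of-range background, with exact per-pot pixel counts
# returned as ground truth for the imaging pipeline.

#' A calibrated RGB tray image
#'
#' @param pixels Numeric array `height x width x 3` with values in [0, 1].
#' @param scale_mm_per_px Millimetres per pixel (> 0).
#' @return An object of class `tray_image`.
#' @export
tray_image <- function(pixels, scale_mm_per_px) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stopf("tray image must be a height x width x 3 array")
  }
  if (scale_mm_per_px <= 0) stopf("scale_mm_per_px must be > 0")
  structure(list(pixels = pixels, scale_mm_per_px = scale_mm_per_px),
            class = "tray_image")
}

#' @export
print.tray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tray_image> %d x %d px, %.3f mm/px\n", d[1], d[2],
              x$scale_mm_per_px))
  invisible(x)
}

#' Render a synthetic tray image with known per-pot pixel truth
#'
#' Draws each plant as a filled disk centred in its pot cell, sized so the
#' disk's pixel count matches the requested rosette area at the image
#' scale. The background is a uniform colour outside both segmentation
#' colour ranges (default mid grey, zero saturation). The exact number of
#' disk pixels per pot is returned, giving the imaging pipeline a known
#' ground truth.
#'
#' @param areas Data frame with columns `pot` and `area_mm2` (one row per
#'   plant; pots absent from `areas`, and unused pots, stay empty).
#' @param layout A [pot_layout()].
#' @param scale_mm_per_px Millimetres per pixel (default 1.25).
#' @param plant_rgb Disk colour, length-3 RGB in [0, 1] (default a
#'   saturated green, hue approximately 1/3).
#' @param background_rgb Background colour (default mid grey).
#' @return List with `image` (a [tray_image()]) and `truth` (data frame
#'   `pot`, `pixels` with the exact drawn pixel count per used pot).
#' @details A disk of area `a` mm^2 needs `a / scale^2` pixels, i.e.
#'   radius `sqrt(a / scale^2 / pi)` px. Rendering refuses disks whose
#'   diameter exceeds the pot cell, mirroring the experimental design in
#'   which plants are kept from growing into each other.
#' @export
render_tray_image <- function(areas, layout, scale_mm_per_px = 1.25,
                              plant_rgb = c(0.1, 0.75, 0.15),
                              background_rgb = c(0.5, 0.5, 0.5)) {
  stopifnot(is.data.frame(areas), all(c("pot", "area_mm2") %in% names(areas)))
  cells <- layout$cells
  unknown <- setdiff(areas$pot, cells$pot)
  if (length(unknown)) stopf("unknown pot id(s): %s", paste(unknown, collapse = ", "))
  if (any(!cells$used[match(areas$pot, cells$pot)])) {
    stopf("areas reference unused pots")
  }
  h <- layout$height; w <- layout$width
  img <- array(rep(background_rgb, each = h * w), dim = c(h, w, 3))
  truth <- data.frame(pot = cells$pot[cells$used], pixels = 0L)

  for (i in seq_len(nrow(areas))) {
    a <- areas$area_mm2[i]
    if (is.na(a) || a <= 0) next
    npix <- a / scale_mm_per_px^2
    r <- sqrt(npix / pi)
    cell <- cells[cells$pot == areas$pot[i], ]
    if (2 * r > layout$cell_px) {
      stopf("pot %d: disk of radius %.1f px overflows its %d px cell",
            cell$pot, r, layout$cell_px)
    }
    # pixel centres at integer 0-based coordinates; cell centre of the
    # half-open rectangle [x0, x1) is at (x0 + x1 - 1) / 2
    cx <- (cell$x0 + cell$x1 - 1) / 2
    cy <- (cell$y0 + cell$y1 - 1) / 2
    xs <- cell$x0:(cell$x1 - 1)
    ys <- cell$y0:(cell$y1 - 1)
    inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
    n_in <- sum(inside)
    rows <- ys[row(inside)[inside]] + 1L
    colsx <- xs[col(inside)[inside]] + 1L
    for (ch in 1:3) img[cbind(rows, colsx, ch)] <- plant_rgb[ch]
    truth$pixels[truth$pot == cell$pot] <- n_in
  }
  list(image = tray_image(img, scale_mm_per_px), truth = truth)
}

#' Read and write calibrated tray images
#'
#' PNG is read natively; TIFF is supported when the `tiff` package is
#' available. Alpha channels are dropped; greyscale images are expanded to
#' three channels.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param scale_mm_per_px Calibration to attach (mm per pixel).
#' @param image A [tray_image()].
#' @return `read_tray_image()` returns a [tray_image()];
#'   `write_tray_image()` returns `path` invisibly.
#' @export
read_tray_image <- function(path, scale_mm_per_px) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stopf("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else stopf("unsupported image format '%s'", ext)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  tray_image(px, scale_mm_per_px)
}

#' @rdname read_tray_image
#' @export
write_tray_image <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}
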