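#' Pot-grid layout of a multipot tray
#'
#' Describes how a tray image tiles into pot cells: a `rows` x `cols` grid
#' of square cells of `cell_px` pixels, with half-open pixel rectangles
#' `[x0, x1) x [y0, y1)` in 0-based image coordinates so cells tile the
#' tray exactly without overlap. Only every second pot is used (a
#' checkerboard), which keeps rosettes from growing into each other and
#' makes per-pot pixel counting unambiguous; the default 6 x 9 grid is a
#' 54-pot tray with 27 usable pots.
#'
#' @param rows,cols Grid dimensions (default 6 x 9).
#' @param cell_px Side of one pot cell in pixels (default 40).
#' @param origin Pixel offset `c(x, y)` of the grid's top-left corner
#'   (default `c(0, 0)`).
#' @param every_second Use only pots on a checkerboard pattern (default
#'   TRUE). With `FALSE` all pots are used.
#' @return An object of class `pot_layout`: a list with `rows`, `cols`,
#'   `cell_px`, `width`, `height` (pixel extent) and `cells`, a data frame
#'   with one row per pot (`pot` id, 0-based `row`/`col`, rectangle
#'   `x0,x1,y0,y1`, logical `used`).
#' @export
pot_layout <- function(rows = 6, cols = 9, cell_px = 40, origin = c(0, 0),
                       every_second = TRUE) {
  if (rows < 1 || cols < 1) stopf("layout needs at least one row and column")
  if (cell_px < 2) stopf("cell_px must be at least 2")
  grid <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  cells <- data.frame(
    pot = seq_len(rows * cols),
    row = grid$row,
    col = grid$col,
    x0 = origin[1] + grid$col * cell_px,
    y0 = origin[2] + grid$row * cell_px
  )
  cells$x1 <- cells$x0 + cell_px
  cells$y1 <- cells$y0 + cell_px
  cells$used <- if (every_second) (cells$row + cells$col) %% 2 == 0 else TRUE
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_px = as.integer(cell_px),
                 width = as.integer(origin[1] + cols * cell_px),
                 height = as.integer(origin[2] + rows * cell_px),
                 cells = cells),
            class = "pot_layout")
}

#' @export
print.pot_layout <- function(x, ...) {
  cat(sprintf("<pot_layout> %d x %d pots (%d used), cell %d px, image %d x %d px\n",
              x$rows, x$cols, sum(x$cells$used), x$cell_px, x$width, x$height))
  invisible(x)
}

# Cells must not overlap and must lie inside the given pixel extent.
#' @noRd
validate_layout_against <- function(layout, width, height) {
  cells <- layout$cells
  if (any(cells$x0 < 0 | cells$y0 < 0 | cells$x1 > width | cells$y1 > height)) {
    stopf("pot cells extend beyond the %d x %d image", width, height)
  }
  n <- nrow(cells)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      overlap <- cells$x0[j] < cells$x1[i] & cells$x1[j] > cells$x0[i] &
        cells$y0[j] < cells$y1[i] & cells$y1[j] > cells$y0[i]
      if (any(overlap)) stopf("pot cells %d and %d overlap", i, j[which(overlap)[1]])
    }
  }
  invisible(layout)
}

#' Write or read a pot layout as YAML
#'
#' @param layout A [pot_layout()] object.
#' @param path File path.
#' @return `read_pot_layout()` returns a `pot_layout`;
#'   `write_pot_layout()` returns `path` invisibly.
#' @export
write_pot_layout <- function(layout, path) {
  yaml::write_yaml(list(
    rows = layout$rows, cols = layout$cols, cell_px = layout$cell_px,
    width = layout$width, height = layout$height,
    used_pots = layout$cells$pot[layout$cells$used]
  ), path)
  invisible(path)
}

#' @rdname write_pot_layout
#' @export
read_pot_layout <- function(path) {
  spec <- yaml::read_yaml(path)
  lay <- pot_layout(rows = spec$rows, cols = spec$cols, cell_px = spec$cell_px)
  lay$cells$used <- lay$cells$pot %in% unlist(spec$used_pots)
  lay
}
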