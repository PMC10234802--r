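#' Generate a regular analysis grid
#'
#' Builds a rectangular lattice of square cells in abstract planar meter
#' coordinates. Cell `(row, col)` (both 0-based, row 0 at the bottom) spans
#' `[col * cell_size, (col + 1) * cell_size] x [row * cell_size,
#' (row + 1) * cell_size]`. Cell ids are row-major integers starting at 1, so
#' `cell_id = row * ncols + col + 1`.
#'
#' @param nrows,ncols Number of rows/columns; both must be at least 2.
#' @param cell_size Side length of each square cell, in meters.
#'
#' @return An object of class `fs_grid`: a list with elements `cells` (a
#'   data.frame with columns `cell_id`, `row`, `col`, `xmin`, `ymin`, `xmax`,
#'   `ymax`), `nrows`, `ncols`, `cell_size`, and `extent`
#'   (`c(xmin, ymin, xmax, ymax)`).
#' @examples
#' g <- generate_grid(2, 2, 300)
#' nrow(g$cells)         # 4
#' with(g$cells, (xmax - xmin) * (ymax - ymin))  # each 90000 m^2
#' @export
generate_grid <- function(nrows, ncols, cell_size = 300) {
  if (length(nrows) != 1L || length(ncols) != 1L || is.na(nrows) || is.na(ncols) ||
      nrows != as.integer(nrows) || ncols != as.integer(ncols)) {
    stop("`nrows` and `ncols` must be single whole numbers", call. = FALSE)
  }
  nrows <- as.integer(nrows)
  ncols <- as.integer(ncols)
  if (nrows < 2L || ncols < 2L) {
    stop("grid must have at least 2 rows and 2 columns (got ",
         nrows, " x ", ncols, ")", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number (meters)", call. = FALSE)
  }
  row <- rep(0:(nrows - 1L), each = ncols)
  col <- rep(0:(ncols - 1L), times = nrows)
  cells <- data.frame(
    cell_id = seq_len(nrows * ncols),
    row = row,
    col = col,
    xmin = col * cell_size,
    ymin = row * cell_size,
    xmax = (col + 1) * cell_size,
    ymax = (row + 1) * cell_size
  )
  structure(
    list(cells = cells, nrows = nrows, ncols = ncols, cell_size = cell_size,
         extent = c(xmin = 0, ymin = 0,
                    xmax = ncols * cell_size, ymax = nrows * cell_size)),
    class = "fs_grid"
  )
}

#' @export
print.fs_grid <- function(x, ...) {
  cat(sprintf("<fs_grid> %d x %d cells of %g m (%d cells, %.1f km x %.1f km)\n",
              x$nrows, x$ncols, x$cell_size, x$nrows * x$ncols,
              x$ncols * x$cell_size / 1000, x$nrows * x$cell_size / 1000))
  invisible(x)
}

n_cells <- function(grid) grid$nrows * grid$ncols

#' Map (row, col) indices to cell ids
#'
#' @param grid An `fs_grid`.
#' @param row,col 0-based row/column indices (vectorized).
#' @return Integer cell ids (row-major, starting at 1).
#' @keywords internal
cell_id_at <- function(grid, row, col) {
  as.integer(row) * grid$ncols + as.integer(col) + 1L
}

cell_centers <- function(grid) {
  cbind(x = (grid$cells$col + 0.5) * grid$cell_size,
        y = (grid$cells$row + 0.5) * grid$cell_size)
}

is_fs_grid <- function(x) inherits(x, "fs_grid")
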