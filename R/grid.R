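#' Define a planar raster grid
#'
#' A grid is a plain planar lattice in degree units: no projection or
#' great-circle handling. Cell values are stored in `n_rows x n_cols`
#' matrices with row 1 at the **north** edge; cells are numbered row-major
#' (cell 1 is the north-west corner). `origin_x`/`origin_y` give the
#' south-west (lower-left) corner, so the centroid of matrix element
#' `[row, col]` is at
#' `x = origin_x + (col - 0.5) * resolution`,
#' `y = origin_y + (n_rows - row + 0.5) * resolution`.
#'
#' @param origin_x,origin_y Coordinates of the lower-left corner (degrees).
#' @param resolution Cell size in degrees (one number; cells are square).
#' @param n_cols,n_rows Number of columns and rows.
#'
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(n_cols = 105, n_rows = 105, resolution = 0.1)
#' @export
grid_spec <- function(origin_x = 1, origin_y = 1, resolution = 0.1,
                      n_cols = 105, n_rows = 105) {
  stopifnot(is.numeric(resolution), resolution > 0,
            n_cols >= 1, n_rows >= 1,
            is.finite(origin_x), is.finite(origin_y))
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         resolution = as.numeric(resolution),
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols at %g deg, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$resolution, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

# row-major cell ids -> (row, col)
cell_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  stopifnot(all(cell >= 1L), all(cell <= n_cells(grid)))
  list(row = (cell - 1L) %/% grid$n_cols + 1L,
       col = (cell - 1L) %% grid$n_cols + 1L)
}

#' Cell centroid coordinates
#'
#' @param grid A [grid_spec()].
#' @param cell Integer row-major cell ids (1 = north-west corner cell).
#' @return A tibble with columns `cell`, `x`, `y`.
#' @export
cell_centroids <- function(grid, cell) {
  rc <- cell_rowcol(grid, cell)
  tibble(cell = as.integer(cell),
         x = grid$origin_x + (rc$col - 0.5) * grid$resolution,
         y = grid$origin_y + (grid$n_rows - rc$row + 0.5) * grid$resolution)
}

#' Locate points on a grid
#'
#' Maps x/y coordinates to row-major cell ids. Points outside the grid
#' extent are an error.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors (degrees).
#' @return Integer cell ids.
#' @export
point_to_cell <- function(grid, x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  col <- floor((x - grid$origin_x) / grid$resolution) + 1
  row <- grid$n_rows - floor((y - grid$origin_y) / grid$resolution)
  # points sitting exactly on the top/right boundary belong to the edge cell
  col[x == grid$origin_x + grid$n_cols * grid$resolution] <- grid$n_cols
  row[y == grid$origin_y + grid$n_rows * grid$resolution] <- 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  if (any(bad)) {
    stop(sprintf("%d point(s) fall outside the grid extent (first offender: x=%g, y=%g)",
                 sum(bad), x[which(bad)[1]], y[which(bad)[1]]), call. = FALSE)
  }
  as.integer((row - 1) * grid$n_cols + col)
}

# matrix (rows = north first) -> values in row-major cell order
mat_to_cells <- function(m) as.vector(t(m))

# row-major cell-order vector -> matrix
cells_to_mat <- function(v, grid) {
  matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}
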