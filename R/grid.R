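#' Regular 2D pixel grid specification
#'
#' Defines the raster every map in the package lives on. The grid is centred
#' on the origin: column index increases with +x, row index increases with -y,
#' and pixel centres are spaced `pixel_mm` apart. A point belongs to the pixel
#' whose centre is nearest under the half-open convention
#' `[centre - pixel/2, centre + pixel/2)` along x (mirrored along y).
#'
#' @param n_rows,n_cols grid dimensions in pixels (both at least 8).
#' @param pixel_mm pixel pitch in mm (default 1).
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(71, 91)
#' range(pixel_coords(g)$x)
#' @export
grid_spec <- function(n_rows, n_cols, pixel_mm = 1) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 8L || n_cols < 8L)
    stop("grid must be at least 8 x 8 pixels")
  if (!is.finite(pixel_mm) || pixel_mm <= 0)
    stop("pixel_mm must be positive")
  structure(list(n_rows = n_rows, n_cols = n_cols, pixel_mm = pixel_mm),
            class = "grid_spec")
}

#' Default applicator grid
#'
#' The linear applicator uses a 71 x 91 grid at 1 mm/pixel (breast between two
#' antenna rows); the circular applicator uses a square 91 x 91 grid so the
#' antenna ring fits around the breast.
#'
#' @param scheme `"linear"` or `"circular"`.
#' @return a [grid_spec()].
#' @export
default_grid <- function(scheme = c("linear", "circular")) {
  scheme <- match.arg(scheme)
  if (scheme == "linear") grid_spec(71, 91) else grid_spec(91, 91)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return list with `x` (length `n_cols`, increasing) and `y` (length
#'   `n_rows`, decreasing with row index), both in mm.
#' @export
pixel_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cx <- (grid$n_cols + 1) / 2
  cy <- (grid$n_rows + 1) / 2
  list(x = (seq_len(grid$n_cols) - cx) * grid$pixel_mm,
       y = (cy - seq_len(grid$n_rows)) * grid$pixel_mm)
}

#' Map points (mm) to pixel indices
#'
#' Uses the half-open pixel convention: a point belongs to the pixel whose
#' centre is within half a pixel below it along +x (mirrored along y).
#'
#' @param grid a [grid_spec()].
#' @param x,y point coordinates in mm.
#' @return a two-column `(row, col)` integer matrix; `NA` outside the grid.
#' @export
point_to_pixel <- function(grid, x, y) {
  co <- pixel_coords(grid)
  p <- grid$pixel_mm
  col <- floor((x - co$x[1]) / p + 0.5) + 1
  row <- floor((co$y[1] - y) / p + 0.5) + 1
  col[col < 1 | col > grid$n_cols] <- NA_integer_
  row[row < 1 | row > grid$n_rows] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Distance (mm) of every pixel centre from a point
#'
#' @param grid a [grid_spec()].
#' @param center point (x, y) in mm.
#' @return an `n_rows x n_cols` matrix of distances.
#' @export
pixel_distances <- function(grid, center) {
  co <- pixel_coords(grid)
  dx <- outer(rep(1, grid$n_rows), co$x - center[1])
  dy <- outer(co$y - center[2], rep(1, grid$n_cols))
  sqrt(dx^2 + dy^2)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$pixel_mm, b$pixel_mm))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels at %g mm/pixel (%g x %g mm)\n",
              x$n_rows, x$n_cols, x$pixel_mm,
              x$n_rows * x$pixel_mm, x$n_cols * x$pixel_mm))
  invisible(x)
}
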