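#' Discretization grid for attention and inhibition maps
#'
#' The model computes all maps on a regular grid of cell centers laid over
#' the image. Coordinates are continuous degrees of visual angle with the
#' origin at the lower-left image corner; cell `(i, j)` has its center at
#' `x_i = (i - 1/2) * extent_x / n_x`, `y_j = (j - 1/2) * extent_y / n_y`.
#' Maps are numeric matrices with `n_x` rows and `n_y` columns, so
#' `M[i, j]` is the value at `(x_i, y_j)`.
#'
#' @param n_x,n_y Number of cells along x and y (default 128 each, the
#'   discretization the model family was developed on).
#' @param extent_x,extent_y Image size in degrees of visual angle.
#' @return An object of class `sw_grid`: a list with `n_x`, `n_y`,
#'   `extent_x`, `extent_y` and the cell-center vectors `xs`, `ys`.
#' @examples
#' g <- sw_grid(64, 48, extent_x = 32, extent_y = 24)
#' dim(gaussian_map(c(16, 12), 3, g))
#' @export
sw_grid <- function(n_x = 128, n_y = 128, extent_x = 32, extent_y = 24) {
  stopifnot(n_x >= 2, n_y >= 2, extent_x > 0, extent_y > 0)
  n_x <- as.integer(n_x)
  n_y <- as.integer(n_y)
  g <- list(
    n_x = n_x, n_y = n_y,
    extent_x = extent_x, extent_y = extent_y,
    xs = (seq_len(n_x) - 0.5) * (extent_x / n_x),
    ys = (seq_len(n_y) - 0.5) * (extent_y / n_y)
  )
  class(g) <- "sw_grid"
  g
}

#' @export
print.sw_grid <- function(x, ...) {
  cat(sprintf(
    "<sw_grid> %d x %d cells over %.3g x %.3g degrees (cell %.3g x %.3g)\n",
    x$n_x, x$n_y, x$extent_x, x$extent_y,
    x$extent_x / x$n_x, x$extent_y / x$n_y
  ))
  invisible(x)
}

is_sw_grid <- function(x) inherits(x, "sw_grid")

#' Map degree coordinates to grid cells and back
#'
#' `deg_to_cell()` returns the (1-based) index of the cell whose center is
#' nearest to a point; coordinates outside the image extent are clamped to
#' the border cell. `cell_to_deg()` returns the cell-center coordinates.
#'
#' @param p Numeric vector `c(x, y)` in degrees, or an n-by-2 matrix of
#'   points.
#' @param idx Integer vector `c(i, j)`, or an n-by-2 matrix of indices.
#' @param grid An [sw_grid()].
#' @return For `deg_to_cell()`, an integer vector `c(i, j)` (or n-by-2
#'   matrix); for `cell_to_deg()`, numeric degrees in the same shape.
#' @examples
#' g <- sw_grid(5, 5, 10, 10)
#' deg_to_cell(c(5, 5), g)       # the middle cell
#' cell_to_deg(c(3, 3), g)
#' @export
deg_to_cell <- function(p, grid) {
  stopifnot(is_sw_grid(grid))
  m <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
  i <- pmin(pmax(floor(m[, 1] / (grid$extent_x / grid$n_x)) + 1, 1), grid$n_x)
  j <- pmin(pmax(floor(m[, 2] / (grid$extent_y / grid$n_y)) + 1, 1), grid$n_y)
  out <- cbind(as.integer(i), as.integer(j))
  if (is.matrix(p)) out else out[1, ]
}

#' @rdname deg_to_cell
#' @export
cell_to_deg <- function(idx, grid) {
  stopifnot(is_sw_grid(grid))
  m <- if (is.matrix(idx)) idx else matrix(idx, ncol = 2)
  stopifnot(all(m[, 1] >= 1), all(m[, 1] <= grid$n_x),
            all(m[, 2] >= 1), all(m[, 2] <= grid$n_y))
  out <- cbind(grid$xs[m[, 1]], grid$ys[m[, 2]])
  if (is.matrix(idx)) out else out[1, ]
}

#' Two-dimensional Gaussian evaluated on the grid
#'
#' Evaluates the (unnormalized-by-grid) bivariate Gaussian density
#' `G(x, y) = 1 / (2 pi sx sy) * exp(-(x - cx)^2 / (2 sx^2) - (y - cy)^2 / (2 sy^2))`
#' at every cell center. This is the aperture used by both the attention
#' stream (width `sigma_A`) and the inhibitory fixation tagging stream
#' (width `sigma_F`). Downstream the model always renormalizes by the
#' discrete grid sum, so Gaussians are implicitly border-truncated.
#'
#' @param center Numeric `c(x, y)` in degrees. May lie outside the image
#'   (e.g. a post-saccadic remap location); the map is then truncated.
#' @param sigma Standard deviation in degrees; a scalar or `c(sx, sy)`.
#' @inheritParams deg_to_cell
#' @return A `n_x` by `n_y` numeric matrix, positive everywhere.
#' @export
gaussian_map <- function(center, sigma, grid) {
  stopifnot(is_sw_grid(grid), length(center) == 2, all(is.finite(center)))
  sigma <- rep_len(as.numeric(sigma), 2)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be strictly positive", call. = FALSE)
  }
  gx <- exp(-(grid$xs - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(grid$ys - center[2])^2 / (2 * sigma[2]^2))
  (1 / (2 * pi * sigma[1] * sigma[2])) * outer(gx, gy)
}

#' Normalize a map to unit discrete sum
#'
#' All normalizations in the model are plain discrete sums over grid cells
#' (no cell-area factor), matching the model's sum-over-cells notation.
#'
#' @param M Nonnegative numeric matrix.
#' @return `M / sum(M)`.
#' @export
normalize_map <- function(M) {
  s <- sum(M)
  if (!is.finite(s) || s <= 0) {
    stop("map must have a positive, finite sum", call. = FALSE)
  }
  M / s
}

#' Uniform probability map on a grid
#'
#' @inheritParams deg_to_cell
#' @return Matrix with every cell `1 / (n_x * n_y)`.
#' @export
uniform_map <- function(grid) {
  stopifnot(is_sw_grid(grid))
  matrix(1 / (grid$n_x * grid$n_y), grid$n_x, grid$n_y)
}
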