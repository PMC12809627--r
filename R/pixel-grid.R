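#' Square pixel grid over the visual field
#'
#' Defines the field of view on which stimuli and receptive fields are
#' rendered. Pixel centers are placed at `n_pixels` evenly spaced points from
#' `-fov_half` to `+fov_half` degrees, endpoints inclusive, on both axes.
#' x increases rightward, y increases upward. All images produced on a grid
#' are matrices indexed `[ix, iy]` so that `img[ix, iy]` is the luminance at
#' `(coords[ix], coords[iy])`.
#'
#' The sampling (Nyquist) frequency limit is `1 / (2 * spacing)` cycles per
#' degree; stimuli must stay strictly below it.
#'
#' @param fov_half half-extent of the field of view, degrees (default 60,
#'   i.e. a 120 x 120 degree field).
#' @param n_pixels number of pixels per side (default 200).
#' @return an object of class `pixel_grid` with elements `fov_half`,
#'   `n_pixels`, `coords` (pixel-center coordinates, degrees), `spacing`
#'   (degrees/pixel) and `nyquist` (cycles/degree).
#' @examples
#' g <- pixel_grid(60, 200)
#' g$nyquist
#' @export
pixel_grid <- function(fov_half = 60, n_pixels = 200) {
  stopifnot(is.numeric(fov_half), length(fov_half) == 1, fov_half > 0,
            is.numeric(n_pixels), length(n_pixels) == 1, n_pixels >= 2)
  n_pixels <- as.integer(n_pixels)
  coords <- seq(-fov_half, fov_half, length.out = n_pixels)
  spacing <- coords[2] - coords[1]
  structure(
    list(fov_half = fov_half, n_pixels = n_pixels, coords = coords,
         spacing = spacing, nyquist = 1 / (2 * spacing)),
    class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("pixel_grid: %d x %d px over [%g, %g] deg (%.4g deg/px, Nyquist %.3g cpd)\n",
              x$n_pixels, x$n_pixels, -x$fov_half, x$fov_half, x$spacing, x$nyquist))
  invisible(x)
}

#' Coordinate meshes for a pixel grid
#'
#' @param grid a [pixel_grid()].
#' @return list with matrices `x` and `y`, each `n_pixels` square, giving the
#'   coordinates of every pixel center (`x[ix, iy] == coords[ix]`).
#' @export
grid_mesh <- function(grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  n <- grid$n_pixels
  list(x = matrix(grid$coords, n, n),
       y = matrix(grid$coords, n, n, byrow = TRUE))
}

# stop if a stimulus frequency would alias on this grid
assert_below_nyquist <- function(grid, sf) {
  if (any(sf >= grid$nyquist)) {
    stop(sprintf("spatial frequency %g cpd is at or above the grid Nyquist limit (%g cpd)",
                 max(sf), grid$nyquist), call. = FALSE)
  }
  invisible(TRUE)
}

# index of the pixel whose center is closest to 0 (exact 0 on odd grids)
grid_origin_index <- function(grid) which.min(abs(grid$coords))
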