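#' Render a sinusoidal grating
#'
#' Renders a full-field static sinusoidal grating at 100% contrast on a
#' mid-gray (0) background convention: luminance ranges over \[-1, 1\].
#'
#' Orientation follows the intuitive convention in which a *horizontal*
#' grating (horizontal stripes, luminance varying along y) is 0 degrees and
#' angles increase counterclockwise, so orientation coincides with the polar
#' angle of the stripes. Internally this is converted to the wave-vector
#' angle `theta_g = -pi * (orientation + 90) / 180` and the image is
#' `cos(2 pi sf (cos(theta_g) x + sin(theta_g) y) + phase)`.
#'
#' @param grid a [pixel_grid()].
#' @param orientation grating orientation theta_c in degrees (interpreted
#'   mod 180).
#' @param sf spatial frequency, cycles/degree; must be below the grid
#'   Nyquist limit.
#' @param phase grating phase, radians.
#' @return luminance image (matrix `[ix, iy]`) with values in \[-1, 1\].
#' @examples
#' g <- pixel_grid(60, 121)
#' img <- render_grating(g, orientation = 0, sf = 0.04)
#' @export
render_grating <- function(grid, orientation, sf, phase = 0) {
  stopifnot(inherits(grid, "pixel_grid"), is.numeric(orientation),
            is.numeric(sf), sf > 0, is.numeric(phase))
  assert_below_nyquist(grid, sf)
  tg <- grating_angle(orientation)
  ax <- 2 * pi * sf * cos(tg) * grid$coords
  ay <- 2 * pi * sf * sin(tg) * grid$coords
  cos(outer(ax, ay, "+") + phase)
}

# wave-vector angle (radians) from the stripe-orientation convention; with
# y increasing upward the counterclockwise-positive convention needs the
# wave vector at orientation + 90 (a negated angle here would rotate
# orientations clockwise and mirror every oblique preference)
grating_angle <- function(orientation) pi * (orientation + 90) / 180

#' Aperture specification
#'
#' Hard-edged aperture through which a stimulus is shown; pixels whose
#' centers fall outside take the background luminance 0. Membership is
#' decided by pixel-center inclusion with `<=` boundary tests.
#'
#' Shapes:
#' * `"circle"`: `x^2 + y^2 <= radius^2`.
#' * `"square"`: `|x| <= side/2` and `|y| <= side/2`.
#' * `"diamond"`: the square rotated 45 degrees about the origin,
#'   `|x| + |y| <= side / sqrt(2)`.
#' * `"half_plane_horizontal_edge"`: keeps the upper half plane `y >= 0`
#'   (a horizontal edge through the origin). Combine with another aperture
#'   by applying both in sequence.
#' * `"half_plane_vertical_edge"`: keeps the right half plane `x >= 0`.
#' * `"none"`: no vignetting.
#'
#' @param shape one of the shapes above.
#' @param radius circle radius, degrees.
#' @param side square/diamond side length, degrees.
#' @return an object of class `aperture`.
#' @export
aperture <- function(shape = c("circle", "square", "diamond",
                               "half_plane_horizontal_edge",
                               "half_plane_vertical_edge", "none"),
                     radius = NULL, side = NULL) {
  shape <- match.arg(shape)
  if (shape == "circle" && (is.null(radius) || radius <= 0))
    stop("circle aperture requires a positive 'radius'")
  if (shape %in% c("square", "diamond") && (is.null(side) || side <= 0))
    stop(sprintf("%s aperture requires a positive 'side'", shape))
  structure(list(shape = shape, radius = radius, side = side),
            class = "aperture")
}

#' @export
print.aperture <- function(x, ...) {
  dim <- switch(x$shape,
                circle = sprintf(" radius %g deg", x$radius),
                square = , diamond = sprintf(" side %g deg", x$side), "")
  cat(sprintf("aperture: %s%s\n", x$shape, dim))
  invisible(x)
}

#' Logical membership mask of an aperture on a grid
#'
#' @param ap an [aperture()].
#' @param grid a [pixel_grid()].
#' @return logical matrix, TRUE where the pixel center lies inside.
#' @export
aperture_mask <- function(ap, grid) {
  stopifnot(inherits(ap, "aperture"), inherits(grid, "pixel_grid"))
  m <- grid_mesh(grid)
  switch(ap$shape,
         circle = m$x^2 + m$y^2 <= ap$radius^2,
         square = abs(m$x) <= ap$side / 2 & abs(m$y) <= ap$side / 2,
         diamond = abs(m$x) + abs(m$y) <= ap$side / sqrt(2),
         half_plane_horizontal_edge = m$y >= 0,
         half_plane_vertical_edge = m$x >= 0,
         none = matrix(TRUE, grid$n_pixels, grid$n_pixels),
         stop("unknown aperture shape: ", ap$shape))
}

#' Apply an aperture to a luminance image
#'
#' Pixels strictly outside the aperture are set to the background value 0;
#' pixels inside are unchanged. Applying an aperture twice equals applying
#' it once.
#'
#' @param img luminance image from the same grid.
#' @param ap an [aperture()].
#' @param grid the [pixel_grid()] the image was rendered on.
#' @return the vignetted image.
#' @export
apply_aperture <- function(img, ap, grid) {
  stopifnot(is.matrix(img), all(dim(img) == grid$n_pixels))
  if (ap$shape == "none") return(img)
  img[!aperture_mask(ap, grid)] <- 0
  img
}

#' Build a battery of apertured gratings
#'
#' One image per combination of orientation, phase, spatial frequency and
#' aperture. The default battery is the standard probe set: 12 orientations
#' in 15-degree steps and 4 phases in 90-degree steps.
#'
#' @param grid a [pixel_grid()].
#' @param orientations orientations in degrees.
#' @param phases phases in degrees.
#' @param sfs spatial frequencies, cycles/degree.
#' @param apertures a single [aperture()] or a list of apertures.
#' @return an object of class `stimulus_set`: list with `images` (list of
#'   matrices) and `meta` (data.frame with columns `orientation`, `phase`,
#'   `sf`, `aperture`).
#' @export
grating_battery <- function(grid,
                            orientations = seq(0, 165, by = 15),
                            phases = c(0, 90, 180, 270),
                            sfs = 0.04,
                            apertures = aperture("none")) {
  stopifnot(length(orientations) > 0, length(phases) > 0, length(sfs) > 0)
  if (inherits(apertures, "aperture")) apertures <- list(apertures)
  stopifnot(length(apertures) > 0,
            all(vapply(apertures, inherits, TRUE, "aperture")))
  ap_lab <- vapply(apertures, function(a) {
    paste0(a$shape, if (!is.null(a$radius)) paste0("_r", a$radius)
           else if (!is.null(a$side)) paste0("_s", a$side) else "")
  }, "")
  meta <- expand.grid(orientation = orientations, phase = phases, sf = sfs,
                      aperture = ap_lab, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  masks <- lapply(apertures, aperture_mask, grid = grid)
  names(masks) <- ap_lab
  images <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    img <- render_grating(grid, meta$orientation[i], meta$sf[i],
                          meta$phase[i] * pi / 180)
    img[!masks[[meta$aperture[i]]]] <- 0
    images[[i]] <- img
  }
  structure(list(images = images, meta = meta, grid = grid),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set: %d images (%d orientations x %d phases x %d sfs x %d apertures)\n",
              length(x$images), length(unique(x$meta$orientation)),
              length(unique(x$meta$phase)), length(unique(x$meta$sf)),
              length(unique(x$meta$aperture))))
  invisible(x)
}

#' Moving-bar stimulus specification
#'
#' A light bar (luminance 1) swept across a simulated display. The display
#' window has background luminance 0 and the area outside it ("offscreen")
#' luminance -1. Display edges are treated either as a `mask` (the bar slides
#' behind the edge and is clipped) or as a `boundary` (no frame is produced
#' once the bar would cross the display edge along its motion axis; the last
#' presented frame is the one whose leading edge exactly meets the edge).
#'
#' @param orientation `"vertical"` (bar sweeps along x) or `"horizontal"`
#'   (bar sweeps along y).
#' @param positions bar center positions along the motion axis, degrees.
#' @param width bar width, degrees (default 2).
#' @param display display window `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param edge_mode `"mask"` or `"boundary"`.
#' @return an object of class `bar_spec`.
#' @export
bar_stimulus_spec <- function(orientation = c("vertical", "horizontal"),
                              positions = seq(-30, 30, by = 0.25),
                              width = 2,
                              display = c(-30, 0, -30, 30),
                              edge_mode = c("mask", "boundary")) {
  orientation <- match.arg(orientation)
  edge_mode <- match.arg(edge_mode)
  if (width <= 0) stop("bar width must be positive")
  stopifnot(length(display) == 4, display[1] < display[2], display[3] < display[4])
  structure(list(orientation = orientation, positions = positions,
                 width = width, display = display, edge_mode = edge_mode),
            class = "bar_spec")
}

# display-only image: offscreen -1, display window 0
display_background <- function(display, grid) {
  m <- grid_mesh(grid)
  img <- matrix(-1, grid$n_pixels, grid$n_pixels)
  inside <- m$x >= display[1] & m$x <= display[2] &
            m$y >= display[3] & m$y <= display[4]
  img[inside] <- 0
  img
}

# positions retained under boundary semantics: bar wholly inside the display
# along its motion axis (last frame: leading edge exactly at the edge)
bar_boundary_positions <- function(spec) {
  lim <- if (spec$orientation == "vertical") spec$display[1:2] else spec$display[3:4]
  keep <- spec$positions - spec$width / 2 >= lim[1] &
          spec$positions + spec$width / 2 <= lim[2]
  spec$positions[keep]
}

#' Render bar stimulus frames
#'
#' In `mask` mode one frame is produced per center position; positions where
#' the bar lies entirely outside the display yield "blank" frames (display
#' background only). In `boundary` mode frames are only produced while the
#' bar is wholly inside the display along its motion axis.
#'
#' @param spec a [bar_stimulus_spec()].
#' @param grid a [pixel_grid()].
#' @param include_blank append one explicit blank (no-bar) frame, used for
#'   baseline estimation in boundary mode (default TRUE).
#' @return list with `frames` (list of luminance matrices), `meta`
#'   (data.frame: `orientation`, `center`, `is_blank`), and `background`
#'   (the display-only image).
#' @export
render_bar_frames <- function(spec, grid, include_blank = TRUE) {
  stopifnot(inherits(spec, "bar_spec"), inherits(grid, "pixel_grid"))
  if (spec$display[1] < -grid$fov_half || spec$display[2] > grid$fov_half ||
      spec$display[3] < -grid$fov_half || spec$display[4] > grid$fov_half)
    stop("display window must lie inside the grid field of view")
  bg <- display_background(spec$display, grid)
  m <- grid_mesh(grid)
  in_disp <- m$x >= spec$display[1] & m$x <= spec$display[2] &
             m$y >= spec$display[3] & m$y <= spec$display[4]
  centers <- if (spec$edge_mode == "boundary") bar_boundary_positions(spec) else spec$positions
  axis_coord <- if (spec$orientation == "vertical") m$x else m$y
  frames <- vector("list", length(centers))
  blank <- logical(length(centers))
  for (i in seq_along(centers)) {
    img <- bg
    bar <- abs(axis_coord - centers[i]) <= spec$width / 2 & in_disp
    img[bar] <- 1
    frames[[i]] <- img
    blank[i] <- !any(bar)
  }
  meta <- data.frame(orientation = rep(spec$orientation, length(centers)),
                     center = centers, is_blank = blank,
                     stringsAsFactors = FALSE)
  if (include_blank) {
    frames <- c(frames, list(bg))
    meta <- rbind(meta, data.frame(orientation = "blank", center = NA_real_,
                                   is_blank = TRUE))
  }
  list(frames = frames, meta = meta, background = bg)
}
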