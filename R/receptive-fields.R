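#' Difference-of-Gaussians (center-surround) receptive field
#'
#' Builds the classic circular-symmetric center-surround profile
#' \deqn{f(r) = e^{-r^2 / 2\sigma_c^2} - k\, e^{-r^2 / 2\sigma_s^2}}
#' where `cs_ratio` is the ratio of the *volume* under the surround Gaussian
#' to the volume under the center Gaussian, so the surround peak multiplier
#' is `k = cs_ratio * sigma_center^2 / sigma_surround^2`. An off-center RF is
#' the exact negation of the on-center RF.
#'
#' @param grid a [pixel_grid()].
#' @param sigma_center center Gaussian SD, degrees (> 0).
#' @param sigma_surround surround Gaussian SD, degrees; must exceed
#'   `sigma_center` whenever `cs_ratio > 0`.
#' @param cs_ratio surround-to-center volume ratio in \[0, 1\].
#' @param center RF center `c(x0, y0)`, degrees.
#' @param polarity `"on"` (bright-center) or `"off"`.
#' @return RF image (matrix `[ix, iy]`).
#' @examples
#' g <- pixel_grid(60, 121)
#' rf <- dog_rf(g, 0.8, 4.7, 0.4)
#' @export
dog_rf <- function(grid, sigma_center, sigma_surround = NULL, cs_ratio = 0,
                   center = c(0, 0), polarity = c("on", "off")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(grid, "pixel_grid"), sigma_center > 0,
            cs_ratio >= 0, cs_ratio <= 1, length(center) == 2)
  if (cs_ratio > 0) {
    if (is.null(sigma_surround) || sigma_surround <= sigma_center)
      stop("sigma_surround must exceed sigma_center when cs_ratio > 0")
  }
  m <- grid_mesh(grid)
  r2 <- (m$x - center[1])^2 + (m$y - center[2])^2
  rf <- exp(-r2 / (2 * sigma_center^2))
  if (cs_ratio > 0) {
    k <- cs_ratio * sigma_center^2 / sigma_surround^2
    rf <- rf - k * exp(-r2 / (2 * sigma_surround^2))
  }
  if (polarity == "off") rf <- -rf
  rf
}

#' Closed-form preferred spatial frequency of a DoG receptive field
#'
#' The Fourier transform of the DoG is proportional to
#' `sigma_c^2 exp(-2 pi^2 sigma_c^2 f^2) - cs_ratio sigma_c^2 exp(-2 pi^2 sigma_s^2 f^2)`;
#' differentiating gives the peak at
#' `f = sqrt(log(cs_ratio sigma_s^2 / sigma_c^2) / (2 pi^2 (sigma_s^2 - sigma_c^2)))`
#' when that logarithm is positive, else the profile is lowpass (peak at 0).
#'
#' @inheritParams dog_rf
#' @return preferred spatial frequency, cycles/degree.
#' @export
dog_peak_sf <- function(sigma_center, sigma_surround = NULL, cs_ratio = 0) {
  if (cs_ratio <= 0) return(0)
  stopifnot(sigma_surround > sigma_center)
  a <- cs_ratio * sigma_surround^2 / sigma_center^2
  if (a <= 1) return(0)
  sqrt(log(a) / (2 * pi^2 * (sigma_surround^2 - sigma_center^2)))
}

#' Gabor envelope standard deviations
#'
#' The minor-axis SD is set by the number of excitatory/inhibitory
#' subregions and the preferred spatial frequency,
#' `sigma_min = n_subregions / (4 sqrt(2) f_pref)`, and the major axis by the
#' length-to-width ratio, `sigma_maj = (lw_ratio / n_subregions) sigma_min`.
#'
#' @param f_pref preferred spatial frequency, cycles/degree (> 0).
#' @param n_subregions number of subregions (default 2).
#' @param lw_ratio length-to-width ratio of the envelope (default 4).
#' @return named vector `c(sigma_min, sigma_maj)` in degrees.
#' @examples
#' gabor_sigmas(0.08) # approx c(4.419, 8.839)
#' @export
gabor_sigmas <- function(f_pref, n_subregions = 2, lw_ratio = 4) {
  stopifnot(f_pref > 0, n_subregions > 0, lw_ratio > 0)
  sigma_min <- n_subregions / (4 * sqrt(2) * f_pref)
  c(sigma_min = sigma_min, sigma_maj = lw_ratio / n_subregions * sigma_min)
}

#' V1-like (Gabor) receptive field
#'
#' An elongated Gaussian envelope (rescaled to a maximum of 1, major axis
#' parallel to the carrier stripes) multiplied pointwise by a sinusoidal
#' carrier at the preferred frequency. Orientation uses the same convention
#' as [render_grating()].
#'
#' @param grid a [pixel_grid()].
#' @param orientation RF orientation theta_c, degrees.
#' @param f_pref carrier/preferred spatial frequency, cycles/degree.
#' @param phase carrier phase, radians.
#' @param center RF center `c(x0, y0)`, degrees.
#' @param n_subregions,lw_ratio see [gabor_sigmas()].
#' @return RF image (matrix).
#' @export
gabor_rf <- function(grid, orientation, f_pref, phase = 0, center = c(0, 0),
                     n_subregions = 2, lw_ratio = 4) {
  stopifnot(inherits(grid, "pixel_grid"), length(center) == 2)
  assert_below_nyquist(grid, f_pref)
  s <- gabor_sigmas(f_pref, n_subregions, lw_ratio)
  tg <- grating_angle(orientation)
  m <- grid_mesh(grid)
  dx <- m$x - center[1]; dy <- m$y - center[2]
  # u: along the stripes (major axis), v: along the wave vector (minor axis)
  u <- -sin(tg) * dx + cos(tg) * dy
  v <-  cos(tg) * dx + sin(tg) * dy
  env <- exp(-(u^2 / (2 * s["sigma_maj"]^2) + v^2 / (2 * s["sigma_min"]^2)))
  env <- env / max(env)
  carrier <- cos(2 * pi * f_pref * (cos(tg) * dx + sin(tg) * dy) + phase)
  env * carrier
}

#' Quadrature pair of Gabor receptive fields
#'
#' The two members differ only by a 90-degree carrier phase; squaring and
#' summing their responses gives a stimulus-phase-invariant energy response.
#'
#' @inheritParams gabor_rf
#' @return list with elements `phase0` and `phase90`.
#' @export
gabor_quadrature <- function(grid, orientation, f_pref, center = c(0, 0),
                             n_subregions = 2, lw_ratio = 4) {
  list(phase0 = gabor_rf(grid, orientation, f_pref, 0, center,
                         n_subregions, lw_ratio),
       phase90 = gabor_rf(grid, orientation, f_pref, pi / 2, center,
                          n_subregions, lw_ratio))
}

#' Preferred spatial frequency from the Fourier spectrum of an RF
#'
#' Slices the centered 2-D discrete Fourier magnitude of the RF image along
#' an axis through the origin and returns the non-negative frequency at the
#' peak magnitude. For circularly symmetric RFs the slice axis is
#' immaterial (asserted by tests); the vertical frequency axis is the
#' default.
#'
#' @param rf RF image rendered on `grid`, centered in the field of view.
#' @param grid the [pixel_grid()].
#' @param axis `"vertical"`, `"horizontal"` or `"diagonal"` slice.
#' @return peak spatial frequency, cycles/degree (0 for lowpass profiles).
#' @export
peak_spatial_frequency <- function(rf, grid,
                                   axis = c("vertical", "horizontal", "diagonal")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(rf), all(dim(rf) == grid$n_pixels))
  if (max(rf) - min(rf) <= 0)
    stop("constant image has no defined spectral peak")
  n <- grid$n_pixels
  f <- stats::fft(rf)
  freqs <- c(0:(n - 1))
  freqs[freqs >= n / 2] <- freqs[freqs >= n / 2] - n
  freqs <- freqs / (n * grid$spacing)
  if (axis == "vertical") {
    mag <- Mod(f[1, ]); fr <- freqs
  } else if (axis == "horizontal") {
    mag <- Mod(f[, 1]); fr <- freqs
  } else {
    mag <- Mod(f[cbind(1:n, 1:n)]); fr <- freqs * sqrt(2)
  }
  keep <- fr >= 0
  fr[keep][which.max(mag[keep])]
}

# width of one frequency bin on a grid, cycles/degree
frequency_bin <- function(grid) 1 / (grid$n_pixels * grid$spacing)
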