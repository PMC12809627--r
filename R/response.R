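#' Scalar response of a receptive field to a stimulus
#'
#' The dot product between the vectorized RF and stimulus images.
#'
#' @param rf RF image.
#' @param stim stimulus image on the same grid.
#' @return scalar response.
#' @export
unit_response <- function(rf, stim) {
  if (!identical(dim(rf), dim(stim)))
    stop("rf and stimulus must share the same grid dimensions")
  sum(rf * stim)
}

#' Combine On-center and Off-center responses
#'
#' Each member of an opposite-polarity pair is thresholded at zero and the
#' two are summed, yielding a response invariant to the luminance polarity
#' of the stimulus. For an exact opposite-polarity pair (`r_off = -r_on`)
#' this equals `abs(r_on)`.
#'
#' @param r_on,r_off responses of the on- and off-center RFs to the same
#'   stimulus (vectorized).
#' @return combined non-negative response.
#' @export
combine_onoff <- function(r_on, r_off) {
  pmax(r_on, 0) + pmax(r_off, 0)
}

#' Quadrature energy response
#'
#' Squared and summed responses of a quadrature Gabor pair; the canonical
#' stimulus-phase-invariant "complex cell" energy.
#'
#' @param r_0,r_90 responses of the phase-0 and phase-90 RFs (vectorized).
#' @return energy response.
#' @export
quadrature_energy <- function(r_0, r_90) {
  r_0^2 + r_90^2
}

#' Multi-axis response container
#'
#' A thin wrapper around a numeric array that records the axis names, the
#' processing stage, the response kind and (when present) the stimulus
#' phases of the phase axis. Stages advance only in the order
#' `raw -> combined -> phase_averaged -> normalized -> modelled`.
#'
#' @param values numeric array.
#' @param axes character vector naming each dimension of `values` (e.g.
#'   `c("orientation", "phase", "location")`).
#' @param stage processing stage tag.
#' @param kind `"onoff"` for rectified center-surround pair responses,
#'   `"energy"` for Gabor quadrature energies, `"linear"` otherwise.
#' @param phases stimulus phases (degrees) indexing the `"phase"` axis.
#' @return an object of class `response_tensor`.
#' @export
response_tensor <- function(values, axes,
                            stage = c("raw", "combined", "phase_averaged",
                                      "normalized", "modelled"),
                            kind = c("linear", "onoff", "energy"),
                            phases = NULL) {
  stage <- match.arg(stage)
  kind <- match.arg(kind)
  if (is.null(dim(values))) values <- array(values, dim = length(values))
  stopifnot(length(axes) == length(dim(values)))
  if ("phase" %in% axes && !is.null(phases))
    stopifnot(length(phases) == dim(values)[match("phase", axes)])
  structure(values, axes = axes, stage = stage, kind = kind, phases = phases,
            class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  cat(sprintf("response_tensor [%s] stage=%s kind=%s dims=%s\n",
              paste(attr(x, "axes"), collapse = " x "),
              attr(x, "stage"), attr(x, "kind"),
              paste(dim(x), collapse = " x ")))
  invisible(x)
}

#' @export
#' @rdname response_tensor
#' @param x a `response_tensor`.
tensor_stage <- function(x) attr(x, "stage")

.assert_stage <- function(x, expected) {
  if (!inherits(x, "response_tensor"))
    stop("expected a response_tensor")
  if (!identical(attr(x, "stage"), expected))
    stop(sprintf("tensor is at stage '%s'; expected '%s'",
                 attr(x, "stage"), expected))
}

# drop one named axis from a tensor by applying a collapse over it
.collapse_axis <- function(x, axis, fun) {
  axes <- attr(x, "axes")
  k <- match(axis, axes)
  if (is.na(k)) stop(sprintf("tensor has no '%s' axis", axis))
  keep <- setdiff(seq_along(axes), k)
  if (length(keep) == 0) {
    out <- array(fun(as.vector(x)), dim = 1)
    return(list(values = out, axes = "scalar"))
  }
  out <- apply(unclass(x), keep, fun)
  if (is.null(dim(out))) out <- array(out, dim = dim(x)[keep])
  list(values = out, axes = axes[keep])
}

#' Average responses across stimulus phases
#'
#' Collapses the `"phase"` axis of a combined-stage tensor.
#'
#' Two methods are available. `"arithmetic"` is the plain mean over the
#' sampled phases. `"invariant"` (the default for rectified On/Off pair
#' responses) computes the exact mean of the rectified response over the
#' whole continuous phase circle: because the underlying pair response at
#' phase `phi` is `|A cos(phi - psi)|`, a balanced phase battery (one whose
#' doubled-angle phasors cancel, e.g. 0/90 or 0/90/180/270 degrees) allows
#' exact reconstruction of the envelope `A = sqrt((2/P) sum r_k^2)` (with
#' factor 1 for the 0/90 pair) and the exact phase average `2 A / pi`. This
#' removes the orientation-dependent quadrature error that a small sampled
#' phase set would otherwise leave in the rectified responses. Energy
#' responses are already phase invariant, so both methods reduce to the
#' arithmetic mean (the default).
#'
#' @param x a `response_tensor` at stage `"combined"` with a `"phase"` axis.
#' @param method `"auto"` (invariant for kind `"onoff"`, arithmetic
#'   otherwise), `"invariant"` or `"arithmetic"`.
#' @return tensor at stage `"phase_averaged"` without the phase axis.
#' @export
average_over_stimulus_phases <- function(x, method = c("auto", "invariant",
                                                       "arithmetic")) {
  method <- match.arg(method)
  .assert_stage(x, "combined")
  kind <- attr(x, "kind")
  if (method == "auto")
    method <- if (identical(kind, "onoff")) "invariant" else "arithmetic"
  if (method == "invariant" && identical(kind, "energy"))
    method <- "arithmetic"
  if (method == "invariant") {
    phases <- attr(x, "phases")
    if (is.null(phases))
      stop("invariant phase averaging requires the tensor's 'phases' attribute")
    ph <- phases * pi / 180
    if (Mod(sum(exp(2i * ph))) > 1e-8 * length(ph))
      stop("invariant phase averaging needs a balanced phase set ",
           "(sum of doubled-angle phasors must vanish), e.g. 0/90 or 0/90/180/270")
    p <- length(ph)
    fac <- if (p == 2) 1 else 2 / p
    col <- .collapse_axis(x, "phase", function(v) sqrt(fac * sum(v^2)) * 2 / pi)
  } else {
    col <- .collapse_axis(x, "phase", mean)
  }
  response_tensor(col$values, col$axes, stage = "phase_averaged", kind = kind)
}

#' Min-max normalize responses across all locations and conditions
#'
#' Rescales the whole tensor to \[0, 1\] using its global minimum and
#' maximum (the scope of one stimulus manipulation). A near-constant tensor
#' (relative range below 1e-9) is mapped to all zeros with a warning, which
#' also prevents numerically flat conditions from having discretization
#' noise amplified to full scale.
#'
#' @param x a `response_tensor` at stage `"phase_averaged"`.
#' @return tensor at stage `"normalized"` with values in \[0, 1\].
#' @export
normalize_responses <- function(x) {
  .assert_stage(x, "phase_averaged")
  v <- as.vector(x)
  rng <- range(v)
  scale_ref <- max(abs(rng), 1e-300)
  if (diff(rng) <= 1e-9 * scale_ref) {
    warning("responses are (near-)constant; normalized tensor set to zeros")
    out <- array(0, dim = dim(x))
  } else {
    out <- (unclass(x) - rng[1]) / diff(rng)
  }
  response_tensor(out, attr(x, "axes"), stage = "normalized",
                  kind = attr(x, "kind"))
}

#' Apply the total response model
#'
#' `R_t = alpha * R_delta + beta + omega`, with `R_delta` the normalized
#' stimulus-driven response and `omega` i.i.d. Gaussian noise of standard
#' deviation `noise_sd` (added only when `noise = TRUE`; seeded). With
#' `alpha = beta = 1` the maximum possible pre-noise increase over the
#' baseline is 100%.
#'
#' @param x a `response_tensor` at stage `"normalized"`.
#' @param alpha gain on the stimulus-driven response (> 0, default 1).
#' @param beta baseline response (> 0, default 1).
#' @param noise logical; add Gaussian noise?
#' @param noise_sd noise standard deviation (default 0.01).
#' @param seed integer seed used when `noise = TRUE`.
#' @return tensor at stage `"modelled"`.
#' @export
apply_response_model <- function(x, alpha = 1, beta = 1, noise = FALSE,
                                 noise_sd = 0.01, seed = NULL) {
  .assert_stage(x, "normalized")
  stopifnot(alpha > 0, beta > 0, noise_sd >= 0)
  out <- alpha * unclass(x) + beta
  if (noise && noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    out <- out + stats::rnorm(length(out), 0, noise_sd)
    dim(out) <- dim(x)
  }
  response_tensor(out, attr(x, "axes"), stage = "modelled",
                  kind = attr(x, "kind"))
}

#' Response field of a translated RF kernel by FFT cross-correlation
#'
#' Because all RFs of one type are translated copies of a common kernel,
#' the responses of RFs centered at every pixel of the grid equal the
#' (zero-padded, linear) spatial cross-correlation of the stimulus with the
#' kernel, sampled at pixel shifts. The kernel must be rendered centered on
#' the pixel closest to the origin; the returned matrix `resp[ix, iy]` is
#' the response of the RF centered at `(coords[ix], coords[iy])`. Exactly
#' equals per-unit dot products for on-lattice RF centers.
#'
#' @param stim stimulus image.
#' @param kernel RF image centered at the grid origin pixel.
#' @param grid the [pixel_grid()].
#' @return matrix of responses, same size as the grid.
#' @export
response_field <- function(stim, kernel, grid) {
  stopifnot(identical(dim(stim), dim(kernel)),
            all(dim(stim) == grid$n_pixels))
  n <- grid$n_pixels
  np <- stats::nextn(2 * n, 2)
  ps <- matrix(0, np, np); ps[1:n, 1:n] <- stim
  pk <- matrix(0, np, np); pk[1:n, 1:n] <- kernel
  cc <- Re(stats::fft(stats::fft(ps) * Conj(stats::fft(pk)), inverse = TRUE)) / (np * np)
  i0 <- grid_origin_index(grid)
  idx <- ((1:n) - i0) %% np + 1
  cc[idx, idx]
}

#' Phase-collapsed On/Off response fields for a DoG receptive field
#'
#' Computes, for every stimulus in a battery sharing one aperture/frequency
#' condition, the combined On/Off pair response of DoG units centered at
#' every pixel, then collapses stimulus phases with the invariant average.
#' For an exact opposite-polarity pair the combined response is the absolute
#' linear response, so only the on-center correlation is required per
#' stimulus.
#'
#' @param grid a [pixel_grid()].
#' @param sigma_center,sigma_surround,cs_ratio DoG parameters.
#' @param orientations stimulus orientations, degrees.
#' @param sf stimulus spatial frequency, cycles/degree.
#' @param ap an [aperture()] or list of apertures applied in sequence.
#' @param phases stimulus phases, degrees (balanced set).
#' @return `response_tensor` `[x, y, orientation]` at stage
#'   `"phase_averaged"`, kind `"onoff"`.
#' @export
dog_response_fields <- function(grid, sigma_center, sigma_surround, cs_ratio,
                                orientations = seq(0, 165, by = 15),
                                sf = 0.04, ap = aperture("none"),
                                phases = c(0, 90, 180, 270)) {
  if (inherits(ap, "aperture")) ap <- list(ap)
  i0 <- grid_origin_index(grid)
  c0 <- grid$coords[i0]
  kern <- dog_rf(grid, sigma_center, sigma_surround, cs_ratio,
                 center = c(c0, c0))
  n <- grid$n_pixels
  vals <- array(0, dim = c(n, n, length(orientations), length(phases)))
  for (i in seq_along(orientations)) {
    for (j in seq_along(phases)) {
      s <- render_grating(grid, orientations[i], sf, phases[j] * pi / 180)
      for (a in ap) s <- apply_aperture(s, a, grid)
      vals[, , i, j] <- abs(response_field(s, kern, grid))
    }
  }
  tens <- response_tensor(vals, c("x", "y", "orientation", "phase"),
                          stage = "combined", kind = "onoff", phases = phases)
  average_over_stimulus_phases(tens)
}

#' Phase-collapsed energy response fields for Gabor receptive fields
#'
#' For each RF orientation, computes the quadrature-pair energy response of
#' units centered at every pixel, for every stimulus orientation, then
#' averages across stimulus phases. Phases 180/270 duplicate 0/90 for energy
#' responses (linearity), so only the unique half of a balanced set is
#' evaluated.
#'
#' @inheritParams dog_response_fields
#' @param rf_orientations RF orientations, degrees (default 8 in
#'   22.5-degree steps).
#' @param f_pref preferred spatial frequency of the RFs, cycles/degree.
#' @param n_subregions,lw_ratio see [gabor_sigmas()].
#' @return `response_tensor` `[x, y, orientation, rf_orientation]` at stage
#'   `"phase_averaged"`, kind `"energy"`.
#' @export
gabor_response_fields <- function(grid, f_pref = 0.08,
                                  rf_orientations = seq(0, 157.5, by = 22.5),
                                  orientations = seq(0, 165, by = 15),
                                  sf = 0.04, ap = aperture("none"),
                                  phases = c(0, 90, 180, 270),
                                  n_subregions = 2, lw_ratio = 4) {
  if (inherits(ap, "aperture")) ap <- list(ap)
  uphase <- unique(phases %% 180)
  i0 <- grid_origin_index(grid)
  c0 <- grid$coords[i0]
  n <- grid$n_pixels
  kerns <- lapply(rf_orientations, function(o)
    gabor_quadrature(grid, o, f_pref, center = c(c0, c0),
                     n_subregions = n_subregions, lw_ratio = lw_ratio))
  vals <- array(0, dim = c(n, n, length(orientations), length(uphase),
                           length(rf_orientations)))
  for (i in seq_along(orientations)) {
    for (j in seq_along(uphase)) {
      s <- render_grating(grid, orientations[i], sf, uphase[j] * pi / 180)
      for (a in ap) s <- apply_aperture(s, a, grid)
      for (k in seq_along(rf_orientations)) {
        f0 <- response_field(s, kerns[[k]]$phase0, grid)
        f9 <- response_field(s, kerns[[k]]$phase90, grid)
        vals[, , i, j, k] <- quadrature_energy(f0, f9)
      }
    }
  }
  tens <- response_tensor(vals, c("x", "y", "orientation", "phase",
                                  "rf_orientation"),
                          stage = "combined", kind = "energy", phases = uphase)
  average_over_stimulus_phases(tens)
}

#' Orientation tuning of DoG units at arbitrary centers
#'
#' Direct dot-product route (no lattice restriction): combined On/Off pair
#' responses for each unit and stimulus, phases collapsed with the invariant
#' average.
#'
#' @inheritParams dog_response_fields
#' @param centers numeric matrix (m x 2) of unit centers, degrees.
#' @param sfs one or more stimulus spatial frequencies.
#' @return `response_tensor` `[orientation, sf, unit]` at stage
#'   `"phase_averaged"`, kind `"onoff"`.
#' @export
dog_unit_tuning <- function(grid, sigma_center, sigma_surround, cs_ratio,
                            centers, orientations = seq(0, 165, by = 15),
                            sfs = 0.04, ap = aperture("none"),
                            phases = c(0, 90, 180, 270)) {
  centers <- matrix(centers, ncol = 2)
  if (inherits(ap, "aperture")) ap <- list(ap)
  rfs <- t(vapply(seq_len(nrow(centers)), function(i)
    as.vector(dog_rf(grid, sigma_center, sigma_surround, cs_ratio,
                     center = centers[i, ])),
    numeric(grid$n_pixels^2)))
  vals <- array(0, dim = c(length(orientations), length(sfs), length(phases),
                           nrow(centers)))
  for (i in seq_along(orientations)) {
    for (q in seq_along(sfs)) {
      for (j in seq_along(phases)) {
        s <- render_grating(grid, orientations[i], sfs[q], phases[j] * pi / 180)
        for (a in ap) s <- apply_aperture(s, a, grid)
        vals[i, q, j, ] <- abs(rfs %*% as.vector(s))
      }
    }
  }
  tens <- response_tensor(vals, c("orientation", "sf", "phase", "unit"),
                          stage = "combined", kind = "onoff", phases = phases)
  average_over_stimulus_phases(tens)
}

#' Orientation tuning of Gabor units at arbitrary centers
#'
#' Quadrature energy responses by direct dot products, phases averaged.
#'
#' @inheritParams gabor_response_fields
#' @param centers numeric matrix (m x 2) of unit centers, degrees.
#' @param unit_orientations RF orientation of each unit, degrees (length m).
#' @return `response_tensor` `[orientation, unit]` at stage
#'   `"phase_averaged"`, kind `"energy"`.
#' @export
gabor_unit_tuning <- function(grid, f_pref, centers, unit_orientations,
                              orientations = seq(0, 165, by = 15),
                              sf = 0.04, ap = aperture("none"),
                              phases = c(0, 90, 180, 270),
                              n_subregions = 2, lw_ratio = 4) {
  centers <- matrix(centers, ncol = 2)
  stopifnot(length(unit_orientations) == nrow(centers))
  if (inherits(ap, "aperture")) ap <- list(ap)
  uphase <- unique(phases %% 180)
  m <- nrow(centers)
  rf0 <- matrix(0, m, grid$n_pixels^2)
  rf9 <- matrix(0, m, grid$n_pixels^2)
  for (i in seq_len(m)) {
    q <- gabor_quadrature(grid, unit_orientations[i], f_pref,
                          center = centers[i, ],
                          n_subregions = n_subregions, lw_ratio = lw_ratio)
    rf0[i, ] <- as.vector(q$phase0)
    rf9[i, ] <- as.vector(q$phase90)
  }
  vals <- array(0, dim = c(length(orientations), length(uphase), m))
  for (i in seq_along(orientations)) {
    for (j in seq_along(uphase)) {
      s <- render_grating(grid, orientations[i], sf, uphase[j] * pi / 180)
      for (a in ap) s <- apply_aperture(s, a, grid)
      sv <- as.vector(s)
      vals[i, j, ] <- quadrature_energy(as.vector(rf0 %*% sv),
                                        as.vector(rf9 %*% sv))
    }
  }
  tens <- response_tensor(vals, c("orientation", "phase", "unit"),
                          stage = "combined", kind = "energy", phases = uphase)
  average_over_stimulus_phases(tens)
}

#' Bar-response statistics for one or more receptive fields
#'
#' Baseline (mean response over blank, no-bar frames) is subtracted from
#' every frame response; responses are then normalized per RF to a maximum
#' of 1 across all bar presentations, and mean horizontal- and vertical-bar
#' responses are reported.
#'
#' @param responses matrix of combined frame responses (frames x RFs), or a
#'   vector for a single RF.
#' @param meta data.frame describing the frames, with columns `orientation`
#'   (`"horizontal"`, `"vertical"` or `"blank"`) and `is_blank`.
#' @return data.frame with one row per RF: `mean_h`, `mean_v`, `os_bar`,
#'   `preference`.
#' @export
bar_response_statistics <- function(responses, meta) {
  if (is.null(dim(responses))) responses <- matrix(responses, ncol = 1)
  stopifnot(nrow(responses) == nrow(meta))
  if (!any(meta$is_blank))
    stop("no blank frames available for baseline estimation")
  baseline <- colMeans(responses[meta$is_blank, , drop = FALSE])
  r <- sweep(responses, 2, baseline)
  # every position frame is a presentation, including positions where the
  # bar is hidden behind a mask edge (their response equals the baseline)
  bar <- meta$orientation %in% c("horizontal", "vertical")
  mx <- apply(abs(r[bar, , drop = FALSE]), 2, max)
  mx[mx == 0] <- 1
  r <- sweep(r, 2, mx, "/")
  mh <- colMeans(r[meta$orientation == "horizontal", , drop = FALSE])
  mv <- colMeans(r[meta$orientation == "vertical", , drop = FALSE])
  cbind(data.frame(mean_h = mh, mean_v = mv), os_bar(mh, mv))
}
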