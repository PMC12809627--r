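#' Orientation-preference map
#'
#' Per-location preferred orientation (degrees, mod 180) together with a
#' selectivity value in \[0, 1\] used as display alpha.
#'
#' @param preferred matrix (or vector) of preferred orientations, degrees.
#' @param selectivity matching gOSI (or OS_bar) values.
#' @param alpha display-normalized selectivity (defaults to min-max of
#'   `selectivity`).
#' @param coords list describing the grid (e.g. `list(x = ..., y = ...)`),
#'   or NULL.
#' @param space `"visual"` or `"anatomical"`.
#' @param condition free-form condition label.
#' @return object of class `orientation_map`.
#' @export
orientation_map <- function(preferred, selectivity, alpha = NULL,
                            coords = NULL, space = c("visual", "anatomical"),
                            condition = "") {
  space <- match.arg(space)
  stopifnot(identical(dim(preferred), dim(selectivity)) ||
              length(preferred) == length(selectivity))
  if (is.null(alpha)) {
    alpha <- suppressWarnings(normalize_gosi_for_display(selectivity))
    if (is.matrix(selectivity)) dim(alpha) <- dim(selectivity)
  }
  structure(list(preferred = preferred, selectivity = selectivity,
                 alpha = alpha, coords = coords, space = space,
                 condition = condition),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  n <- length(x$preferred)
  ok <- !is.na(x$preferred)
  cat(sprintf("orientation_map (%s%s): %d locations (%d valid)\n",
              x$space,
              if (nzchar(x$condition)) paste0(", ", x$condition) else "",
              n, sum(ok)))
  if (any(ok)) {
    rs <- orientation_resultant(x$preferred[ok])
    cat(sprintf("  circular mean preference %.1f deg (resultant %.2f); median selectivity %.3g\n",
                rs$mean, rs$length, stats::median(x$selectivity[ok])))
  }
  invisible(x)
}

#' Build an orientation map from phase-averaged response fields
#'
#' Runs the response-model tail of the pipeline (normalization within the
#' given tensor, baseline/gain, optional noise) and derives per-location
#' preferred orientation and gOSI.
#'
#' @param fields `response_tensor` `[x, y, orientation]` (stage
#'   `"phase_averaged"`) or a plain array of that shape.
#' @param orientations stimulus orientations, degrees.
#' @param grid the [pixel_grid()] (used for coordinates).
#' @param alpha,beta,noise,noise_sd,seed see [apply_response_model()].
#' @param condition label.
#' @return an [orientation_map()] in visual coordinates, with the modelled
#'   response array attached as attribute `"responses"`.
#' @export
map_from_fields <- function(fields, orientations, grid,
                            alpha = 1, beta = 1, noise = FALSE,
                            noise_sd = 0.01, seed = NULL, condition = "") {
  if (!inherits(fields, "response_tensor"))
    fields <- response_tensor(fields, c("x", "y", "orientation"),
                              stage = "phase_averaged")
  modelled <- apply_response_model(normalize_responses(fields),
                                   alpha = alpha, beta = beta, noise = noise,
                                   noise_sd = noise_sd, seed = seed)
  dims <- dim(modelled)
  rmat <- matrix(unclass(modelled), dims[1] * dims[2], dims[3])
  pref <- matrix(preferred_orientation(rmat, orientations), dims[1], dims[2])
  g <- matrix(gosi(rmat, orientations), dims[1], dims[2])
  m <- orientation_map(pref, g,
                       coords = list(x = grid$coords, y = grid$coords),
                       space = "visual", condition = condition)
  attr(m, "responses") <- unclass(modelled)
  m
}
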