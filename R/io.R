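#' Default run configuration
#'
#' @return nested list of defaults for [load_config()].
#' @export
default_config <- function() {
  list(
    experiment = "spatial_frequency",
    seed = 1L,
    noise = FALSE,
    scale = "full",
    out_dir = ".",
    params = list())
}

.known_experiments <- c("aperture_shape", "spatial_frequency",
                        "rf_grid_search", "bar", "single_unit_population",
                        "preference_switching")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, fills defaults and rejects unknown
#' keys (naming the offending key path). `params` is passed through to the
#' selected experiment driver as extra arguments and is validated against
#' that driver's formals.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("config must be a .yaml/.yml or .json file")
  if (!is.list(raw)) stop("config must be a mapping/object")
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  if (!cfg$experiment %in% .known_experiments)
    stop("experiment must be one of: ",
         paste(.known_experiments, collapse = ", "))
  if (!cfg$scale %in% c("full", "test"))
    stop("scale must be 'full' or 'test'")
  cfg$seed <- as.integer(cfg$seed)
  driver <- .experiment_driver(cfg$experiment)
  bad <- setdiff(names(cfg$params), names(formals(driver)))
  if (length(bad))
    stop("unknown config key(s): ", paste0("params.", bad, collapse = ", "))
  cfg
}

#' Write a configuration to file
#'
#' @param cfg configuration list.
#' @param path output path (`.yaml` or `.json`).
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}

.experiment_driver <- function(id) {
  switch(id,
         aperture_shape = run_aperture_experiment,
         spatial_frequency = run_sf_experiment,
         rf_grid_search = run_rf_grid_search,
         bar = run_bar_experiment,
         single_unit_population = run_single_unit_population_comparison,
         preference_switching = run_preference_switching,
         stop("unknown experiment id: ", id))
}

#' Run an experiment from a configuration
#'
#' Dispatches to the experiment driver, then writes the echoed
#' configuration (with package version and seed), CSV summaries and PNG
#' map renderings into the output directory.
#'
#' @param cfg configuration list from [load_config()] (or compatible).
#' @param write write outputs to `cfg$out_dir` (default TRUE).
#' @return the experiment result, invisibly when writing.
#' @export
run_from_config <- function(cfg, write = TRUE) {
  driver <- .experiment_driver(cfg$experiment)
  args <- cfg$params
  fm <- names(formals(driver))
  if ("scale" %in% fm && is.null(args$scale)) args$scale <- cfg$scale
  if ("seed" %in% fm && is.null(args$seed)) args$seed <- cfg$seed
  if ("noise" %in% fm && is.null(args$noise) &&
      cfg$experiment != "preference_switching") args$noise <- cfg$noise
  res <- do.call(driver, args)
  if (!write) return(res)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- cfg
  echo$package_version <- as.character(utils::packageVersion("rfpopmap"))
  write_config(echo, file.path(cfg$out_dir, "config_echo.json"))
  .write_experiment_outputs(res, cfg$out_dir)
  invisible(res)
}

.write_experiment_outputs <- function(res, dir) {
  for (nm in c("probes", "classification", "transition", "summary",
               "single", "area")) {
    x <- res[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(res$maps)) {
    for (cond in names(res$maps)) {
      entry <- res$maps[[cond]]
      if (inherits(entry, "orientation_map")) entry <- list(map = entry)
      for (kind in names(entry)) {
        m <- entry[[kind]]
        if (inherits(m, "orientation_map")) {
          render_orientation_map(m, file.path(dir, paste0(cond, "_", kind, ".png")))
          export_orientation_map(m, file.path(dir, paste0(cond, "_", kind, ".csv")))
        }
      }
    }
  }
  invisible(dir)
}

#' Export an orientation map as CSV
#'
#' Long format: one row per location with `x`, `y`, `preferred_deg`,
#' `selectivity`, `alpha`.
#'
#' @param map an [orientation_map()].
#' @param path output CSV path.
#' @export
export_orientation_map <- function(map, path) {
  stopifnot(inherits(map, "orientation_map"))
  pref <- map$preferred
  if (is.null(dim(pref))) pref <- matrix(pref, ncol = 1)
  xs <- map$coords$x; ys <- map$coords$y
  d <- data.frame(x = rep(xs, times = length(ys)),
                  y = rep(ys, each = length(xs)),
                  preferred_deg = as.vector(map$preferred),
                  selectivity = as.vector(map$selectivity),
                  alpha = as.vector(map$alpha))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Render an orientation map as a PNG
#'
#' Hue encodes the preferred orientation on a 180-degree-periodic color
#' wheel anchored so that 0 degrees is red and 90 degrees is cyan; alpha
#' encodes selectivity (display-normalized gOSI or OS_bar); missing cells
#' are fully transparent. Rows of the PNG run top-to-bottom, so the image
#' is flipped to put +y at the top.
#'
#' @param map an [orientation_map()].
#' @param path output PNG path.
#' @param alpha_threshold cells with alpha below this value are rendered
#'   fully transparent (default 0: alpha conveys selectivity).
#' @return the path, invisibly.
#' @export
render_orientation_map <- function(map, path, alpha_threshold = 0) {
  stopifnot(inherits(map, "orientation_map"))
  pref <- map$preferred
  a <- map$alpha
  if (is.null(dim(pref))) {
    side <- sqrt(length(pref))
    if (side != round(side)) stop("map is not renderable as an image")
    pref <- matrix(pref, side); a <- matrix(a, side)
  }
  hue <- (pref %% 180) / 180
  a2 <- a
  a2[is.na(a2) | is.na(hue)] <- 0
  a2[a2 < alpha_threshold] <- 0
  hue[is.na(hue)] <- 0
  col <- grDevices::hsv(hue, s = 1, v = 1)
  rgbv <- grDevices::col2rgb(col) / 255
  n1 <- nrow(pref); n2 <- ncol(pref)
  img <- array(0, dim = c(n2, n1, 4))
  # map matrix [ix, iy] (y up) to image rows (top-down)
  reorder <- function(v) t(matrix(v, n1, n2))[n2:1, , drop = FALSE]
  img[, , 1] <- reorder(rgbv[1, ])
  img[, , 2] <- reorder(rgbv[2, ])
  img[, , 3] <- reorder(rgbv[3, ])
  img[, , 4] <- reorder(as.vector(a2))
  png::writePNG(img, path)
  invisible(path)
}
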