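#' @title Simulation experiment drivers
#' @description Orchestrate the five simulation protocols end to end:
#'   aperture shape/size, stimulus spatial frequency, RF grid search, bar
#'   stimuli, single-unit vs population RF structure, and preference
#'   switching. Each driver accepts a `scale` preset: `"full"` runs at the
#'   published problem sizes, `"test"` reduces only the anatomical and
#'   bar-stimulus grids (the 200-pixel stimulus grid is kept in both
#'   presets, since classification of the highest spatial frequency is
#'   unreliable on coarser grids).
#' @name experiments
NULL

scale_preset <- function(scale = c("full", "test")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(anat_n = 241, bar_n = 1200, bar_step = 0.25)
  } else {
    list(anat_n = 41, bar_n = 240, bar_step = 1)
  }
}

# joint min-max normalization + response model across a list of
# phase-averaged field arrays (one stimulus manipulation)
.model_condition_fields <- function(field_list, alpha = 1, beta = 1,
                                    noise = FALSE, noise_sd = 0.01,
                                    seed = NULL) {
  rng <- range(unlist(lapply(field_list, range)))
  span <- diff(rng)
  if (span <= 1e-9 * max(abs(rng), 1e-300)) {
    warning("condition responses are (near-)constant; normalized to zeros")
    norm <- lapply(field_list, function(f) array(0, dim = dim(f)))
  } else {
    norm <- lapply(field_list, function(f) (f - rng[1]) / span)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lapply(norm, function(f) {
    out <- alpha * f + beta
    if (noise && noise_sd > 0) {
      out <- out + stats::rnorm(length(out), 0, noise_sd)
      dim(out) <- dim(f)
    }
    out
  })
}

# orientation map from a modelled [x, y, orientation] array
.map_from_modelled <- function(arr, orientations, grid, space = "visual",
                               condition = "", coords = NULL) {
  dims <- dim(arr)
  rmat <- matrix(arr, dims[1] * dims[2], dims[3])
  pref <- matrix(preferred_orientation(rmat, orientations), dims[1], dims[2])
  g <- matrix(suppressWarnings(gosi(rmat, orientations)), dims[1], dims[2])
  if (is.null(coords)) coords <- list(x = grid$coords, y = grid$coords)
  orientation_map(pref, g, coords = coords, space = space,
                  condition = condition)
}

# smooth each orientation slice of a modelled array (NA-aware)
.smooth_fields <- function(arr, spacing, kernel_sd, truncate = 4) {
  out <- arr
  for (k in seq_len(dim(arr)[3]))
    out[, , k] <- smooth_map(arr[, , k], spacing, kernel_sd = kernel_sd,
                             truncate = truncate)
  out
}

# resample a modelled [x, y, orientation] array to an anatomical grid,
# returning an [ax, ay, orientation] array with NA outside the transform
.to_anatomical <- function(arr, grid, transform, anat) {
  rs <- resample_responses(arr, grid, transform, anat)
  array(rs$values, dim = c(anat$n, anat$n, dim(arr)[3]))
}

.probe_inset <- function(sigma_center, sigma_surround, cs_ratio) {
  if (cs_ratio > 0) sigma_surround else sigma_center
}

# classify probes from an [orientation, sf, unit] phase-averaged tensor
.classify_probes <- function(tens, orientations, sfs, probes) {
  v <- unclass(tens)
  out <- expand.grid(sf = sfs, probe = seq_len(nrow(probes)),
                     KEEP.OUT.ATTRS = FALSE)
  out$normal <- probes$normal[out$probe]
  out$angle <- probes$angle[out$probe]
  out$pref_argmax <- NA_real_
  out$pref_resultant <- NA_real_
  for (i in seq_len(nrow(out))) {
    q <- match(out$sf[i], sfs)
    u <- out$probe[i]
    tc <- v[, q, u]
    out$pref_argmax[i] <- orientations[which.max(tc)] %% 180
    out$pref_resultant[i] <- preferred_orientation(tc, orientations)
  }
  out$class <- classify_radial(out$pref_argmax, out$normal)
  out
}

#' Aperture shape and size experiment
#'
#' Center-surround units (sigma 1.5/11.4 deg, surround volume ratio 0.8,
#' preferred SF 0.04 cpd) respond to 0.04 cpd gratings in circular apertures
#' of radius 20/30/40 degrees and square/diamond apertures of side 40.
#' Produces single-unit and population orientation maps in visual (and
#' optionally anatomical) coordinates, plus boundary-probe preferences.
#'
#' @param scale `"full"` or `"test"` preset.
#' @param grid stimulus [pixel_grid()] (default the 200 px, +-60 deg grid).
#' @param sigma_center,sigma_surround,cs_ratio DoG parameters.
#' @param sf stimulus spatial frequency, cycles/degree.
#' @param include_anatomical also produce anatomical/population maps via the
#'   retinotopic transform (slower).
#' @param anchors an [anchor_set()] for the transform.
#' @param pop_kernel_deg population smoothing SD in visual degrees.
#' @param smoothing a [smoothing_spec()] for anatomical smoothing.
#' @param noise,noise_sd,seed response-model noise controls.
#' @return list with `maps` (per condition: `single`, `population`, and when
#'   requested `single_anat`, `population_anat`), `probes` (boundary-probe
#'   preference table) and `params`.
#' @export
run_aperture_experiment <- function(scale = c("full", "test"),
                                    grid = pixel_grid(60, 200),
                                    sigma_center = 1.5, sigma_surround = 11.4,
                                    cs_ratio = 0.8, sf = 0.04,
                                    include_anatomical = FALSE,
                                    anchors = default_anchors(),
                                    pop_kernel_deg = 0.44,
                                    smoothing = smoothing_spec(),
                                    noise = FALSE, noise_sd = 0.01, seed = 1) {
  preset <- scale_preset(scale)
  orientations <- seq(0, 165, by = 15)
  conds <- list(circle_20 = aperture("circle", radius = 20),
                circle_30 = aperture("circle", radius = 30),
                circle_40 = aperture("circle", radius = 40),
                square_40 = aperture("square", side = 40),
                diamond_40 = aperture("diamond", side = 40))
  fields <- lapply(conds, function(ap)
    unclass(dog_response_fields(grid, sigma_center, sigma_surround, cs_ratio,
                                orientations, sf, ap)))
  modelled <- .model_condition_fields(fields, noise = noise,
                                      noise_sd = noise_sd,
                                      seed = if (noise) seed else NULL)
  tr <- anat <- NULL
  if (include_anatomical) {
    tr <- fit_retinotopy(anchors)
    anat <- anatomical_grid(preset$anat_n)
  }
  maps <- list()
  for (nm in names(conds)) {
    arr <- modelled[[nm]]
    entry <- list(
      single = .map_from_modelled(arr, orientations, grid,
                                  condition = nm),
      population = .map_from_modelled(
        .smooth_fields(arr, grid$spacing, pop_kernel_deg),
        orientations, grid, condition = paste0(nm, " (population)")))
    if (include_anatomical) {
      an <- .to_anatomical(arr, grid, tr, anat)
      entry$single_anat <- .map_from_modelled(
        an, orientations, grid, space = "anatomical", condition = nm,
        coords = list(x = anat$coords, y = anat$coords))
      sm <- .smooth_fields(an, anat$coords[2] - anat$coords[1],
                           smoothing$kernel_sd, smoothing$truncate)
      entry$population_anat <- .map_from_modelled(
        sm, orientations, grid, space = "anatomical",
        condition = paste0(nm, " (population)"),
        coords = list(x = anat$coords, y = anat$coords))
    }
    maps[[nm]] <- entry
  }
  probes <- lapply(names(conds), function(nm) {
    ap <- conds[[nm]]
    if (!ap$shape %in% c("circle", "square", "diamond")) return(NULL)
    # curved rims: probe the radially tuned band one surround-SD inside;
    # straight edges keep radial preferences on the boundary itself
    pr <- edge_probes(ap, inset = if (ap$shape == "circle")
      .probe_inset(sigma_center, sigma_surround, cs_ratio) else 0)
    tens <- dog_unit_tuning(grid, sigma_center, sigma_surround, cs_ratio,
                            cbind(pr$x, pr$y), orientations, sf, ap)
    cl <- .classify_probes(tens, orientations, sf, pr)
    cl$condition <- nm
    cl
  })
  probes <- do.call(rbind, probes)
  list(maps = maps, probes = probes,
       params = list(sigma_center = sigma_center,
                     sigma_surround = sigma_surround, cs_ratio = cs_ratio,
                     sf = sf, orientations = orientations, scale = scale[1]))
}

#' Spatial-frequency experiment
#'
#' The 0.08 cpd-preferring center-surround unit (sigma 0.8/4.7, volume
#' ratio 0.4) viewing 30-degree-radius circular gratings at spatial
#' frequencies 0.01-0.32 cpd. Classifies the preferred orientation at
#' canonical edge probes (inset one surround SD inside the rim, where the
#' radially tuned band lies) as radial or anti-radial per frequency and
#' reports the lowest anti-radial frequency; optionally produces the full
#' orientation maps.
#'
#' @inheritParams run_aperture_experiment
#' @param sfs stimulus spatial frequencies, cycles/degree.
#' @param radius circular aperture radius, degrees.
#' @param include_maps also compute per-frequency orientation maps.
#' @return list with `classification` (probe x sf table), `transition`
#'   (per-probe lowest anti-radial frequency; `$lowest_anti_radial_sf` is
#'   the canonical right-edge probe value), optionally `maps`, and
#'   `params`.
#' @export
run_sf_experiment <- function(scale = c("full", "test"),
                              grid = pixel_grid(60, 200),
                              sigma_center = 0.8, sigma_surround = 4.7,
                              cs_ratio = 0.4,
                              sfs = c(0.01, 0.02, 0.04, 0.08, 0.16, 0.32),
                              radius = 30, include_maps = FALSE,
                              include_anatomical = FALSE,
                              anchors = default_anchors(),
                              pop_kernel_deg = 0.44,
                              smoothing = smoothing_spec(),
                              noise = FALSE, noise_sd = 0.01, seed = 1) {
  preset <- scale_preset(scale)
  orientations <- seq(0, 165, by = 15)
  ap <- aperture("circle", radius = radius)
  inset <- .probe_inset(sigma_center, sigma_surround, cs_ratio)
  pr <- edge_probes(ap, inset = inset)
  tens <- dog_unit_tuning(grid, sigma_center, sigma_surround, cs_ratio,
                          cbind(pr$x, pr$y), orientations, sfs, ap)
  cl <- .classify_probes(tens, orientations, sfs, pr)
  trans <- do.call(rbind, lapply(split(cl, cl$probe), function(d) {
    d <- d[order(d$sf), ]
    anti <- d$sf[d$class == "anti-radial"]
    data.frame(probe = d$probe[1], angle = pr$angle[d$probe[1]],
               lowest_anti_radial_sf = if (length(anti)) min(anti) else NA_real_)
  }))
  out <- list(classification = cl, transition = trans,
              lowest_anti_radial_sf =
                trans$lowest_anti_radial_sf[trans$angle == 0],
              params = list(sigma_center = sigma_center,
                            sigma_surround = sigma_surround,
                            cs_ratio = cs_ratio, sfs = sfs, radius = radius,
                            probe_inset = inset, scale = scale[1]))
  if (include_maps) {
    fields <- lapply(sfs, function(s)
      unclass(dog_response_fields(grid, sigma_center, sigma_surround,
                                  cs_ratio, orientations, s, ap)))
    names(fields) <- paste0("sf_", sfs)
    modelled <- .model_condition_fields(fields, noise = noise,
                                        noise_sd = noise_sd,
                                        seed = if (noise) seed else NULL)
    maps <- list()
    tr <- anat <- NULL
    if (include_anatomical) {
      tr <- fit_retinotopy(anchors)
      anat <- anatomical_grid(preset$anat_n)
    }
    for (nm in names(modelled)) {
      arr <- modelled[[nm]]
      entry <- list(
        single = .map_from_modelled(arr, orientations, grid, condition = nm),
        population = .map_from_modelled(
          .smooth_fields(arr, grid$spacing, pop_kernel_deg),
          orientations, grid, condition = paste0(nm, " (population)")))
      if (include_anatomical) {
        an <- .to_anatomical(arr, grid, tr, anat)
        sm <- .smooth_fields(an, anat$coords[2] - anat$coords[1],
                             smoothing$kernel_sd, smoothing$truncate)
        entry$population_anat <- .map_from_modelled(
          sm, orientations, grid, space = "anatomical",
          condition = paste0(nm, " (population)"),
          coords = list(x = anat$coords, y = anat$coords))
      }
      maps[[nm]] <- entry
    }
    out$maps <- maps
  }
  out
}

#' Default grid-search cells
#'
#' Surround size / volume-ratio pairs constrained to a preferred spatial
#' frequency of 0.08 cpd (center SD 0.8 deg), plus the no-surround control.
#'
#' @return data.frame with `sigma_center`, `sigma_surround`, `cs_ratio`.
#' @export
grid_search_cells <- function() {
  rbind(
    data.frame(sigma_center = 0.8, sigma_surround = NA_real_, cs_ratio = 0),
    data.frame(sigma_center = 0.8,
               sigma_surround = c(3, 4.7, 5.2, 5.5, 5.7),
               cs_ratio = c(0.2, 0.4, 0.6, 0.8, 1)))
}

#' Receptive-field grid search
#'
#' For each center-surround parameter cell, verifies the preferred spatial
#' frequency on the grid (spectral slice vs closed form) and classifies the
#' canonical right-edge probe preference per stimulus frequency.
#'
#' @inheritParams run_sf_experiment
#' @param cells data.frame as from [grid_search_cells()].
#' @param tuning_sfs frequencies for the reported SF tuning curves.
#' @return list with `summary` (per-cell peak SFs), `classification`
#'   (cell x sf probe classes) and `tuning` (full-field SF tuning curves).
#' @export
run_rf_grid_search <- function(scale = c("full", "test"),
                               grid = pixel_grid(60, 200),
                               cells = grid_search_cells(),
                               sfs = c(0.01, 0.02, 0.04, 0.08, 0.16, 0.32),
                               radius = 30,
                               tuning_sfs = seq(0.005, 0.4, by = 0.005)) {
  orientations <- seq(0, 165, by = 15)
  ap <- aperture("circle", radius = radius)
  i0 <- grid_origin_index(grid)
  c0 <- grid$coords[i0]
  summ <- cells
  summ$peak_sf_fft <- NA_real_
  summ$peak_sf_closed_form <- NA_real_
  cls_list <- list()
  tun_list <- list()
  for (i in seq_len(nrow(cells))) {
    sc <- cells$sigma_center[i]
    ss <- if (is.na(cells$sigma_surround[i])) NULL else cells$sigma_surround[i]
    cs <- cells$cs_ratio[i]
    rf <- dog_rf(grid, sc, ss, cs, center = c(c0, c0))
    summ$peak_sf_fft[i] <- peak_spatial_frequency(rf, grid)
    summ$peak_sf_closed_form[i] <- dog_peak_sf(sc, ss, cs)
    inset <- .probe_inset(sc, if (is.null(ss)) NA else ss, cs)
    pr <- edge_probes(ap, inset = inset)[1, , drop = FALSE] # right edge
    tens <- dog_unit_tuning(grid, sc, ss, cs, cbind(pr$x, pr$y),
                            orientations, sfs, ap)
    cl <- .classify_probes(tens, orientations, sfs, pr)
    cl$cell <- i
    cls_list[[i]] <- cl
    tun <- dog_unit_tuning(grid, sc, ss, cs, cbind(0, 0),
                           orientations = 0, sfs = tuning_sfs,
                           ap = aperture("none"), phases = c(0, 90))
    tun_list[[i]] <- data.frame(cell = i, sf = tuning_sfs,
                                response = as.vector(unclass(tun)[1, , 1]))
  }
  list(summary = summ, classification = do.call(rbind, cls_list),
       tuning = do.call(rbind, tun_list))
}

#' Bar stimulus experiment
#'
#' A 2-degree light bar swept across a simulated display with hard edges.
#' In single-RF mode (display spanning x in \[-30, 0\], RF at the display
#' edge (0, 0)) the display edge is treated as either a mask or a boundary;
#' in grid mode (display +-15 deg, RF lattice within +-20 deg, boundary
#' edges) bar orientation-selectivity (OS_bar) maps are produced for three
#' RF sizes. Responses use the linear on-center route with the no-bar
#' baseline subtracted (after subtraction the response is the bar-overlap
#' integral, identical for the thresholded route), computed exactly through
#' the separable structure of the DoG kernel and the bar frames.
#'
#' @inheritParams run_aperture_experiment
#' @param rf_sizes list of `c(sigma_center, sigma_surround)` pairs.
#' @param cs_ratio surround volume ratio shared by all sizes.
#' @param include_maps run the grid-mode OS_bar maps.
#' @param os_threshold |OS_bar| level used for the selective-area summary.
#' @return list with `single` (per RF size and edge mode: mean responses,
#'   ratio, OS_bar), and in grid mode `maps` (per RF size: `os_bar`,
#'   `preference`, `mean_h`, `mean_v` matrices on the bar grid) and `area`
#'   (selective-area counts).
#' @export
run_bar_experiment <- function(scale = c("full", "test"),
                               rf_sizes = list(c(0.8, 4.7), c(3, 6.5),
                                               c(6, 15)),
                               cs_ratio = 0.4, include_maps = TRUE,
                               os_threshold = 0.05) {
  preset <- scale_preset(scale)
  grid <- pixel_grid(30, preset$bar_n)
  positions <- seq(-30, 30, by = preset$bar_step)
  single <- list()
  for (sz in rf_sizes) {
    for (mode in c("mask", "boundary")) {
      resp <- NULL; meta <- NULL
      for (orient in c("vertical", "horizontal")) {
        spec <- bar_stimulus_spec(orient, positions, width = 2,
                                  display = c(-30, 0, -30, 30),
                                  edge_mode = mode)
        br <- .bar_unit_sweep(grid, sz[1], sz[2], cs_ratio, c(0, 0), spec)
        resp <- c(resp, br$responses)
        meta <- rbind(meta, br$meta)
      }
      resp <- c(resp, 0) # explicit blank frame
      meta <- rbind(meta, data.frame(orientation = "blank", center = NA_real_,
                                     is_blank = TRUE))
      st <- bar_response_statistics(resp, meta)
      st$ratio_h_v <- st$mean_h / st$mean_v
      single[[paste0("rf_", sz[1], "_", sz[2], "_", mode)]] <-
        cbind(data.frame(sigma_center = sz[1], sigma_surround = sz[2],
                         edge_mode = mode), st)
    }
  }
  out <- list(single = do.call(rbind, single))
  if (include_maps) {
    display <- c(-15, 15, -15, 15)
    x <- grid$coords
    dx <- which(x >= display[1] & x <= display[2])
    dy <- which(x >= display[3] & x <= display[4])
    maps <- list(); area <- NULL
    rf_keep <- abs(grid$coords) <= 20
    for (sz in rf_sizes) {
      sum_h <- sum_v <- mx <- matrix(0, grid$n_pixels, grid$n_pixels)
      n_h <- n_v <- 0L
      for (orient in c("vertical", "horizontal")) {
        spec <- bar_stimulus_spec(orient, positions, width = 2,
                                  display = display, edge_mode = "boundary")
        centers <- bar_boundary_positions(spec)
        axis_idx <- if (orient == "vertical") dx else dy
        other_idx <- if (orient == "vertical") dy else dx
        # fixed sweep duration: removed boundary frames count as blanks
        if (orient == "horizontal") n_h <- length(positions)
        else n_v <- length(positions)
        for (cc in centers) {
          slab <- axis_idx[abs(x[axis_idx] - cc) <= spec$width / 2]
          r <- .dog_bar_slab_field(grid, sz[1], sz[2], cs_ratio,
                                   slab, other_idx, orient)
          mx <- pmax(mx, abs(r))
          if (orient == "horizontal") sum_h <- sum_h + r
          else sum_v <- sum_v + r
        }
      }
      mx[mx == 0] <- 1
      mh <- (sum_h / n_h) / mx
      mv <- (sum_v / n_v) / mx
      ob <- os_bar(as.vector(mh), as.vector(mv))
      osm <- matrix(ob$os_bar, grid$n_pixels, grid$n_pixels)
      prm <- matrix(ob$preference, grid$n_pixels, grid$n_pixels)
      osm[!rf_keep, ] <- NA; osm[, !rf_keep] <- NA
      key <- paste0("rf_", sz[1], "_", sz[2])
      maps[[key]] <- list(os_bar = osm, preference = prm,
                          mean_h = mh, mean_v = mv,
                          coords = grid$coords)
      # how far from the display edge the selectivity pattern extends:
      # |OS_bar|-weighted mean distance from the nearest display edge
      Xc <- matrix(grid$coords, grid$n_pixels, grid$n_pixels)
      dedge <- pmin(abs(abs(Xc) - display[2]), abs(abs(t(Xc)) - display[2]))
      w <- abs(osm); w[is.na(w)] <- 0
      area <- rbind(area, data.frame(
        sigma_center = sz[1], sigma_surround = sz[2],
        selective_area = sum(abs(osm) > os_threshold, na.rm = TRUE),
        selective_spread = sum(w * dedge) / sum(w)))
    }
    out$maps <- maps
    out$area <- area
  }
  out$params <- list(scale = scale[1], cs_ratio = cs_ratio,
                     positions_step = preset$bar_step,
                     grid_n = preset$bar_n, os_threshold = os_threshold)
  out
}

#' Single-unit vs population RF structure comparison
#'
#' Center-surround and randomly oriented V1-like populations viewing the
#' same 0.04 cpd, 30-degree-radius circular grating. Produces paired
#' single-unit and population orientation maps for both RF types and
#' edge-probe alignment statistics (mean cos of twice the angular deviation
#' from the local edge normal; 1 = perfectly radial).
#'
#' @inheritParams run_aperture_experiment
#' @param f_pref Gabor preferred spatial frequency, cycles/degree.
#' @param rf_orientations the discrete Gabor orientation set sampled at
#'   each location.
#' @return list with `maps` (`dog$single`, `dog$population`,
#'   `gabor$single`, `gabor$population`), `stats` (probe alignments and
#'   per-probe detail) and `params`.
#' @export
run_single_unit_population_comparison <- function(
    scale = c("full", "test"), grid = pixel_grid(60, 200),
    sigma_center = 0.8, sigma_surround = 4.7, cs_ratio = 0.4,
    f_pref = 0.08, sf = 0.04, radius = 30,
    rf_orientations = seq(0, 157.5, by = 22.5),
    pop_kernel_deg = 0.44, seed = 1) {
  orientations <- seq(0, 165, by = 15)
  ap <- aperture("circle", radius = radius)
  n <- grid$n_pixels

  dog_f <- unclass(dog_response_fields(grid, sigma_center, sigma_surround,
                                       cs_ratio, orientations, sf, ap))
  dog_m <- .model_condition_fields(list(dog = dog_f))$dog
  gab_f <- unclass(gabor_response_fields(grid, f_pref, rf_orientations,
                                         orientations, sf, ap))
  gab_m <- .model_condition_fields(list(g = gab_f))$g  # [x,y,orient,rf_orient]

  # one random RF orientation per location, shared across stimulus conditions
  loc <- array(gab_m, dim = c(n * n, length(orientations),
                              length(rf_orientations)))
  sel <- assign_random_rf_orientation(loc, seed = seed)
  pick <- attr(sel, "rf_orientation_index")
  gab_sel <- array(sel, dim = c(n, n, length(orientations)))

  # Population pooling for the V1-like map follows the published sampling
  # density: one random orientation is drawn per *map sample*, with samples
  # about twice as dense as the RF lattice (as the anatomical grid is), so
  # the 0.44-deg kernel pools a local group of independently oriented
  # units. Responses are bilinearly resampled onto the finer grid.
  fine <- seq(-grid$fov_half, grid$fov_half, by = grid$spacing / 2)
  nf <- length(fine)
  fx <- rep(fine, times = nf); fy <- rep(fine, each = nf)
  old_rs <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 1)
  pick_fine <- sample.int(length(rf_orientations), nf * nf, replace = TRUE)
  if (!is.null(old_rs)) assign(".Random.seed", old_rs, globalenv())
  gab_fine <- array(NA_real_, dim = c(nf * nf, length(orientations)))
  for (k in seq_along(rf_orientations)) {
    idx <- which(pick_fine == k)
    gab_fine[idx, ] <- resample_bilinear(gab_m[, , , k], grid$coords,
                                         grid$coords, fx[idx], fy[idx])
  }
  gab_fine <- array(gab_fine, dim = c(nf, nf, length(orientations)))
  fine_grid <- pixel_grid(grid$fov_half, nf)

  maps <- list(
    dog = list(
      single = .map_from_modelled(dog_m, orientations, grid,
                                  condition = "center-surround"),
      population = .map_from_modelled(
        .smooth_fields(dog_m, grid$spacing, pop_kernel_deg),
        orientations, grid, condition = "center-surround (population)")),
    gabor = list(
      single = .map_from_modelled(gab_sel, orientations, grid,
                                  condition = "V1-like"),
      population = .map_from_modelled(
        .smooth_fields(gab_fine, grid$spacing / 2, pop_kernel_deg),
        orientations, fine_grid, condition = "V1-like (population)")))

  inset <- .probe_inset(sigma_center, sigma_surround, cs_ratio)
  pr <- edge_probes(ap, inset = inset)
  pidx <- cbind(vapply(pr$x, function(v) which.min(abs(grid$coords - v)), 1L),
                vapply(pr$y, function(v) which.min(abs(grid$coords - v)), 1L))
  pidx_f <- cbind(vapply(pr$x, function(v) which.min(abs(fine - v)), 1L),
                  vapply(pr$y, function(v) which.min(abs(fine - v)), 1L))
  probe_pref <- function(map) {
    idx <- if (nrow(map$preferred) == nf) pidx_f else pidx
    map$preferred[idx]
  }
  gab_theta <- rf_orientations[pick[(pidx[, 2] - 1L) * n + pidx[, 1]]]
  # pooled maps carry finite-sample orientation noise at single pixels, so
  # the population radial statistic aggregates over the whole ring at the
  # aperture boundary (where the V1-like population band lies)
  ring_alignment <- function(map, r0, width = 1) {
    nn <- nrow(map$preferred)
    cs <- map$coords$x
    Xr <- matrix(cs, nn, nn); Yr <- matrix(cs, nn, nn, byrow = TRUE)
    rr <- sqrt(Xr^2 + Yr^2)
    band <- rr >= r0 - width & rr <= r0 + width
    normal <- (atan2(Yr, Xr) * 180 / pi) %% 180
    edge_alignment(map$preferred[band], normal[band])
  }
  stats <- list(
    dog_single_alignment = edge_alignment(probe_pref(maps$dog$single),
                                          pr$normal),
    dog_population_alignment = edge_alignment(
      probe_pref(maps$dog$population), pr$normal),
    gabor_population_alignment = ring_alignment(maps$gabor$population,
                                                radius),
    gabor_single_dev_from_own = orientation_distance(
      probe_pref(maps$gabor$single), gab_theta),
    detail = data.frame(pr,
                        dog_single = probe_pref(maps$dog$single),
                        dog_population = probe_pref(maps$dog$population),
                        gabor_single = probe_pref(maps$gabor$single),
                        gabor_theta = gab_theta,
                        gabor_population = probe_pref(maps$gabor$population)))
  list(maps = maps, stats = stats,
       params = list(sf = sf, f_pref = f_pref, radius = radius,
                     probe_inset = inset, seed = seed, scale = scale[1]))
}

#' Preference switching and maintenance experiment
#'
#' A fixed set of unit locations within the central visual field responds
#' to 36 grating orientations vignetted by a horizontal edge, a vertical
#' edge (half-disc apertures), or no aperture at all, for center-surround
#' and V1-like RF structure. Center-surround units switch their preference
#' with the edge orientation; V1-like units keep their intrinsic
#' preference. With no aperture, response noise is the only source of
#' preference variation for center-surround units.
#'
#' Default unit placements are seeded uniform draws over the quadrant of
#' the central 20 x 20 degree region that remains stimulated under both
#' half-disc apertures (exact coordinates may be supplied).
#'
#' @inheritParams run_aperture_experiment
#' @param n_units number of units (default 53).
#' @param units optional explicit unit coordinates (n x 2 matrix, degrees).
#' @param orientations stimulus orientations (default 36 in 5-deg steps).
#' @param f_pref Gabor preferred SF, cycles/degree.
#' @param gabor_orientations per-unit Gabor orientation, degrees (default:
#'   seeded uniform over \[0, 180)).
#' @param radius radius of the vignetting circle, degrees.
#' @param noise `"none_only"` adds the modelled Gaussian noise only in the
#'   no-aperture condition (where it is the object of study); `TRUE`/
#'   `FALSE` switch it for all conditions.
#' @param n_fits number of example units receiving von Mises tuning fits.
#' @return list with `dog` and `gabor` sub-lists (`preferred`: unit x
#'   condition matrix, `switch`: per-unit circular distance between the two
#'   edge conditions, `fits`: example von Mises fits), `units`, `summary`
#'   and `params`.
#' @export
run_preference_switching <- function(scale = c("full", "test"),
                                     grid = pixel_grid(60, 200),
                                     n_units = 53, units = NULL,
                                     orientations = seq(0, 175, by = 5),
                                     sigma_center = 0.8,
                                     sigma_surround = 4.7, cs_ratio = 0.4,
                                     f_pref = 0.08, sf = 0.04, radius = 30,
                                     gabor_orientations = NULL,
                                     noise = "none_only", noise_sd = 0.01,
                                     seed = 1, n_fits = 2) {
  if (is.null(units)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    units <- cbind(stats::runif(n_units, 1, 10), stats::runif(n_units, 1, 10))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  units <- matrix(units, ncol = 2)
  n_units <- nrow(units)
  if (is.null(gabor_orientations)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed + 1)
    gabor_orientations <- stats::runif(n_units, 0, 180)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  conds <- list(
    horizontal_edge = list(aperture("circle", radius = radius),
                           aperture("half_plane_horizontal_edge")),
    vertical_edge = list(aperture("circle", radius = radius),
                         aperture("half_plane_vertical_edge")),
    none = list(aperture("none")))
  noise_for <- function(cond) {
    if (identical(noise, "none_only")) cond == "none" else isTRUE(noise)
  }
  analyze <- function(tuning_fun) {
    raw <- lapply(names(conds), function(nm) tuning_fun(conds[[nm]]))
    names(raw) <- names(conds)
    modelled <- list()
    rng <- range(unlist(lapply(raw, range)))
    span <- diff(rng)
    for (nm in names(conds)) {
      v <- if (span > 1e-9 * max(abs(rng), 1e-300))
        (raw[[nm]] - rng[1]) / span else array(0, dim = dim(raw[[nm]]))
      v <- v + 1 # alpha = beta = 1
      if (noise_for(nm)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(seed + 2)
        v <- v + stats::rnorm(length(v), 0, noise_sd)
        dim(v) <- dim(raw[[nm]])
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }
      modelled[[nm]] <- v
    }
    pref_resultant <- vapply(modelled, function(v)
      preferred_orientation(t(v), orientations), numeric(n_units))
    # single-unit preferences are read from fitted von Mises tuning curves
    # (the doubled-angle resultant is biased toward the aperture's radial
    # energy for units within a degree or two of the edge)
    pref <- vapply(modelled, function(v)
      vapply(seq_len(ncol(v)), function(u) {
        f <- try(fit_von_mises(v[, u], orientations), silent = TRUE)
        if (inherits(f, "try-error")) pref_resultant[u, 1]
        else coef(f)[["mu"]]
      }, numeric(1)), numeric(n_units))
    dimnames(pref) <- dimnames(pref_resultant)
    g <- vapply(modelled, function(v)
      suppressWarnings(gosi(t(v), orientations)), numeric(n_units))
    fits <- lapply(seq_len(min(n_fits, n_units)), function(u)
      lapply(modelled, function(v) fit_von_mises(v[, u], orientations)))
    list(preferred = pref, preferred_resultant = pref_resultant, gosi = g,
         switch = orientation_distance(pref[, "horizontal_edge"],
                                       pref[, "vertical_edge"]),
         fits = fits, modelled = modelled)
  }
  dog_res <- analyze(function(ap_list) {
    t <- dog_unit_tuning(grid, sigma_center, sigma_surround, cs_ratio,
                         units, orientations, sf, ap_list)
    array(unclass(t)[, 1, ], dim = c(length(orientations), n_units))
  })
  gab_res <- analyze(function(ap_list) {
    t <- gabor_unit_tuning(grid, f_pref, units, gabor_orientations,
                           orientations, sf, ap_list)
    array(unclass(t), dim = c(length(orientations), n_units))
  })
  rs_h <- orientation_resultant(dog_res$preferred[, "horizontal_edge"])
  rs_v <- orientation_resultant(dog_res$preferred[, "vertical_edge"])
  rs_n <- orientation_resultant(dog_res$preferred[, "none"])
  summary <- list(
    dog_mean_pref_horizontal_edge = rs_h$mean,
    dog_mean_pref_vertical_edge = rs_v$mean,
    dog_mean_switch = mean(dog_res$switch),
    dog_none_resultant = rs_n$length,
    rayleigh_null_95 = sqrt(-log(0.05) / n_units),
    gabor_max_dev_from_own = max(orientation_distance(
      gab_res$preferred, matrix(gabor_orientations, n_units, 3))))
  list(dog = dog_res, gabor = gab_res, units = units,
       gabor_orientations = gabor_orientations, summary = summary,
       params = list(orientations = orientations, sf = sf, radius = radius,
                     noise = noise, noise_sd = noise_sd, seed = seed,
                     scale = scale[1]))
}
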