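test_that("spatial-frequency experiment reproduces the preference transition", {
  res <- run_sf_experiment("full")
  cl <- res$classification
  right <- cl[cl$probe == 1, ]
  right <- right[order(right$sf), ]
  expect_equal(right$class,
               c("radial", "radial", "radial", "radial",
                 "anti-radial", "anti-radial"))
  expect_equal(res$lowest_anti_radial_sf, 0.16)
  # the transition is the same at every boundary probe
  expect_true(all(res$transition$lowest_anti_radial_sf == 0.16))
})

test_that("aperture experiment: edge-orthogonal preferences and a silent center", {
  res <- run_aperture_experiment("test")
  sq <- res$probes[res$probes$condition == "square_40", ]
  # square edge midpoints prefer the edge-orthogonal orientation
  expect_equal(sq$pref_argmax[sq$normal == 0 & sq$angle %in% c(0, 180)],
               c(0, 0))
  expect_equal(sq$pref_argmax[sq$normal == 90], c(90, 90))
  # circular aperture: the unit at the stimulus center is far less
  # selective than units along the rim (display-normalized gOSI below the
  # 10th percentile of the rim band)
  m <- res$maps$circle_20$single
  n <- length(m$coords$x)
  ci <- which.min(abs(m$coords$x))
  X <- matrix(m$coords$x, n, n); Y <- matrix(m$coords$y, n, n, byrow = TRUE)
  ring <- sqrt(X^2 + Y^2) >= 18 & sqrt(X^2 + Y^2) <= 20
  expect_lt(m$alpha[ci, ci], stats::quantile(m$alpha[ring], 0.1))
  # population smoothing keeps the map structure (same radial preferences
  # at the boundary probes of the circle)
  circ <- res$probes[res$probes$condition == "circle_30", ]
  expect_true(all(circ$class[circ$normal %% 90 == 0] == "radial"))
})

test_that("classification-level results survive a scaled-down grid", {
  g <- pixel_grid(60, 121) # 1 deg pixels
  sq <- aperture("square", side = 40)
  t56 <- dog_unit_tuning(g, 1.5, 11.4, 0.8, rbind(c(0, 20), c(-20, 0)),
                         ors12, 0.04, sq)
  v <- unclass(t56)
  expect_equal(ors12[which.max(v[, 1, 1])], 90)
  expect_equal(ors12[which.max(v[, 1, 2])], 0)
  # transition frequencies below Nyquist margin behave as at full scale
  pr <- edge_probes(aperture("circle", radius = 30), inset = 4.7)[1, ]
  tens <- dog_unit_tuning(g, 0.8, 4.7, 0.4, cbind(pr$x, pr$y), ors12,
                          sfs = c(0.04, 0.08, 0.16),
                          ap = aperture("circle", radius = 30))
  cls <- classify_radial(
    ors12[apply(unclass(tens)[, , 1], 2, which.max)], pr$normal)
  expect_equal(cls, c("radial", "radial", "anti-radial"))
})

test_that("preference maps rotate with the stimulus (circular aperture)", {
  g <- pixel_grid(30, 61)
  f <- rfpopmap:::.model_condition_fields(list(a = unclass(
    dog_response_fields(g, 0.8, 4.7, 0.4, ors12, 0.1,
                        aperture("circle", radius = 12)))))$a
  m <- rfpopmap:::.map_from_modelled(f, ors12, g)
  n <- g$n_pixels
  pr_rot <- matrix(NA_real_, n, n)
  sel <- m$alpha > 0.2
  sel_rot <- matrix(FALSE, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      pr_rot[n + 1 - j, i] <- m$preferred[i, j]
      sel_rot[n + 1 - j, i] <- sel[i, j]
    }
  }
  d <- abs((m$preferred - (pr_rot + 90)) %% 180)
  d <- pmin(d, 180 - d)
  expect_lt(max(d[sel & sel_rot]), 1e-6)
})

test_that("grid search: surround cells hold 0.08 cpd; no surround, no radial", {
  gs <- run_rf_grid_search()
  bin <- 1 / (200 * (120 / 199))
  surround <- gs$summary$cs_ratio > 0
  expect_true(all(abs(gs$summary$peak_sf_fft[surround] - 0.08) < bin))
  expect_true(all(abs(gs$summary$peak_sf_fft[surround] -
                        gs$summary$peak_sf_closed_form[surround]) < bin))
  # no-surround (lowpass) cell is never classified radial at any frequency
  ns_cell <- which(gs$summary$cs_ratio == 0)
  ns <- gs$classification[gs$classification$cell == ns_cell, ]
  expect_true(all(ns$class == "anti-radial"))
  # the (4.7, 0.4) cell reproduces the spatial-frequency experiment
  ref <- which(gs$summary$sigma_surround == 4.7 & gs$summary$cs_ratio == 0.4)
  rc <- gs$classification[gs$classification$cell == ref, ]
  rc <- rc[order(rc$sf), ]
  expect_equal(rc$class, c("radial", "radial", "radial", "radial",
                           "anti-radial", "anti-radial"))
  # full-field SF tuning curves of surround cells peak near 0.08
  for (cell in which(surround)) {
    tun <- gs$tuning[gs$tuning$cell == cell, ]
    expect_lt(abs(tun$sf[which.max(tun$response)] - 0.08), 0.02)
  }
})

test_that("bar experiment: mask edges are silent, boundary edges oriented", {
  res <- run_bar_experiment("test")
  s <- res$single
  mask <- s[s$edge_mode == "mask", ]
  # mask-mode: horizontal and vertical sweeps drive the edge RF equally
  expect_true(all(abs(mask$ratio_h_v - 1) < 0.01))
  expect_true(all(mask$os_bar < 1e-9))
  # boundary-mode: horizontal bars win at a vertical display edge
  bound <- s[s$edge_mode == "boundary", ]
  expect_true(all(bound$mean_h > bound$mean_v))
  expect_true(all(bound$preference == "horizontal"))
  # larger RFs spread selectivity further from the display edge
  expect_true(all(diff(res$area$selective_spread) > 0))
  # boundary maps: horizontal preference along vertical display edges and
  # vice versa (majority vote within 2 deg of each edge, selective pixels)
  m <- res$maps[["rf_0.8_4.7"]]
  n <- length(m$coords)
  X <- matrix(m$coords, n, n); Y <- matrix(m$coords, n, n, byrow = TRUE)
  vedge <- abs(abs(X) - 15) <= 2 & abs(Y) <= 10 & !is.na(m$os_bar) &
    m$os_bar > 0.05
  hedge <- abs(abs(Y) - 15) <= 2 & abs(X) <= 10 & !is.na(m$os_bar) &
    m$os_bar > 0.05
  expect_gt(mean(m$preference[vedge] == "horizontal"), 0.9)
  expect_gt(mean(m$preference[hedge] == "vertical"), 0.9)
})

test_that("single-unit vs population comparison separates the RF structures", {
  res <- run_single_unit_population_comparison("test", seed = 3)
  st <- res$stats
  # center-surround preferences are radial at edge probes, and remain so
  # after population smoothing
  expect_gt(st$dog_single_alignment, 0.9)
  expect_gt(st$dog_population_alignment, 0.9)
  # V1-like single units keep their own orientation (within 15 deg)
  expect_true(all(st$gabor_single_dev_from_own <= 15))
  # but the pooled V1-like population turns radial along the aperture
  expect_gt(st$gabor_population_alignment, 0.3)
})

test_that("preference switching: center-surround units switch, V1-like hold", {
  ps <- run_preference_switching(seed = 1)
  sm <- ps$summary
  d90 <- abs(((sm$dog_mean_pref_horizontal_edge - 90 + 90) %% 180) - 90)
  d0 <- abs(((sm$dog_mean_pref_vertical_edge + 90) %% 180) - 90)
  expect_lt(d90, 10)
  expect_lt(d0, 10)
  expect_gt(sm$dog_mean_switch, 80)
  expect_lte(sm$gabor_max_dev_from_own, 15)
  # no aperture + noise: preferences scatter uniformly (resultant under the
  # Rayleigh-style null bound) and selectivity is negligible
  expect_lt(sm$dog_none_resultant, sm$rayleigh_null_95)
  expect_lt(max(ps$dog$gosi[, "none"]), 0.05)
  # example fits exist for both RF types and all conditions
  expect_s3_class(ps$dog$fits[[1]]$horizontal_edge, "von_mises_fit")
  expect_s3_class(ps$gabor$fits[[1]]$none, "von_mises_fit")
})
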