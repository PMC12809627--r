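test_that("unit responses are dot products with shape checking", {
  g <- tiny_grid()
  rf <- dog_rf(g, 1, 4, 0.5)
  expect_equal(unit_response(rf, matrix(0, g$n_pixels, g$n_pixels)), 0)
  expect_gt(unit_response(rf, rf), 0)
  expect_equal(unit_response(rf, rf), sum(rf^2))
  expect_error(unit_response(rf, matrix(0, 3, 3)), "grid")
})

test_that("On/Off combination is rectified, polarity-invariant", {
  expect_equal(combine_onoff(0.5, -0.5), 0.5)
  expect_equal(combine_onoff(-2, -3), 0)
  expect_equal(combine_onoff(c(1, -1), c(-1, 1)), c(1, 1))
  # for an exact opposite-polarity pair the combined response is |r|
  r <- rnorm(50)
  expect_equal(combine_onoff(r, -r), abs(r))
  # stimulus luminance polarity invariance, exactly
  g <- tiny_grid()
  on <- dog_rf(g, 1, 4, 0.5); off <- -on
  s <- apply_aperture(render_grating(g, 30, 0.05, 1),
                      aperture("circle", radius = 15), g)
  expect_identical(
    combine_onoff(unit_response(on, s), unit_response(off, s)),
    combine_onoff(unit_response(on, -s), unit_response(off, -s)))
})

test_that("quadrature energy is stimulus-phase invariant", {
  expect_equal(quadrature_energy(3, 4), 25)
  expect_equal(quadrature_energy(0, 0), 0)
  g <- small_grid()
  q <- gabor_quadrature(g, 45, 0.08, center = c(10, 5))
  en <- vapply(c(0, 45, 90, 135) * pi / 180, function(ph) {
    s <- render_grating(g, 30, 0.08, ph)
    quadrature_energy(unit_response(q$phase0, s), unit_response(q$phase90, s))
  }, numeric(1))
  expect_lt(diff(range(en)) / mean(en), 0.01)
  # near an aperture edge single-phase energies do vary, but the balanced
  # 4-phase arithmetic mean is exactly invariant to the phase origin
  ap <- aperture("circle", radius = 25)
  mean_en <- function(shift) mean(vapply(
    (c(0, 90, 180, 270)) * pi / 180 + shift, function(ph) {
      s <- apply_aperture(render_grating(g, 30, 0.08, ph), ap, g)
      quadrature_energy(unit_response(q$phase0, s),
                        unit_response(q$phase90, s))
    }, numeric(1)))
  expect_equal(mean_en(0), mean_en(0.61), tolerance = 1e-9)
})

test_that("stimulus-phase averaging: arithmetic and invariant methods", {
  t4 <- response_tensor(array(c(0, 0, 2, 2), c(4, 1)), c("phase", "unit"),
                        stage = "combined", kind = "energy",
                        phases = c(0, 90, 180, 270))
  expect_equal(as.vector(average_over_stimulus_phases(t4, "arithmetic")), 1)
  expect_equal(tensor_stage(average_over_stimulus_phases(t4)),
               "phase_averaged")

  # invariant collapse equals the exact mean of |A cos(phi - psi)| over the
  # continuous phase circle -- oracle: dense rendered phase sweep
  g <- tiny_grid()
  rf <- dog_rf(g, 1, 4, 0.5, center = c(8, 3))
  ap <- aperture("circle", radius = 12)
  resp <- function(ph) {
    s <- apply_aperture(render_grating(g, 30, 0.07, ph), ap, g)
    abs(unit_response(rf, s))
  }
  dense <- mean(vapply(seq(0, 2 * pi, length.out = 7201)[-7201], resp,
                       numeric(1)))
  batt <- vapply(c(0, 90, 180, 270) * pi / 180, resp, numeric(1))
  tb <- response_tensor(array(batt, c(4, 1)), c("phase", "unit"),
                        stage = "combined", kind = "onoff",
                        phases = c(0, 90, 180, 270))
  inv <- as.vector(average_over_stimulus_phases(tb, "invariant"))
  expect_equal(inv, dense, tolerance = 1e-6)
  # identical result from the minimal 0/90 pair
  t2 <- response_tensor(array(batt[1:2], c(2, 1)), c("phase", "unit"),
                        stage = "combined", kind = "onoff", phases = c(0, 90))
  expect_equal(as.vector(average_over_stimulus_phases(t2)), inv)
  # the phase-averaged value is invariant under re-randomized phase sets
  shift <- 0.42
  batt2 <- vapply(c(0, 90, 180, 270) * pi / 180 + shift, resp, numeric(1))
  tb2 <- response_tensor(array(batt2, c(4, 1)), c("phase", "unit"),
                         stage = "combined", kind = "onoff",
                         phases = c(0, 90, 180, 270))
  expect_equal(as.vector(average_over_stimulus_phases(tb2)), inv,
               tolerance = 1e-9)
  # unbalanced phase sets are rejected for the invariant method
  tu <- response_tensor(array(batt[1:2], c(2, 1)), c("phase", "unit"),
                        stage = "combined", kind = "onoff", phases = c(0, 45))
  expect_error(average_over_stimulus_phases(tu, "invariant"), "balanced")
})

test_that("normalization rescales globally and guards constants", {
  t <- response_tensor(array(c(2, 4, 6), 3), "unit", stage = "phase_averaged")
  expect_equal(as.vector(normalize_responses(t)), c(0, 0.5, 1))
  t01 <- response_tensor(array(c(0, 0.25, 1), 3), "unit",
                         stage = "phase_averaged")
  expect_equal(as.vector(normalize_responses(t01)), c(0, 0.25, 1))
  tc <- response_tensor(array(rep(5, 4), 4), "unit", stage = "phase_averaged")
  expect_warning(z <- normalize_responses(tc), "constant")
  expect_equal(as.vector(z), rep(0, 4))
  # argmax position is preserved (monotone map)
  v <- runif(20)
  tv <- response_tensor(array(v, 20), "unit", stage = "phase_averaged")
  expect_equal(which.max(as.vector(normalize_responses(tv))), which.max(v))
  expect_error(normalize_responses(z), "stage")
})

test_that("total response model applies gain, baseline and seeded noise", {
  t <- response_tensor(array(c(0, 0.5, 1), 3), "unit", stage = "normalized")
  m <- apply_response_model(t, alpha = 1, beta = 1, noise = FALSE)
  expect_equal(as.vector(m), c(1, 1.5, 2))
  expect_equal(tensor_stage(m), "modelled")
  # with alpha = beta = 1 the pre-noise ceiling is a 100% increase
  expect_equal((max(as.vector(m)) - 1) / 1 * 100, 100)
  n1 <- apply_response_model(t, noise = TRUE, seed = 7)
  n2 <- apply_response_model(t, noise = TRUE, seed = 7)
  expect_identical(as.vector(n1), as.vector(n2))
  n3 <- apply_response_model(t, noise = TRUE, seed = 8)
  expect_false(identical(as.vector(n1), as.vector(n3)))
})

test_that("FFT response fields equal per-unit dot products", {
  g <- pixel_grid(32, 64)
  i0 <- which.min(abs(g$coords))
  c0 <- g$coords[i0]
  kern <- dog_rf(g, 1, 4, 0.5, center = c(c0, c0))
  s <- apply_aperture(render_grating(g, 30, 0.05, 0.7),
                      aperture("circle", radius = 20), g)
  f <- response_field(s, kern, g)
  idx <- cbind(c(1, 10, 33, 64, 50), c(5, 60, 33, 1, 50))
  direct <- apply(idx, 1, function(ij)
    direct_dog_response(g, 1, 4, 0.5,
                        c(g$coords[ij[1]], g$coords[ij[2]]), s))
  expect_lt(max(abs(f[idx] - direct)) / max(abs(direct)), 1e-6)
})

test_that("full-field grating sweep peaks at the DoG preferred frequency", {
  g <- std_grid()
  bin <- 1 / (g$n_pixels * g$spacing)
  sfs <- seq(bin, 0.2, by = bin)
  tens <- dog_unit_tuning(g, 0.8, 4.7, 0.4, cbind(0, 0), orientations = 0,
                          sfs = sfs, ap = aperture("none"),
                          phases = c(0, 90))
  tune <- as.vector(unclass(tens)[1, , 1])
  expect_lt(abs(sfs[which.max(tune)] - peak_spatial_frequency(
    dog_rf(g, 0.8, 4.7, 0.4), g)), bin + 1e-12)
})

test_that("bar statistics subtract baseline and normalize presentations", {
  # small rendered sweep, responses via plain dot products
  g <- tiny_grid()
  kern <- dog_rf(g, 1, 4, 0.4, center = c(0, 0))
  disp <- c(-30, 0, -30, 30)
  resp <- NULL; meta <- NULL
  for (orient in c("vertical", "horizontal")) {
    fr <- render_bar_frames(
      bar_stimulus_spec(orient, seq(-30, 30, 2), 2, disp, "mask"), g,
      include_blank = (orient == "vertical"))
    resp <- c(resp, vapply(fr$frames, function(f) sum(kern * f), numeric(1)))
    meta <- rbind(meta, fr$meta)
  }
  st <- bar_response_statistics(resp, meta)
  # blank-frame response equals the baseline, i.e. zero after subtraction
  blank_i <- which(meta$orientation == "blank")
  baseline <- mean(resp[meta$is_blank])
  expect_equal(resp[blank_i] - baseline, 0)
  expect_true(all(abs(c(st$mean_h, st$mean_v)) <= 1))
  expect_error(bar_response_statistics(resp, transform(meta, is_blank = FALSE)),
               "blank")
})

test_that("separable bar sweep equals rendered-frame dot products", {
  g <- tiny_grid()
  disp <- c(-30, 0, -30, 30)
  for (mode in c("mask", "boundary")) {
    spec <- bar_stimulus_spec("vertical", seq(-30, 30, 3), 2, disp, mode)
    sw <- rfpopmap:::.bar_unit_sweep(g, 1, 4, 0.4, c(-2, 3), spec)
    kern <- dog_rf(g, 1, 4, 0.4, center = c(-2, 3))
    bg <- rfpopmap:::display_background(disp, g)
    rbase <- sum(kern * bg)
    fr <- render_bar_frames(spec, g, include_blank = FALSE)
    rendered <- vapply(fr$frames, function(f) sum(kern * f), numeric(1)) - rbase
    shown <- sw$meta$center %in% fr$meta$center & !sw$meta$is_blank
    expect_equal(sw$responses[shown],
                 rendered[match(sw$meta$center[shown], fr$meta$center)],
                 tolerance = 1e-9)
    expect_true(all(sw$responses[!shown] == 0))
  }
  # slab-field route agrees with the 2-D FFT correlation route
  x <- g$coords
  dx <- which(x >= disp[1] & x <= disp[2])
  dy <- which(x >= disp[3] & x <= disp[4])
  slab <- dx[abs(x[dx] - (-6)) <= 1]
  fld <- rfpopmap:::.dog_bar_slab_field(g, 1, 4, 0.4, slab, dy, "vertical")
  i0 <- which.min(abs(x)); c0 <- x[i0]
  kern0 <- dog_rf(g, 1, 4, 0.4, center = c(c0, c0))
  frame <- rfpopmap:::display_background(disp, g)
  m <- grid_mesh(g)
  frame[abs(m$x - (-6)) <= 1 & frame == 0] <- 1
  fft_field <- response_field(frame, kern0, g) -
    response_field(rfpopmap:::display_background(disp, g), kern0, g)
  expect_equal(fld, fft_field, tolerance = 1e-8)
})
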