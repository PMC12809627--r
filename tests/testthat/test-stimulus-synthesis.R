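test_that("grating rendering follows the stripe-orientation convention", {
  g <- small_grid()
  i0 <- which(g$coords == 0)
  img <- render_grating(g, orientation = 0, sf = 0.04, phase = 0)
  # cos(0) = 1 at the origin, any frequency
  expect_equal(img[i0, i0], 1)
  # horizontal grating: every column of constant y is constant along x
  expect_equal(max(abs(sweep(img, 2, img[1, ]))), 0)
  # vertical grating varies along x only
  imgv <- render_grating(g, orientation = 90, sf = 0.04)
  expect_equal(max(abs(sweep(imgv, 1, imgv[, 1]))), 0)
  # oblique orientation: with counterclockwise-positive angles the image is
  # constant along the stripe direction, here the main diagonal for 45 deg
  img45 <- render_grating(g, orientation = 45, sf = 0.05)
  idx <- 20:40
  expect_lt(max(abs(diff(img45[cbind(idx, idx)]))), 1e-12)
  # and NOT constant along the anti-diagonal (the clockwise mirror)
  expect_gt(max(abs(diff(img45[cbind(idx, g$n_pixels + 1 - idx)]))), 0.1)
  # values bounded
  expect_true(all(abs(img45) <= 1))
})

test_that("grating spectrum peaks at the stimulus frequency", {
  g <- std_grid()
  img <- render_grating(g, orientation = 0, sf = 0.04)
  f <- stats::fft(img)
  n <- g$n_pixels
  freqs <- 0:(n - 1); freqs[freqs >= n / 2] <- freqs[freqs >= n / 2] - n
  freqs <- freqs / (n * g$spacing)
  # horizontal grating: energy on the vertical frequency axis
  pos <- which(freqs >= 0)
  mag <- Mod(f[1, ])
  pk <- freqs[pos][which.max(mag[pos])]
  expect_lt(abs(pk - 0.04), 1 / (n * g$spacing))  # within one bin
  # and (almost) no energy on the horizontal frequency axis
  expect_lt(max(Mod(f[pos[-1], 1])), max(mag) * 1e-6)
})

test_that("frequencies at or above Nyquist are rejected", {
  g <- small_grid()
  expect_error(render_grating(g, 0, g$nyquist), "Nyquist")
  expect_silent(render_grating(g, 0, g$nyquist * 0.9))
})

test_that("aperture membership uses pixel-center inclusion", {
  g <- small_grid()
  ix <- function(v) which(g$coords == v)
  img <- matrix(1, g$n_pixels, g$n_pixels)
  circ <- apply_aperture(img, aperture("circle", radius = 20), g)
  expect_equal(circ[ix(25), ix(0)], 0)          # 25 deg from center: outside
  expect_equal(circ[ix(20), ix(0)], 1)          # boundary pixel: inside (<=)
  sq <- apply_aperture(img, aperture("square", side = 40), g)
  expect_equal(sq[ix(19), ix(19)], 1)
  expect_equal(sq[ix(21), ix(0)], 0)
  dia <- apply_aperture(img, aperture("diamond", side = 40), g)
  # |x| + |y| <= 40/sqrt(2) ~ 28.28, so (0, 30) is outside but (0, 28) is in
  expect_equal(dia[ix(0), ix(30)], 0)
  expect_equal(dia[ix(0), ix(28)], 1)
  hp <- apply_aperture(img, aperture("half_plane_horizontal_edge"), g)
  expect_equal(hp[ix(5), ix(-1)], 0)
  expect_equal(hp[ix(5), ix(0)], 1)
  expect_error(aperture("circle"), "radius")
  expect_error(aperture("pentagon"), "arg")
})

test_that("aperture application is idempotent", {
  g <- tiny_grid()
  img <- render_grating(g, 30, 0.05, 0.4)
  for (ap in list(aperture("circle", radius = 12),
                  aperture("diamond", side = 20),
                  aperture("half_plane_vertical_edge"))) {
    once <- apply_aperture(img, ap, g)
    expect_identical(apply_aperture(once, ap, g), once)
  }
})

test_that("battery sizes are the product of the factor levels", {
  g <- tiny_grid()
  b <- grating_battery(g, sfs = 0.04, apertures = aperture("none"))
  expect_equal(length(b$images), 48)  # 12 orientations x 4 phases
  b1 <- grating_battery(g, orientations = 0, phases = 0, sfs = 0.04)
  expect_equal(length(b1$images), 1)
  b6 <- grating_battery(g, sfs = c(0.01, 0.02, 0.04, 0.08, 0.16, 0.32) / 2)
  expect_equal(length(b6$images), 288)
})

test_that("phase polarity and rotation symmetries hold", {
  g <- small_grid()
  a <- render_grating(g, 40, 0.06, phase = 0.7)
  b <- render_grating(g, 40, 0.06, phase = 0.7 + pi)
  expect_equal(a, -b)
  # rotating the orientation by 90 deg rotates the image by 90 deg: the
  # new image at (x, y) equals the old image at (y, -x)
  n <- g$n_pixels
  t0 <- render_grating(g, 25, 0.05)
  t90 <- render_grating(g, 115, 0.05)
  rotated <- t0[, n:1][cbind(rep(1:n, n), rep(1:n, each = n))]
  old_at <- matrix(NA_real_, n, n)
  for (i in 1:n) old_at[i, ] <- t0[, n + 1 - i]  # value at (y, -x)
  expect_equal(t90, old_at, tolerance = 1e-12)
})

test_that("bar frames respect mask and boundary edge semantics", {
  g <- tiny_grid()
  pos <- seq(-30, 30, by = 1)
  disp <- c(-30, 0, -30, 30)
  mask <- render_bar_frames(
    bar_stimulus_spec("vertical", pos, 2, disp, "mask"), g)
  bound <- render_bar_frames(
    bar_stimulus_spec("vertical", pos, 2, disp, "boundary"), g)
  # mask: one frame per position plus the explicit blank
  expect_equal(nrow(mask$meta), length(pos) + 1)
  # boundary: strictly fewer frames for bars crossing the display edge
  expect_lt(nrow(bound$meta), nrow(mask$meta))
  # the last presented boundary frame has its leading edge at the display
  # edge: center -1, leading edge -1 + width/2 = 0
  expect_equal(max(bound$meta$center, na.rm = TRUE), -1)
  # mask frames with the bar entirely offscreen are blank
  far <- which(mask$meta$center == 20)
  expect_true(mask$meta$is_blank[far])
  expect_identical(mask$frames[[far]], mask$background)
  # bar pixels are 1, display background 0, offscreen -1
  f <- mask$frames[[which(mask$meta$center == -10)]]
  expect_setequal(unique(as.vector(f)), c(-1, 0, 1))
  expect_error(bar_stimulus_spec(width = 0), "width")
})
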