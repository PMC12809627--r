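test_that("anchor sets are validated", {
  expect_error(anchor_set(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0), c(1, 1))),
               ">= 3")
  expect_error(anchor_set(rbind(c(0, 0), c(1, 1), c(2, 2)), diag(3)[, 1:2]),
               "collinear")
  expect_error(anchor_set(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1)),
                          matrix(0, 4, 2)), "duplicate")
  a <- default_anchors()
  expect_s3_class(a, "anchor_set")
  expect_equal(nrow(a$anat), 10)
})

test_that("natural-neighbor transform is exact at anchors and linear-precise", {
  a <- default_anchors()
  tr <- fit_retinotopy(a)
  p <- predict(tr, a$anat)
  expect_true(all(p$valid))
  expect_equal(cbind(p$x_deg, p$y_deg), unname(a$vis), tolerance = 1e-12)
  # linear precision: identity-valued anchors reproduce any interior query
  ia <- anchor_set(a$anat, a$anat)
  ti <- fit_retinotopy(ia)
  q <- rbind(c(0.11, -0.2), c(0.3, 0.25), c(-0.4, 0.1), c(0, 0))
  pi2 <- predict(ti, q)
  expect_equal(cbind(pi2$x_deg, pi2$y_deg), q, tolerance = 1e-9)
  # centroid of three identity-mapped anchors maps to the centroid
  tri <- anchor_set(rbind(c(0, 0), c(1, 0), c(0, 1)),
                    rbind(c(0, 0), c(1, 0), c(0, 1)))
  ct <- predict(fit_retinotopy(tri), rbind(colMeans(tri$anat)))
  expect_equal(c(ct$x_deg, ct$y_deg), colMeans(tri$anat), tolerance = 1e-9)
})

test_that("queries outside the anchor hull are flagged invalid", {
  tr <- fit_retinotopy(default_anchors())
  out <- predict(tr, rbind(c(2, 2), c(-0.9, 0), c(0, 0)))
  expect_equal(out$valid, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(out$x_deg[1:2])))
  mc <- map_coordinates(tr, rbind(c(0.1, 0.1)))
  expect_true(mc$valid)
})

test_that("default anchors rotate visual into anatomical space", {
  a <- default_anchors()
  # 90-degree rotation sense: anatomical x tracks visual y and anatomical y
  # tracks negative visual x
  expect_gt(cor(a$anat[, 1], a$vis[, 2]), 0.9)
  expect_lt(cor(a$anat[, 2], a$vis[, 1]), -0.9)
})

test_that("transform is continuous inside the hull", {
  tr <- fit_retinotopy(default_anchors())
  t_path <- seq(-0.55, 0.55, length.out = 101)
  p <- predict(tr, cbind(t_path, 0.2 * sin(3 * t_path)))
  expect_true(all(p$valid))
  steps <- sqrt(diff(p$x_deg)^2 + diff(p$y_deg)^2)
  # no jumps: steps stay within a small multiple of the query spacing
  # scaled by the anatomical-to-visual magnification (~48 deg/mm)
  expect_lt(max(steps), 10 * (t_path[2] - t_path[1]) * 48)
})

test_that("bilinear resampling is exact on nodes, cells and affine fields", {
  xs <- seq(-2, 2, by = 0.5); ys <- seq(-1, 3, by = 0.5)
  f <- outer(xs, ys, function(x, y) 2 * x - 3 * y + 1)
  # node
  expect_equal(resample_bilinear(f, xs, ys, xs[3], ys[4]), f[3, 4])
  # center of a cell with values {0, 0, 2, 2}
  m <- matrix(c(0, 0, 2, 2), 2, 2)
  expect_equal(resample_bilinear(m, c(0, 1), c(0, 1), 0.5, 0.5), 1)
  # affine exactness at arbitrary interior points
  set.seed(1)
  tx <- runif(50, -2, 2); ty <- runif(50, -1, 3)
  expect_equal(resample_bilinear(f, xs, ys, tx, ty),
               2 * tx - 3 * ty + 1, tolerance = 1e-9)
  # outside-extent targets are excluded
  expect_true(is.na(resample_bilinear(f, xs, ys, 2.4, 0)))
  # outputs bounded by the four surrounding node values
  g <- matrix(runif(100), 10)
  xs2 <- 1:10
  px <- runif(40, 1, 10); py <- runif(40, 1, 10)
  v <- resample_bilinear(g, xs2, xs2, px, py)
  for (i in seq_along(px)) {
    ix <- findInterval(px[i], xs2); iy <- findInterval(py[i], xs2)
    ix <- min(ix, 9); iy <- min(iy, 9)
    nodes <- g[ix:(ix + 1), iy:(iy + 1)]
    expect_gte(v[i], min(nodes) - 1e-12)
    expect_lte(v[i], max(nodes) + 1e-12)
  }
})

test_that("per-location random RF orientation is seeded and uniform", {
  n <- 10000
  vals <- array(rep(1:8, each = n), c(n, 8))
  a1 <- assign_random_rf_orientation(vals, seed = 3)
  a2 <- assign_random_rf_orientation(vals, seed = 3)
  expect_identical(a1, a2)
  counts <- tabulate(attr(a1, "rf_orientation_index"), 8)
  # 3-sigma multinomial bound per orientation bin
  expect_true(all(abs(counts - n / 8) < 3 * sqrt(n * (1 / 8) * (7 / 8))))
  # with a condition axis, the same draw applies to every condition
  vals3 <- array(0, c(5, 2, 3))
  for (k in 1:3) vals3[, , k] <- k
  sel <- assign_random_rf_orientation(vals3, seed = 1)
  pick <- attr(sel, "rf_orientation_index")
  expect_equal(sel[, 1], pick)
  expect_equal(sel[, 2], pick)
})

test_that("response resampling propagates transform validity", {
  g <- tiny_grid()
  fields <- array(0, c(g$n_pixels, g$n_pixels, 2))
  m <- grid_mesh(g)
  fields[, , 1] <- m$x; fields[, , 2] <- m$y
  # identity-scaled anchors: anatomical coordinates in the same units
  a <- anchor_set(rbind(c(-20, -20), c(20, -20), c(20, 20), c(-20, 20),
                        c(0, 0), c(10, -5)),
                  rbind(c(-20, -20), c(20, -20), c(20, 20), c(-20, 20),
                        c(0, 0), c(10, -5)))
  tr <- fit_retinotopy(a)
  anat <- anatomical_grid(n = 11, half = 30)
  rs <- resample_responses(fields, g, tr, anat)
  inside <- rs$mapped$valid
  expect_true(any(inside) && any(!inside))
  expect_equal(rs$values[inside, 1], anat$pts[inside, 1], tolerance = 1e-9)
  expect_equal(rs$values[inside, 2], anat$pts[inside, 2], tolerance = 1e-9)
  expect_true(all(is.na(rs$values[!inside, ])))
})
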