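# Separable fast path for bar-stimulus responses.
#
# The DoG kernel factorizes into center and surround products of 1-D
# Gaussians, and every bar frame differs from the display background by a
# rank-1 indicator (bar slab x display extent). The baseline-subtracted
# response of an RF at (xi, yi) is therefore an outer product of 1-D
# Gaussian correlations, exact and far cheaper than 2-D convolution.

# g_sigma correlation of a column/row indicator: out[i] = sum_{j in idx}
# exp(-(coords[j] - coords[i])^2 / (2 sigma^2))
.gauss_corr_idx <- function(coords, idx, sigma) {
  if (!length(idx)) return(numeric(length(coords)))
  d <- outer(coords, coords[idx], "-")
  rowSums(exp(-d^2 / (2 * sigma^2)))
}

# baseline-subtracted response field of DoG RFs (centers at every pixel)
# to one bar frame: vertical bars have their slab on the x axis
.dog_bar_slab_field <- function(grid, sigma_center, sigma_surround, cs_ratio,
                                slab_idx, other_idx, orient) {
  k <- if (cs_ratio > 0) cs_ratio * sigma_center^2 / sigma_surround^2 else 0
  ac <- .gauss_corr_idx(grid$coords, slab_idx, sigma_center)
  bc <- .gauss_corr_idx(grid$coords, other_idx, sigma_center)
  f <- if (orient == "vertical") outer(ac, bc) else outer(bc, ac)
  if (k > 0) {
    as <- .gauss_corr_idx(grid$coords, slab_idx, sigma_surround)
    bs <- .gauss_corr_idx(grid$coords, other_idx, sigma_surround)
    f <- f - k * (if (orient == "vertical") outer(as, bs) else outer(bs, as))
  }
  f
}

# per-frame baseline-subtracted responses of one RF at `center` across a
# bar sweep. The sweep has fixed duration: every position in `spec$positions`
# is one frame. In boundary mode, positions where the bar has disappeared
# past the display edge are blank frames with response 0 (= baseline); this
# is what makes an edge RF see boundary-limited bars for a shorter total
# time than bars sweeping the full display.
.bar_unit_sweep <- function(grid, sigma_center, sigma_surround, cs_ratio,
                            center, spec) {
  k <- if (cs_ratio > 0) cs_ratio * sigma_center^2 / sigma_surround^2 else 0
  x <- grid$coords
  gc1 <- function(idx, c0, s) sum(exp(-(x[idx] - c0)^2 / (2 * s^2)))
  dx <- which(x >= spec$display[1] & x <= spec$display[2])
  dy <- which(x >= spec$display[3] & x <= spec$display[4])
  shown <- if (spec$edge_mode == "boundary")
    spec$positions %in% bar_boundary_positions(spec)
  else rep(TRUE, length(spec$positions))
  axis_idx <- if (spec$orientation == "vertical") dx else dy
  other_idx <- if (spec$orientation == "vertical") dy else dx
  c_axis <- if (spec$orientation == "vertical") center[1] else center[2]
  c_other <- if (spec$orientation == "vertical") center[2] else center[1]
  oc <- gc1(other_idx, c_other, sigma_center)
  os <- if (k > 0) gc1(other_idx, c_other, sigma_surround) else 0
  r <- numeric(length(spec$positions))
  blank <- !shown
  for (i in seq_along(spec$positions)) {
    if (!shown[i]) next
    slab <- axis_idx[abs(x[axis_idx] - spec$positions[i]) <= spec$width / 2]
    if (!length(slab)) { blank[i] <- TRUE; next }
    r[i] <- gc1(slab, c_axis, sigma_center) * oc -
      (if (k > 0) k * gc1(slab, c_axis, sigma_surround) * os else 0)
  }
  list(responses = r,
       meta = data.frame(orientation = rep(spec$orientation,
                                           length(spec$positions)),
                         center = spec$positions, is_blank = blank,
                         stringsAsFactors = FALSE))
}
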