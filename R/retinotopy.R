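#' Anchor set pairing anatomical and visual coordinates
#'
#' A small set of corresponding points used to train the retinotopic
#' transform: anatomical positions in millimetres on the imaging window and
#' their visual-field positions in degrees.
#'
#' @param anat numeric matrix (n x 2) of anatomical coordinates, mm.
#' @param vis numeric matrix (n x 2) of visual coordinates, degrees.
#' @param anat_half,vis_half half-extents of the anatomical window (mm) and
#'   visual window (degrees); defaults 0.83 mm and 40 degrees.
#' @return an object of class `anchor_set`.
#' @export
anchor_set <- function(anat, vis, anat_half = 0.83, vis_half = 40) {
  anat <- as.matrix(anat); vis <- as.matrix(vis)
  stopifnot(ncol(anat) == 2, ncol(vis) == 2, nrow(anat) == nrow(vis),
            nrow(anat) >= 3)
  d <- as.matrix(stats::dist(anat))
  diag(d) <- Inf
  if (min(d) < 1e-9) stop("duplicate anatomical anchor points")
  hull <- grDevices::chull(anat)
  if (length(hull) < 3) stop("anchors are collinear; a 2-D hull is required")
  structure(list(anat = anat, vis = vis, hull = hull,
                 anat_half = anat_half, vis_half = vis_half),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d anchors, anatomical window +-%g mm, visual window +-%g deg\n",
              nrow(x$anat), x$anat_half, x$vis_half))
  invisible(x)
}

#' Default (synthetic) anchor set
#'
#' The published retinotopic alignment exists only as a figure, so the
#' package ships a synthetic approximation built in code: ten anchors whose
#' anatomical-to-visual mapping is a 90-degree rotation (clockwise from
#' visual to anatomical space) composed with a mild radial warp, spanning
#' the +-0.83 mm anatomical and +-40 degree visual windows. It reproduces
#' the qualitative rotation-plus-distortion of the published alignment and
#' is *not* derived from data.
#'
#' @return an [anchor_set()].
#' @export
default_anchors <- function() {
  g <- 0.62
  anat <- rbind(c(-g, -g), c(0, -g), c(g, -g),
                c(-g, 0), c(g, 0),
                c(-g, g), c(0, g), c(g, g),
                c(0.28, 0.30), c(-0.25, -0.33))
  # anatomical -> visual: 90 deg counterclockwise rotation, scaling,
  # plus a gentle barrel warp
  s <- 40 / 0.83
  base <- cbind(-anat[, 2], anat[, 1]) * s
  r2 <- (anat[, 1]^2 + anat[, 2]^2) / 0.83^2
  vis <- base * (1 - 0.12 * r2)
  anchor_set(anat, vis)
}

#' Read / write anchor sets as CSV
#'
#' CSV columns: `anat_x_mm`, `anat_y_mm`, `vis_x_deg`, `vis_y_deg`.
#'
#' @param path file path.
#' @param anchors an [anchor_set()] (for writing).
#' @return [read_anchors()] returns an [anchor_set()].
#' @export
read_anchors <- function(path) {
  d <- utils::read.csv(path)
  need <- c("anat_x_mm", "anat_y_mm", "vis_x_deg", "vis_y_deg")
  if (!all(need %in% names(d)))
    stop("anchor CSV must contain columns: ", paste(need, collapse = ", "))
  anchor_set(as.matrix(d[, c("anat_x_mm", "anat_y_mm")]),
             as.matrix(d[, c("vis_x_deg", "vis_y_deg")]))
}

#' @rdname read_anchors
#' @export
write_anchors <- function(anchors, path) {
  stopifnot(inherits(anchors, "anchor_set"))
  utils::write.csv(data.frame(anat_x_mm = anchors$anat[, 1],
                              anat_y_mm = anchors$anat[, 2],
                              vis_x_deg = anchors$vis[, 1],
                              vis_y_deg = anchors$vis[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

## ---- Sibson natural-neighbor machinery -------------------------------
## Convex polygons are m x 2 matrices of vertices in order; clipping is by
## successive half-planes (Sutherland-Hodgman restricted to convex input).

.clip_halfplane <- function(poly, nx, ny, d) {
  # keep points with nx*x + ny*y <= d
  m <- nrow(poly)
  if (m == 0) return(poly)
  v <- poly[, 1] * nx + poly[, 2] * ny - d
  inside <- v <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(0, m + 2, 2)
  k <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if (inside[i]) { k <- k + 1; out[k, ] <- poly[i, ] }
    if (inside[i] != inside[j]) {
      t <- v[i] / (v[i] - v[j])
      k <- k + 1
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

.poly_area <- function(poly) {
  m <- nrow(poly)
  if (m < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:m, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# bisector half-plane of q against p: points closer to q than p
.bisector <- function(q, p) {
  nx <- p[1] - q[1]; ny <- p[2] - q[2]
  mid <- (p + q) / 2
  c(nx, ny, nx * mid[1] + ny * mid[2])
}

# Voronoi cell of site i within a large bounding box
.voronoi_cell <- function(pts, i, box) {
  poly <- box
  for (j in seq_len(nrow(pts))) {
    if (j == i) next
    b <- .bisector(pts[i, ], pts[j, ])
    poly <- .clip_halfplane(poly, b[1], b[2], b[3])
    if (nrow(poly) < 3) break
  }
  poly
}

# point-in-convex-polygon: all edge cross products share a sign (or zero)
.in_hull <- function(hull_pts, q) {
  m <- nrow(hull_pts)
  signs <- numeric(m)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    signs[i] <- (hull_pts[j, 1] - hull_pts[i, 1]) * (q[2] - hull_pts[i, 2]) -
                (hull_pts[j, 2] - hull_pts[i, 2]) * (q[1] - hull_pts[i, 1])
  }
  all(signs >= -1e-12) || all(signs <= 1e-12)
}

#' Fit the retinotopic transform from an anchor set
#'
#' Trains two scattered-data interpolants (anatomical to visual-x and
#' anatomical to visual-y) with natural-neighbor (Sibson) semantics: the
#' prediction at a query is the Voronoi-area-stealing weighted average of
#' the anchor targets. The transform is exact at the anchors, has linear
#' precision, and is continuous inside the anchor hull; queries outside the
#' hull are flagged invalid (no extrapolation).
#'
#' @param anchors an [anchor_set()].
#' @return an object of class `retino_transform` with a [predict()] method.
#' @export
fit_retinotopy <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  pts <- anchors$anat
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  ctr <- colMeans(pts)
  half <- span * 500
  box <- rbind(c(ctr[1] - half, ctr[2] - half), c(ctr[1] + half, ctr[2] - half),
               c(ctr[1] + half, ctr[2] + half), c(ctr[1] - half, ctr[2] + half))
  cells <- lapply(seq_len(nrow(pts)), .voronoi_cell, pts = pts, box = box)
  structure(list(anchors = anchors, cells = cells, box = box,
                 hull_pts = pts[anchors$hull, , drop = FALSE],
                 tol = 1e-9 * span),
            class = "retino_transform")
}

#' @export
print.retino_transform <- function(x, ...) {
  cat(sprintf("retino_transform: natural-neighbor map from %d anchors (anatomical mm -> visual deg)\n",
              nrow(x$anchors$anat)))
  invisible(x)
}

# Sibson weights of the anchors for one query point (assumed inside hull)
.sibson_weights <- function(object, q) {
  pts <- object$anchors$anat
  n <- nrow(pts)
  d2 <- (pts[, 1] - q[1])^2 + (pts[, 2] - q[2])^2
  hit <- which(d2 < object$tol^2)
  if (length(hit)) {
    w <- numeric(n); w[hit[1]] <- 1
    return(w)
  }
  bis <- lapply(seq_len(n), function(j) .bisector(q, pts[j, ]))
  w <- numeric(n)
  for (i in seq_len(n)) {
    poly <- object$cells[[i]]
    for (j in seq_len(n)) {
      b <- bis[[j]]
      poly <- .clip_halfplane(poly, b[1], b[2], b[3])
      if (nrow(poly) < 3) break
    }
    w[i] <- .poly_area(poly)
  }
  s <- sum(w)
  if (s <= 0) return(rep(NA_real_, n))
  w / s
}

#' Map anatomical coordinates to visual coordinates
#'
#' @param object a fitted `retino_transform`.
#' @param newdata matrix or data.frame (n x 2) of anatomical coordinates, mm.
#' @param ... unused.
#' @return data.frame with `x_deg`, `y_deg` and logical `valid` (FALSE for
#'   queries outside the anchor hull; their coordinates are NA).
#' @export
predict.retino_transform <- function(object, newdata, ...) {
  pts <- as.matrix(newdata)
  stopifnot(ncol(pts) == 2)
  vis <- object$anchors$vis
  out <- matrix(NA_real_, nrow(pts), 2)
  valid <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    q <- pts[i, ]
    if (!.in_hull(object$hull_pts, q)) next
    w <- .sibson_weights(object, q)
    if (anyNA(w)) next
    out[i, ] <- c(sum(w * vis[, 1]), sum(w * vis[, 2]))
    valid[i] <- TRUE
  }
  data.frame(x_deg = out[, 1], y_deg = out[, 2], valid = valid)
}

#' @rdname predict.retino_transform
#' @param transform a fitted `retino_transform`.
#' @param pts anatomical coordinates (n x 2).
#' @export
map_coordinates <- function(transform, pts) {
  predict(transform, pts)
}

#' Evenly spaced anatomical query grid
#'
#' @param n samples per side (default 241).
#' @param half half-extent, mm (default 0.83).
#' @return list with `coords`, and `pts` (n^2 x 2 matrix, x varying fastest).
#' @export
anatomical_grid <- function(n = 241, half = 0.83) {
  coords <- seq(-half, half, length.out = n)
  pts <- cbind(rep(coords, times = n), rep(coords, each = n))
  list(coords = coords, pts = pts, n = n, half = half)
}

#' Bilinear resampling of gridded responses at scattered targets
#'
#' Each target is estimated as the axis-distance-weighted average of the
#' four surrounding grid nodes; targets outside the grid extent (fewer than
#' four surrounding nodes) are excluded and return NA. Exact on affine
#' fields, and bounded by the four source node values.
#'
#' @param values matrix `[ix, iy]` on the grid defined by `xs`, `ys`, or a
#'   3-D array `[ix, iy, k]` resampled per slice.
#' @param xs,ys increasing grid node coordinates.
#' @param tx,ty target coordinates.
#' @return vector (or matrix, targets x slices) of resampled values.
#' @export
resample_bilinear <- function(values, xs, ys, tx, ty) {
  stopifnot(length(tx) == length(ty))
  dims <- dim(values)
  is3d <- length(dims) == 3
  nx <- length(xs); ny <- length(ys)
  ix <- findInterval(tx, xs)
  iy <- findInterval(ty, ys)
  ok <- tx >= xs[1] & tx <= xs[nx] & ty >= ys[1] & ty <= ys[ny]
  ix[ix >= nx] <- nx - 1L
  iy[iy >= ny] <- ny - 1L
  ix[ix < 1] <- 1L
  iy[iy < 1] <- 1L
  ux <- (tx - xs[ix]) / (xs[ix + 1] - xs[ix])
  uy <- (ty - ys[iy]) / (ys[iy + 1] - ys[iy])
  w00 <- (1 - ux) * (1 - uy); w10 <- ux * (1 - uy)
  w01 <- (1 - ux) * uy;       w11 <- ux * uy
  get <- function(m) {
    v <- w00 * m[cbind(ix, iy)] + w10 * m[cbind(ix + 1L, iy)] +
         w01 * m[cbind(ix, iy + 1L)] + w11 * m[cbind(ix + 1L, iy + 1L)]
    v[!ok] <- NA_real_
    v
  }
  if (!is3d) return(get(values))
  out <- vapply(seq_len(dims[3]), function(k) get(values[, , k]),
                numeric(length(tx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(tx))
  out
}

#' Resample per-condition response fields onto anatomical coordinates
#'
#' Maps an anatomical query grid through the retinotopic transform and
#' bilinearly resamples visual-coordinate response fields at the mapped
#' positions. Queries outside the anchor hull or outside the visual grid
#' carry NA.
#'
#' @param fields matrix or 3-D array of responses on the visual grid
#'   (`[ix, iy]` or `[ix, iy, condition]`).
#' @param grid the visual [pixel_grid()].
#' @param transform a fitted `retino_transform`.
#' @param anat an [anatomical_grid()].
#' @return list with `values` (targets x conditions matrix), `mapped` (the
#'   mapped visual coordinates with validity), and `anat`.
#' @export
resample_responses <- function(fields, grid, transform, anat) {
  mp <- predict(transform, anat$pts)
  vals <- resample_bilinear(fields, grid$coords, grid$coords,
                            mp$x_deg, mp$y_deg)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  vals[!mp$valid, ] <- NA_real_
  list(values = vals, mapped = mp, anat = anat)
}

#' Keep one random RF orientation per location
#'
#' For response arrays with an RF-orientation axis, draws one orientation
#' uniformly at random per location (seeded) and retains that orientation's
#' responses across all stimulus conditions at that location.
#'
#' @param values array `[location, condition, rf_orientation]` or matrix
#'   `[location, rf_orientation]`.
#' @param seed integer seed.
#' @return array without the RF-orientation axis, plus attribute
#'   `"rf_orientation_index"` recording the draw per location.
#' @export
assign_random_rf_orientation <- function(values, seed = 1) {
  dims <- dim(values)
  stopifnot(!is.null(dims))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nk <- dims[length(dims)]
  nloc <- dims[1]
  pick <- sample.int(nk, nloc, replace = TRUE)
  if (length(dims) == 2) {
    out <- values[cbind(seq_len(nloc), pick)]
  } else if (length(dims) == 3) {
    out <- matrix(0, nloc, dims[2])
    for (k in seq_len(nk)) {
      sel <- pick == k
      out[sel, ] <- values[sel, , k]
    }
  } else stop("values must have 2 or 3 dimensions")
  attr(out, "rf_orientation_index") <- pick
  out
}
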