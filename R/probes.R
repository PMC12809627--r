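#' Canonical edge probes for an aperture
#'
#' Reproducible probe locations standing in for figure-annotated positions:
#' eight points at 45-degree polar steps around the aperture boundary (for
#' squares these are the four edge midpoints plus the four corners; the
#' diamond is the square rotated 45 degrees). Each probe carries the local
#' outward edge-normal orientation (degrees, mod 180).
#'
#' Probes can be inset along the inward normal. For center-surround units
#' the informative, radially tuned band lies about one surround SD inside
#' the boundary (a unit exactly on the boundary has half its RF off the
#' stimulus and reflects edge-parallel energy), so spatial-frequency
#' classification uses `inset = sigma_surround` by default in the
#' experiment drivers; the inset is capped at half the aperture in-radius.
#'
#' @param ap an [aperture()] (`circle`, `square` or `diamond`).
#' @param inset distance to move each probe inward from the boundary,
#'   degrees (default 0).
#' @return data.frame with `x`, `y`, `normal` (outward edge-normal
#'   orientation, degrees mod 180) and `angle` (polar angle of the probe).
#' @export
edge_probes <- function(ap, inset = 0) {
  stopifnot(inherits(ap, "aperture"))
  ang <- seq(0, 315, by = 45)
  rad <- ang * pi / 180
  if (ap$shape == "circle") {
    inset <- min(inset, ap$radius / 2)
    r <- ap$radius - inset
    d <- data.frame(x = r * cos(rad), y = r * sin(rad), normal = ang %% 180,
                    angle = ang)
  } else if (ap$shape %in% c("square", "diamond")) {
    h <- ap$side / 2
    inset <- min(inset, h / 2)
    # boundary points of the square at the 8 polar angles
    bx <- c(h, h, 0, -h, -h, -h, 0, h)
    by <- c(0, h, h, h, 0, -h, -h, -h)
    nx <- c(1, 1, 0, -1, -1, -1, 0, 1) / c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
    ny <- c(0, 1, 1, 1, 0, -1, -1, -1) / c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
    d <- data.frame(x = bx - inset * nx, y = by - inset * ny,
                    normal = (atan2(ny, nx) * 180 / pi) %% 180, angle = ang)
    if (ap$shape == "diamond") {
      rot <- pi / 4
      xr <- d$x * cos(rot) - d$y * sin(rot)
      yr <- d$x * sin(rot) + d$y * cos(rot)
      d$x <- xr; d$y <- yr
      d$normal <- (d$normal + 45) %% 180
      d$angle <- (d$angle + 45) %% 360
    }
  } else {
    stop("edge probes are defined for circle, square and diamond apertures")
  }
  d
}

#' Radial / anti-radial classification of a preferred orientation
#'
#' A preference within 45 degrees of the local edge-normal orientation is
#' radial (pointing toward the stimulus center); otherwise it is
#' anti-radial (parallel to the edge). The 45-degree boundary counts as
#' radial.
#'
#' @param pref preferred orientation(s), degrees.
#' @param normal edge-normal orientation(s), degrees.
#' @return character vector `"radial"` / `"anti-radial"`.
#' @export
classify_radial <- function(pref, normal) {
  d <- abs((pref - normal) %% 180)
  d <- pmin(d, 180 - d)
  ifelse(d <= 45, "radial", "anti-radial")
}

# circular distance between two orientations (degrees, mod 180)
orientation_distance <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# mean resultant and circular mean of orientations (doubled-angle space)
orientation_resultant <- function(pref) {
  z <- mean(exp(2i * pref * pi / 180))
  list(mean = (Arg(z) / 2 * 180 / pi) %% 180, length = Mod(z))
}

# alignment of preferences with edge normals: mean cos(2 * delta), 1 =
# perfectly radial, -1 = perfectly anti-radial
edge_alignment <- function(pref, normal) {
  mean(cos(2 * (pref - normal) * pi / 180))
}
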