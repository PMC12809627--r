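#' Gaussian smoothing specification for population pooling
#'
#' Population responses are emulated by smoothing single-unit responses on
#' the anatomical grid with a circular Gaussian kernel. The default kernel
#' SD is 0.0083 mm (about 0.44 degrees of visual space under the default
#' retinotopic scaling).
#'
#' @param kernel_sd kernel standard deviation, in the units of the grid the
#'   map lives on (mm for anatomical maps, degrees for visual maps).
#' @param truncate kernel truncation radius in multiples of the SD
#'   (default 4; the discretized kernel is renormalized to sum to 1).
#' @return an object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(kernel_sd = 0.0083, truncate = 4) {
  stopifnot(kernel_sd > 0, truncate > 0)
  structure(list(kernel_sd = kernel_sd, truncate = truncate),
            class = "smoothing_spec")
}

#' Smooth a response map with a truncated Gaussian kernel
#'
#' Separable convolution with a normalized, truncated Gaussian. Missing
#' values (NA) are handled by mask-aware renormalization: at mask borders
#' the kernel weights are renormalized over the valid pixels, and missing
#' cells remain missing. A constant map is returned unchanged (up to
#' floating point), and a sub-pixel kernel reduces to the identity.
#'
#' @param m matrix on a regular grid (NAs mark missing cells).
#' @param spacing grid spacing, same units as `kernel_sd`.
#' @param spec a [smoothing_spec()] (or give `kernel_sd` directly).
#' @param kernel_sd,truncate alternative to `spec`.
#' @return smoothed matrix, same size, NAs preserved.
#' @export
smooth_map <- function(m, spacing, spec = NULL, kernel_sd = 0.0083,
                       truncate = 4) {
  stopifnot(is.matrix(m), spacing > 0)
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "smoothing_spec"))
    kernel_sd <- spec$kernel_sd; truncate <- spec$truncate
  }
  sd_px <- kernel_sd / spacing
  r <- ceiling(truncate * sd_px)
  if (r < 1) return(m)
  if (2 * r + 1 > 4 * max(dim(m)))
    stop("smoothing kernel is far wider than the grid")
  k <- stats::dnorm(-r:r, sd = sd_px)
  k <- k / sum(k)
  valid <- !is.na(m)
  m0 <- m; m0[!valid] <- 0
  num <- .sepconv(m0, k)
  den <- .sepconv(matrix(as.numeric(valid), nrow(m)), k)
  out <- num / den
  out[!valid] <- NA_real_
  out
}

# separable 2-D convolution with zero padding beyond the matrix edges
.sepconv <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src <- max(1L, 1L - o):min(n1, n1 - o)
    dst <- src + o
    out[dst, ] <- out[dst, ] + w * m[src, ]
  }
  out2 <- matrix(0, n1, n2)
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src <- max(1L, 1L - o):min(n2, n2 - o)
    dst <- src + o
    out2[, dst] <- out2[, dst] + w * out[, src]
  }
  out2
}
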