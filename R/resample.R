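# Separable linear filters along array axes. Upsampling (cubic-convolution /
# linear / nearest) and Gaussian smoothing are both expressed as an
# (m_out x m_in) weight matrix applied along each axis in turn.

apply_along_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  out <- W %*% m
  dout <- d; dout[axis] <- nrow(W)
  a2 <- array(out, dim = dout[perm])
  aperm(a2, order(perm))
}

# Catmull-Rom cubic convolution weights (a = -0.5) for fractional offset t.
.cubic_weights <- function(t) {
  c(-0.5 * t^3 + t^2 - 0.5 * t,
    1.5 * t^3 - 2.5 * t^2 + 1,
    -1.5 * t^3 + 2 * t^2 + 0.5 * t,
    0.5 * t^3 - 0.5 * t^2)
}

# Interpolation matrix taking n input samples to n*factor output samples.
# Output index j (0-based) samples input coordinate j/factor, so original
# lattice points are hit exactly; indices beyond the ends are clamped
# (edge replication).
.upsample_matrix <- function(n, factor, method) {
  n_out <- n * factor
  W <- matrix(0, n_out, n)
  for (j in seq_len(n_out)) {
    x <- (j - 1) / factor
    base <- floor(x)
    t <- x - base
    if (method == "nearest") {
      idx <- min(max(round(x), 0), n - 1)
      W[j, idx + 1] <- 1
    } else if (method == "linear") {
      i0 <- min(max(base, 0), n - 1)
      i1 <- min(max(base + 1, 0), n - 1)
      W[j, i0 + 1] <- W[j, i0 + 1] + (1 - t)
      W[j, i1 + 1] <- W[j, i1 + 1] + t
    } else {
      w <- .cubic_weights(t)
      for (k in 0:3) {
        idx <- min(max(base - 1 + k, 0), n - 1)
        W[j, idx + 1] <- W[j, idx + 1] + w[k + 1]
      }
    }
  }
  W
}

#' Upsample a volume by an integer factor
#'
#' Increases grid resolution by `factor` along every axis, the step applied
#' to the SUVR and tissue-probability volumes before histogram construction
#' to reduce binning artifacts. Cubic-convolution (bicubic per-plane, applied
#' separably in 3-D) is the default; probability volumes are clipped back to
#' \[0, 1\] after interpolation, and label volumes always use
#' nearest-neighbour so labels are never invented.
#'
#' @param volume a [scalar_volume].
#' @param factor positive integer upsampling factor per axis.
#' @param method `"cubic"` (default), `"linear"` or `"nearest"`.
#' @return A [scalar_volume] with each dimension multiplied by `factor`,
#'   `voxel_size_mm` divided by `factor`, and an affine preserving world
#'   coordinates (the index-origin world position is unchanged).
#' @export
resample_upsample <- function(volume, factor = 2L,
                              method = c("cubic", "linear", "nearest")) {
  method <- match.arg(method)
  if (!inherits(volume, "scalar_volume"))
    stop("`volume` must be a scalar_volume", call. = FALSE)
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      abs(factor - round(factor)) > 1e-9)
    stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(volume)
  if (volume$kind == "label") method <- "nearest"
  d <- dim(volume$data)
  out <- volume$data
  for (ax in 1:3) {
    W <- .upsample_matrix(d[ax], factor, method)
    out <- apply_along_axis(out, W, ax)
  }
  if (volume$kind == "probability") out <- pmin(pmax(out, 0), 1)
  S <- diag(c(rep(1 / factor, 3), 1))
  scalar_volume(out, voxel_size_mm = volume$voxel_size_mm / factor,
                affine = volume$affine %*% S, kind = volume$kind)
}

# Row-normalized truncated Gaussian convolution matrix (n x n) for one axis.
.gaussian_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - r):min(n, i + r)
    w <- exp(-0.5 * ((idx - i) / sigma_vox)^2)
    W[i, idx] <- w / sum(w)
  }
  W
}

#' Gaussian smoothing at a physical FWHM
#'
#' Separable 3-D Gaussian filter, parameterized by full width at half
#' maximum in mm (the convention used to describe PET reconstruction
#' resolution). Kernel truncated at 4 sigma and renormalized at the edges.
#'
#' @param volume a [scalar_volume].
#' @param fwhm_mm scalar or length-3 FWHM in mm; 0 is a no-op.
#' @return Smoothed [scalar_volume] on the same grid.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  if (!inherits(volume, "scalar_volume"))
    stop("`volume` must be a scalar_volume", call. = FALSE)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  if (any(fwhm_mm < 0)) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (all(fwhm_mm == 0)) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / volume$voxel_size_mm
  out <- volume$data
  d <- dim(out)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      out <- apply_along_axis(out, .gaussian_matrix(d[ax], sigma_vox[ax]), ax)
  }
  scalar_volume(out, voxel_size_mm = volume$voxel_size_mm,
                affine = volume$affine, kind = volume$kind)
}
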