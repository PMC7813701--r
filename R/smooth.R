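#' Convert Gaussian kernel FWHM to standard deviation
#'
#' Smoothing kernels are specified by their full width at half maximum
#' (FWHM), the convention of VBM software; the underlying Gaussian sigma is
#' `FWHM / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm kernel FWHM in mm, `>= 0`.
#' @return sigma in mm.
#' @examples
#' fwhmToSigma(8)      # 3.397 mm, the usual 8-mm VBM kernel
#' fwhmToSigma(2.35482)  # ~1
#' @export
fwhmToSigma <- function(fwhm) {
  if (any(fwhm < 0)) argumentError("fwhm must be >= 0 (got %g)", min(fwhm))
  fwhm / (2 * sqrt(2 * log(2)))
}

#' @rdname fwhmToSigma
#' @param sigma Gaussian standard deviation in mm.
#' @export
sigmaToFwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# 1D truncated Gaussian kernel in voxel units, normalized to sum 1.
# Truncation at 4 sigma.
#' @noRd
gaussKernel1d <- function(sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

# Convolve along axis `ax` with kernel `k`, zero padding at the boundary.
# Implemented as a banded-matrix product after rotating the axis first.
#' @noRd
convolveAxis <- function(arr, ax, k) {
  d <- dim(arr)
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[j]
  }
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = n)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable 3D Gaussian smoothing with a kernel specified in mm FWHM.
#' Anisotropic voxels are handled with a per-axis sigma in voxel units
#' (`sigma_mm / voxel_size`); the kernel is truncated at 4 sigma and
#' normalized so a constant image is preserved away from boundaries;
#' boundary handling is zero padding. All arithmetic is double precision.
#'
#' @param vol a [BrainVolume-class] or [GMMap-class].
#' @param fwhm kernel FWHM in mm (`0` returns the input unchanged).
#' @return Same class as `vol`, same grid; a `GMMap` has its
#'   `smoothedFWHM` field updated.
#' @export
gaussianSmooth <- function(vol, fwhm) {
  if (length(fwhm) != 1L || is.na(fwhm) || fwhm < 0)
    argumentError("fwhm must be a single number >= 0")
  if (is(vol, "GMMap")) {
    sm <- gaussianSmooth(vol@volume, fwhm)
    return(new("GMMap", volume = sm, space = vol@space,
               modulated = vol@modulated, smoothedFWHM = fwhm))
  }
  if (fwhm == 0) return(vol)
  vs <- voxelSize(vol)
  if (any(vs <= 0)) geometryError("non-positive voxel sizes")
  sigmaVox <- fwhmToSigma(fwhm) / vs
  out <- vol@data
  for (ax in 1:3)
    if (sigmaVox[ax] > 0) out <- convolveAxis(out, ax, gaussKernel1d(sigmaVox[ax]))
  withData(vol, out)
}
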