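#' Resample a volume onto a target grid through an affine transform
#'
#' Pull-style resampling: each target voxel center is mapped to world
#' coordinates via the target affine, pulled back through the inverse of
#' `transform` (which maps the *source* volume's world coordinates to the
#' *target* world), and the source volume is interpolated there. Voxels
#' mapping outside the source field of view take `fill`.
#'
#' When `transform` is the identity and the target grid equals the source
#' grid the input is returned unchanged (exact, no interpolation).
#'
#' @param vol source [BrainVolume-class].
#' @param transform an [AffineTransform-class] mapping source world to
#'   target world (default identity).
#' @param targetDim,targetAffine grid spec of the output (default: the
#'   source grid).
#' @param interp `"linear"` (trilinear) or `"nearest"`.
#' @param fill value for out-of-field voxels.
#' @return A [BrainVolume-class] on the target grid.
#' @export
resampleVolume <- function(vol, transform = identityTransform(),
                           targetDim = gridDim(vol),
                           targetAffine = volAffine(vol),
                           interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  M <- xfmMatrix(transform)
  sameTarget <- all(targetDim == gridDim(vol)) &&
    max(abs(targetAffine - volAffine(vol))) < 1e-12
  if (sameTarget && max(abs(M - diag(4))) < 1e-12) return(vol)

  # target voxel index -> source continuous voxel index, one 4x4 product
  m <- solve(volAffine(vol)) %*% solve(M) %*% targetAffine
  d <- targetDim
  i <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  j <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  cx <- m[1, 1] * i + m[1, 2] * j + m[1, 3] * k + m[1, 4]
  cy <- m[2, 1] * i + m[2, 2] * j + m[2, 3] * k + m[2, 4]
  cz <- m[3, 1] * i + m[3, 2] * j + m[3, 3] * k + m[3, 4]

  src <- vol@data
  sd3 <- dim(src)
  if (interp == "nearest") {
    xi <- floor(cx + 0.5); yi <- floor(cy + 0.5); zi <- floor(cz + 0.5)
    ok <- xi >= 0 & xi < sd3[1] & yi >= 0 & yi < sd3[2] & zi >= 0 & zi < sd3[3]
    out <- rep(fill, length(cx))
    lin <- xi[ok] + sd3[1] * (yi[ok] + sd3[2] * zi[ok]) + 1
    out[ok] <- src[lin]
  } else {
    x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    out <- numeric(length(cx))
    corner <- function(dx, dy, dz) {
      xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
      ok <- xi >= 0 & xi < sd3[1] & yi >= 0 & yi < sd3[2] & zi >= 0 & zi < sd3[3]
      v <- rep(fill, length(xi))
      lin <- xi[ok] + sd3[1] * (yi[ok] + sd3[2] * zi[ok]) + 1
      v[ok] <- src[lin]
      v
    }
    wx <- list(1 - fx, fx); wy <- list(1 - fy, fy); wz <- list(1 - fz, fz)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      out <- out + wx[[dx + 1]] * wy[[dy + 1]] * wz[[dz + 1]] * corner(dx, dy, dz)
  }
  dim(out) <- d
  brainVolume(out, targetAffine)
}
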