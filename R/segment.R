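# Tissue segmentation: brain masking + Gaussian-mixture EM on intensities.

# --- small 3D binary morphology helpers (6-connectivity) ------------------

# shift logical/numeric array by one voxel along axis, zero fill
#' @noRd
shift1 <- function(a, ax, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  src <- idx
  if (dir > 0) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
  else { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @noRd
dilate6 <- function(a) {
  out <- a
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out | shift1(a, ax, dir)
  out
}

#' @noRd
erode6 <- function(a) !dilate6(!a)

#' @noRd
closing6 <- function(a, iter = 1L) {
  for (i in seq_len(iter)) a <- dilate6(a)
  for (i in seq_len(iter)) a <- erode6(a)
  a
}

# largest 6-connected component of a logical array (frontier-growing BFS)
#' @noRd
largestComponent <- function(fg) {
  visited <- array(FALSE, dim(fg))
  best <- NULL
  bestN <- 0L
  remaining <- fg & !visited
  while (any(remaining)) {
    seedIdx <- which(remaining)[1]
    comp <- array(FALSE, dim(fg))
    comp[seedIdx] <- TRUE
    frontier <- comp
    repeat {
      grow <- dilate6(frontier) & fg & !comp
      if (!any(grow)) break
      comp <- comp | grow
      frontier <- grow
    }
    n <- sum(comp)
    if (n > bestN) { best <- comp; bestN <- n }
    visited <- visited | comp
    remaining <- fg & !visited
  }
  if (is.null(best)) array(FALSE, dim(fg)) else best
}

# Otsu threshold (maximal between-class variance on a 256-bin histogram)
#' @noRd
otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  kstar <- which.max(sigmaB)
  rng[1] + kstar / nbins * diff(rng)
}

#' Foreground brain mask from a T1 volume
#'
#' Otsu intensity threshold, largest 6-connected component, then one
#' morphological closing pass — enough to strip the empty background of a
#' head image without external tools.
#'
#' @param t1 a [BrainVolume-class].
#' @param closingIter closing iterations (dilate then erode), default 1.
#' @param dilateMM final dilation in mm (default 0). A generous mask
#'   (e.g. dilated by the smoothing kernel FWHM) suits the alignment QC,
#'   where findings smoothed beyond the tissue edge are still "on brain".
#' @return A binary [BrainVolume-class] (1 = brain/head foreground).
#' @export
brainMask <- function(t1, closingIter = 1L, dilateMM = 0) {
  thr <- otsuThreshold(as.vector(t1@data))
  fg <- t1@data > thr
  if (!any(fg)) dataError("brain mask is empty (flat image?)")
  fg <- largestComponent(fg)
  fg <- closing6(fg, closingIter)
  if (dilateMM > 0)
    for (i in seq_len(ceiling(dilateMM / min(voxelSize(t1))))) fg <- dilate6(fg)
  withData(t1, fg * 1)
}

# --- EM mixture segmentation ----------------------------------------------

#' Gray matter segmentation by Gaussian-mixture EM
#'
#' Fits a K-component Gaussian mixture to the T1 intensities inside the
#' brain mask by expectation-maximization and returns the posterior of the
#' middle-intensity class — the gray-matter analog in a CSF/GM/WM intensity
#' ordering — as a subject-space probability map. Initialization is by
#' intensity quantiles (deterministic); `seed` only adds optional jitter to
#' the initial means.
#'
#' @param t1 a [BrainVolume-class].
#' @param mask binary [BrainVolume-class]; default [brainMask()] of `t1`.
#' @param nClasses number of tissue classes (default 3).
#' @param maxIter,tol EM iteration budget and log-likelihood tolerance.
#' @param seed optional; jitters initial means by up to 1% of the intensity
#'   range (deterministic given the seed). `NULL` = no jitter.
#' @return A [GMMap-class] (subject space, unmodulated, unsmoothed) whose
#'   `"model"` attribute holds the fitted [SegmentationModel-class].
#' @export
segmentGM <- function(t1, mask = NULL, nClasses = 3L, maxIter = 300L,
                      tol = 1e-6, seed = NULL) {
  if (is.null(mask)) mask <- brainMask(t1)
  assertSameGrid(t1, mask, "t1 and mask")
  inMask <- mask@data > 0.5
  if (!any(inMask)) argumentError("mask is empty")
  x <- as.vector(t1@data[inMask])
  if (any(!is.finite(x))) argumentError("non-finite intensities inside mask")
  if (length(unique(x)) < nClasses)
    voxnormStop("voxnorm_degenerate_fit",
                "fewer than %d distinct intensities inside the mask", nClasses)

  rngX <- diff(range(x))
  sdFloor <- max(1e-12, 1e-3 * rngX)
  qs <- seq(1, 2 * nClasses - 1, by = 2) / (2 * nClasses)
  means <- as.numeric(quantile(x, qs, names = FALSE))
  if (!is.null(seed))
    means <- withSeed(seed, function()
      means + runif(nClasses, -0.01, 0.01) * rngX)
  sds <- rep(max(sd(x) / nClasses, sdFloor), nClasses)
  w <- rep(1 / nClasses, nClasses)

  n <- length(x)
  llTrace <- numeric(0)
  converged <- FALSE
  resp <- matrix(0, n, nClasses)
  for (it in seq_len(maxIter)) {
    for (kk in seq_len(nClasses))
      resp[, kk] <- w[kk] * dnorm(x, means[kk], sds[kk])
    rs <- rowSums(resp)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    resp <- resp / rs
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    means <- colSums(resp * x) / nk
    sds <- sqrt(pmax(colSums(resp * (x - rep(means, each = n))^2) / nk,
                     sdFloor^2))
    w <- nk / n
    llTrace <- c(llTrace, ll)
    if (it > 1 && abs(ll - llTrace[it - 1]) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations; returning best-so-far fit",
                    maxIter))

  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; w <- w[ord] / sum(w)
  gmClass <- ceiling(nClasses / 2) + (nClasses %% 2 == 0)  # middle class
  dens <- sapply(seq_len(nClasses), function(kk)
    w[kk] * dnorm(x, means[kk], sds[kk]))
  post <- dens[, gmClass] / pmax(rowSums(dens), 1e-300)

  out <- array(0, gridDim(t1))
  out[inMask] <- post
  model <- new("SegmentationModel", means = means, sds = sds, weights = w,
               logLik = llTrace, converged = converged)
  gm <- new("GMMap", volume = withData(t1, out), space = "subject",
            modulated = FALSE, smoothedFWHM = NA_real_)
  attr(gm, "model") <- model
  gm
}

setMethod("show", "SegmentationModel", function(object) {
  cat(sprintf("SegmentationModel  %d classes, %sconverged (%d EM iterations)\n",
              length(object@means), if (object@converged) "" else "NOT ",
              length(object@logLik)))
  print(round(rbind(mean = object@means, sd = object@sds,
                    weight = object@weights), 4))
})
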