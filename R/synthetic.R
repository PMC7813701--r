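# Synthetic phantom cohort: shell "brains" with programmed aging, sex
# offset, voxel noise and injectable focal atrophy.

#' Construct a phantom specification
#'
#' Defaults describe the package's reference phantom: a 32^3 grid of 4-mm
#' voxels holding a spherical-shell brain (WM core inside 30 mm, GM ribbon
#' 30-50 mm, CSF rim to 54 mm, logistic boundaries of 3 mm), baseline GM
#' amplitude 0.8, GM declining 0.3%/year past age 18, a +0.02 offset for
#' sex "M", voxel noise SD 0.03 on the GM map, and T1 tissue intensities
#' bg/csf/gm/wm = 0.05/0.25/0.55/0.85 with noise SD 0.02.
#'
#' @param dim,voxelSize grid shape and voxel size (mm).
#' @param gmPeak,rWM,rGM,rBrain,edgeWidth ribbon geometry, see
#'   [PhantomSpec-class].
#' @param ageSlope,sexOffset,noiseSD aging model parameters.
#' @param t1Means,t1NoiseSD T1 rendering parameters.
#' @param refAge baseline age (years).
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(32L, 32L, 32L), voxelSize = c(4, 4, 4),
                        gmPeak = 0.8, rWM = 30, rGM = 50, rBrain = 54,
                        edgeWidth = 3, ageSlope = 0.003, sexOffset = 0.02,
                        noiseSD = 0.03,
                        t1Means = c(bg = 0.05, csf = 0.25, gm = 0.55, wm = 0.85),
                        t1NoiseSD = 0.02, refAge = 18) {
  new("PhantomSpec", dim = as.integer(dim), voxelSize = voxelSize,
      gmPeak = gmPeak, rWM = rWM, rGM = rGM, rBrain = rBrain,
      edgeWidth = edgeWidth, ageSlope = ageSlope, sexOffset = sexOffset,
      noiseSD = noiseSD, t1Means = t1Means, t1NoiseSD = t1NoiseSD,
      refAge = refAge)
}

#' @noRd
phantomAffine <- function(spec) {
  A <- diag(c(spec@voxelSize, 1))
  A[1:3, 4] <- -spec@voxelSize * (spec@dim - 1) / 2  # world origin at center
  A
}

# radial distance from the grid center for every voxel, mm
#' @noRd
phantomRadius <- function(spec) {
  A <- phantomAffine(spec)
  d <- spec@dim
  x <- A[1, 1] * (seq_len(d[1]) - 1) + A[1, 4]
  y <- A[2, 2] * (seq_len(d[2]) - 1) + A[2, 4]
  z <- A[3, 3] * (seq_len(d[3]) - 1) + A[3, 4]
  sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
}

# soft (logistic) or hard tissue fractions from the radius map
#' @noRd
tissueFractions <- function(spec) {
  r <- phantomRadius(spec)
  e <- spec@edgeWidth
  step <- function(u) if (e > 0) 1 / (1 + exp(-u / e)) else (u >= 0) * 1
  list(wm = step(spec@rWM - r),
       gm = step(r - spec@rWM) * step(spec@rGM - r),
       csf = step(r - spec@rGM) * step(spec@rBrain - r),
       bg = step(r - spec@rBrain))
}

#' Baseline GM pattern of a phantom
#'
#' `g0(v) = gmPeak * f_gm(v)`: the GM ribbon at the reference age, before
#' aging, sex offset or noise.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [BrainVolume-class].
#' @export
phantomBaseline <- function(spec)
  brainVolume(spec@gmPeak * tissueFractions(spec)$gm, phantomAffine(spec))

#' Generate one synthetic subject
#'
#' The GM truth is
#' `clip( g0(v) * (1 - ageSlope * (age - refAge)) + sexOffset * [sex == "M"]
#' + noise )` clipped to `[0, 1]`, with iid Gaussian voxel noise; the
#' T1-like image is rendered from the tissue fractions with the configured
#' intensity means plus noise. Deterministic given `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param age subject age in years.
#' @param sex `"F"` or `"M"` (the offset applies to `"M"`).
#' @param seed integer seed (`NULL` for the current RNG stream).
#' @return list: `t1` ([BrainVolume-class]), `gm` (template-space,
#'   modulated, unsmoothed [GMMap-class]), `gmLabel` (logical array, true
#'   GM ribbon), `age`, `sex`.
#' @export
generatePhantom <- function(spec, age, sex = "F", seed = NULL) {
  decline <- spec@ageSlope * (age - spec@refAge)
  if (decline >= 1)
    argumentError("degenerate spec: ageSlope * (age - refAge) = %.3f >= 1",
                  decline)
  frac <- tissueFractions(spec)
  g0 <- spec@gmPeak * frac$gm
  withSeed(seed, function() {
    eps <- if (spec@noiseSD > 0)
      array(rnorm(length(g0), 0, spec@noiseSD), dim(g0)) else 0
    gm <- clip01(g0 * (1 - decline) + spec@sexOffset * (sex == "M") + eps)
    m <- spec@t1Means
    t1 <- m["bg"] * frac$bg + m["csf"] * frac$csf + m["gm"] * frac$gm +
      m["wm"] * frac$wm
    if (spec@t1NoiseSD > 0)
      t1 <- t1 + array(rnorm(length(t1), 0, spec@t1NoiseSD), dim(t1))
    A <- phantomAffine(spec)
    list(t1 = brainVolume(t1, A),
         gm = new("GMMap", volume = brainVolume(gm, A), space = "template",
                  modulated = TRUE, smoothedFWHM = NA_real_),
         gmLabel = frac$gm > 0.5, age = age, sex = sex)
  })
}

#' Generate a synthetic normative cohort
#'
#' One phantom per (age, sex, replicate) cell, each with a per-subject
#' seed derived reproducibly from `seed`. Defaults emulate a normative
#' sample spanning ages 16-77 with both sexes and 6 subjects per cell
#' (744 subjects). Maps are returned in memory, or written as NIfTI plus a
#' `cohort.csv` manifest when `outDir` is given.
#'
#' @param spec a [PhantomSpec-class].
#' @param ages integer ages to cover.
#' @param nPerCell phantoms per (age, sex) cell.
#' @param sexes sex categories.
#' @param seed master seed.
#' @param outDir optional output directory.
#' @param smoothFWHM if non-`NA`, each GM map is Gaussian-smoothed with
#'   this FWHM (mm) before being returned/written.
#' @return list: `cohort` (data.frame `subject_id, age, sex[, gm_map]`),
#'   `maps` (named list of [GMMap-class], `NULL` when written to disk),
#'   `spec`.
#' @export
generateCohort <- function(spec = phantomSpec(), ages = 16:77, nPerCell = 6,
                           sexes = c("F", "M"), seed = 1, outDir = NULL,
                           smoothFWHM = NA_real_) {
  if (nPerCell < 1) argumentError("nPerCell must be >= 1")
  grid <- expand.grid(rep = seq_len(nPerCell), sex = sexes, age = ages,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  ids <- sprintf("sub%04d", seq_len(n))
  cohort <- data.frame(subject_id = ids, age = grid$age, sex = grid$sex,
                       stringsAsFactors = FALSE)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  maps <- if (is.null(outDir)) vector("list", n) else NULL
  paths <- character(n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(spec, grid$age[i], grid$sex[i], seed = seed + i)
    gm <- ph$gm
    if (!is.na(smoothFWHM)) gm <- gaussianSmooth(gm, smoothFWHM)
    if (is.null(outDir)) {
      maps[[i]] <- gm
    } else {
      paths[i] <- file.path(outDir, sprintf("%s_gm.nii", ids[i]))
      writeVolume(gm, paths[i], datatype = "double")
    }
  }
  if (is.null(outDir)) {
    names(maps) <- ids
  } else {
    cohort$gm_map <- paths
    write.csv(cohort, file.path(outDir, "cohort.csv"), row.names = FALSE)
  }
  list(cohort = cohort, maps = maps, spec = spec)
}

#' Inject a focal atrophy lesion into a GM map
#'
#' Within the lesion support the map is shifted by
#' `effectSize * sigma(v) * w(v)` (negative effect = volume loss), where
#' `sigma` is the voxel-wise SD map of the normative library the phantom
#' will be scored against — so the injected deviation is calibrated in SD
#' units and the recovered z at the lesion approximates `effectSize`.
#' Values are clipped at 0 (negative GM volume is unphysical).
#'
#' @param gm a [GMMap-class].
#' @param center lesion center, world mm.
#' @param radius lesion radius, mm (> 0).
#' @param effectSize signed effect in SD units.
#' @param sigmaMap SD [BrainVolume-class] on the same grid.
#' @param profile `"sphere"` (hard ball) or `"gaussian"` (falloff with
#'   sigma = radius / 2).
#' @return The lesioned [GMMap-class]; attribute `"lesionMask"` holds the
#'   logical support (for `"gaussian"`, weight > 0.5).
#' @export
injectAtrophy <- function(gm, center, radius, effectSize, sigmaMap,
                          profile = c("sphere", "gaussian")) {
  profile <- match.arg(profile)
  if (radius <= 0) argumentError("lesion radius must be > 0")
  vol <- gm@volume
  assertSameGrid(vol, sigmaMap, "GM map and sigma map")
  d <- gridDim(vol)
  vox <- solve(volAffine(vol)) %*% c(center, 1)
  if (any(vox[1:3] < 0) || any(vox[1:3] > d - 1))
    argumentError("lesion center (%s) mm lies outside the grid",
                  paste(center, collapse = ", "))
  A <- volAffine(vol)
  i <- seq_len(d[1]) - 1; j <- seq_len(d[2]) - 1; k <- seq_len(d[3]) - 1
  wx <- A[1, 1] * i + A[1, 4] - center[1]
  wy <- A[2, 2] * j + A[2, 4] - center[2]
  wz <- A[3, 3] * k + A[3, 4] - center[3]
  if (max(abs(A[1:3, 1:3] - diag(diag(A[1:3, 1:3])))) > 1e-9)
    argumentError("injectAtrophy assumes an axis-aligned grid")
  dist <- sqrt(outer(outer(wx^2, wy^2, `+`), wz^2, `+`))
  w <- if (profile == "sphere") (dist <= radius) * 1
       else exp(-dist^2 / (2 * (radius / 2)^2))
  out <- clip0(vol@data + effectSize * sigmaMap@data * w)
  res <- new("GMMap", volume = withData(vol, out), space = gm@space,
             modulated = gm@modulated, smoothedFWHM = gm@smoothedFWHM)
  attr(res, "lesionMask") <- w > 0.5
  res
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec  %s voxels @ %g mm; GM ribbon %g-%g mm (peak %g)\n",
              paste(object@dim, collapse = "x"), object@voxelSize[1],
              object@rWM, object@rGM, object@gmPeak))
  cat(sprintf("  aging %.3g/yr from age %g; sex offset %g; noise SD %g\n",
              object@ageSlope, object@refAge, object@sexOffset,
              object@noiseSD))
})
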