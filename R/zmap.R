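# Voxel-wise z deviation maps, thresholding, back-transformation, color
# fusion and alignment QC.

#' Voxel-wise z-map against a normative template
#'
#' `z = (g - mu) / sigma` inside the GM mask wherever `sigma > sdFloor`;
#' 0 everywhere else. All inputs must share one grid.
#'
#' @param subjectGM template-space [GMMap-class] (or [BrainVolume-class]).
#' @param mu,sigma normative mean and SD [BrainVolume-class] maps.
#' @param mask binary GM mask [BrainVolume-class].
#' @param sdFloor voxels with `sigma <= sdFloor` are excluded (z = 0)
#'   rather than clamped; a near-zero-SD voxel yields a meaningless z.
#' @return z-map [BrainVolume-class] (SD units).
#' @export
computeZMap <- function(subjectGM, mu, sigma, mask, sdFloor = 1e-6) {
  g <- if (is(subjectGM, "GMMap")) subjectGM@volume else subjectGM
  assertSameGrid(g, mu, "subject map and mean template")
  assertSameGrid(g, sigma, "subject map and SD template")
  assertSameGrid(g, mask, "subject map and mask")
  if (any(sigma@data < 0)) argumentError("sigma must be >= 0")
  use <- (mask@data > 0.5) & (sigma@data > sdFloor)
  z <- array(0, gridDim(g))
  z[use] <- (g@data[use] - mu@data[use]) / sigma@data[use]
  withData(g, z)
}

#' Threshold a z-map
#'
#' Keeps voxels with `|z| > zCut` (strict inequality: a voxel at exactly
#' the cut is not indicated) and zeroes the rest.
#'
#' @param z z-map [BrainVolume-class].
#' @param zCut threshold in SD units (default 2.5).
#' @return Thresholded [BrainVolume-class].
#' @export
thresholdZMap <- function(z, zCut = 2.5) {
  if (zCut < 0) argumentError("zCut must be >= 0")
  withData(z, z@data * (abs(z@data) > zCut))
}

#' Transform a z-map back into subject space
#'
#' Resamples the *continuous* z-map through the inverse of the recorded
#' subject-to-template transform onto the subject grid with trilinear
#' interpolation. Threshold afterwards ([thresholdZMap()]): interpolating
#' a thresholded (discontinuous) field would smear its edges.
#'
#' @param z template-space z-map [BrainVolume-class].
#' @param transform the subject-to-template [AffineTransform-class]
#'   recorded at preprocessing.
#' @param subjectDim,subjectAffine the subject grid spec.
#' @return Subject-space z-map [BrainVolume-class].
#' @export
zToSubjectSpace <- function(z, transform, subjectDim, subjectAffine) {
  if (is.null(transform)) stateError("no subject-to-template transform recorded")
  resampleVolume(z, invertTransform(transform), subjectDim, subjectAffine,
                 interp = "linear", fill = 0)
}

#' Color-code a z-map and fuse it with the structural scan
#'
#' Renders the T1 as window/level-normalized grayscale and alpha-blends a
#' diverging colormap over suprathreshold voxels: negative z (volume loss)
#' ramps blue to cyan, positive z red to yellow, saturating at
#' `|z| = zMax`. Subthreshold voxels show pure grayscale.
#'
#' @param t1 subject [BrainVolume-class].
#' @param zSubject subject-space z-map on the same grid.
#' @param zCut,zMax color ramp start and saturation, SD units.
#' @param alpha blend weight of the color where `|z| > zCut`.
#' @return 4D array `(x, y, z, 3)` of RGB in `[0, 1]`, with the subject
#'   affine attached as attribute `"affine"`.
#' @export
colorizeAndFuse <- function(t1, zSubject, zCut = 2.5, zMax = 10, alpha = 0.6) {
  if (zMax <= zCut) argumentError("zMax (%g) must exceed zCut (%g)", zMax, zCut)
  assertSameGrid(t1, zSubject, "t1 and z-map")
  g <- t1@data
  q <- quantile(g, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q <- range(g) + c(0, 1e-12)
  gray <- clip01((g - q[1]) / (q[2] - q[1]))

  z <- zSubject@data
  hot <- abs(z) > zCut
  ramp <- clip01((abs(z) - zCut) / (zMax - zCut))
  r <- gray; gg <- gray; b <- gray
  neg <- hot & z < 0
  pos <- hot & z > 0
  # loss: blue -> cyan; gain: red -> yellow
  r[neg] <- (1 - alpha) * gray[neg]
  gg[neg] <- (1 - alpha) * gray[neg] + alpha * ramp[neg]
  b[neg] <- (1 - alpha) * gray[neg] + alpha
  r[pos] <- (1 - alpha) * gray[pos] + alpha
  gg[pos] <- (1 - alpha) * gray[pos] + alpha * ramp[pos]
  b[pos] <- (1 - alpha) * gray[pos]
  out <- array(c(r, gg, b), dim = c(gridDim(t1), 3))
  attr(out, "affine") <- t1@affine
  out
}

#' Alignment quality check of the colored overlay
#'
#' Fraction of colored (suprathreshold) voxels falling inside the subject
#' brain mask; a well-aligned map keeps its findings on brain tissue.
#'
#' @param colored binary [BrainVolume-class] (or logical/0-1 array) of
#'   colored voxels in subject space.
#' @param mask binary subject brain-mask [BrainVolume-class].
#' @return list with `fraction` (in `[0, 1]`; 1 when there are no colored
#'   voxels) and `noFindings` flag.
#' @export
qcOverlayAlignment <- function(colored, mask) {
  cv <- if (is(colored, "BrainVolume")) colored@data else colored
  mv <- if (is(mask, "BrainVolume")) mask@data else mask
  if (!all(dim(cv) == dim(mv))) geometryError("QC inputs are not on one grid")
  n <- sum(cv > 0.5)
  if (n == 0) return(list(fraction = 1, noFindings = TRUE))
  list(fraction = sum(cv > 0.5 & mv > 0.5) / n, noFindings = FALSE)
}

#' Map one subject against the normative library
#'
#' The full single-subject workflow: preprocess the T1 (or take a supplied
#' preprocessed GM map), compute the voxel-wise z-map against the matched
#' (age, sex) templates, transform it back into subject space, threshold,
#' color-fuse with the T1, and run the alignment QC. A QC failure is
#' flagged, not fatal — all artifacts are still produced.
#'
#' @param t1 subject [BrainVolume-class].
#' @param templates a [TemplateSet-class].
#' @param age subject age in years (must lie within the template range).
#' @param sex subject sex (must be a template category).
#' @param reference registration target for preprocessing; required unless
#'   `gm` is supplied.
#' @param gm optional preprocessed template-space [GMMap-class] (bypass;
#'   smoothed to the library FWHM via [asPreprocessedGM()] if needed).
#' @param transform subject-to-template transform accompanying `gm`
#'   (default identity: `gm` on the template grid *is* subject space).
#' @param zCut,zMax,alpha see [thresholdZMap()] and [colorizeAndFuse()].
#' @param qcCutoff minimum aligned fraction for QC success (default 0.95).
#' @param fwhm preprocessing smoothing FWHM; defaults to the library's
#'   provenance value (8 mm if unrecorded).
#' @param seed passed to the segmentation stage.
#' @return An [AtrophyMap-class].
#' @export
mapSubject <- function(t1, templates, age, sex, reference = NULL, gm = NULL,
                       transform = NULL, zCut = 2.5, zMax = 10, alpha = 0.6,
                       qcCutoff = 0.95, fwhm = NULL, seed = NULL) {
  key <- templateKey(templates, age, sex)  # validates age range and sex
  fwhm <- fwhm %||% templates@provenance$fwhm
  if (is.null(fwhm) || is.na(fwhm)) fwhm <- 8

  if (is.null(gm)) {
    if (is.null(reference))
      argumentError("either a preprocessed 'gm' map or a 'reference' volume is required")
    pp <- preprocessSubject(t1, reference, fwhm = fwhm, seed = seed)
    gm <- pp$gm
    transform <- pp$transform
  } else {
    gm <- withStage("bypass", asPreprocessedGM(gm, fwhm))
    transform <- transform %||% identityTransform("subject2template")
  }

  mu <- templateMean(templates, age, sex)
  sigma <- templateSD(templates, age, sex)
  mask <- templateMask(templates)
  zT <- withStage("z-map", computeZMap(gm, mu, sigma, mask,
                                       templates@provenance$sdFloor %||% 1e-6))
  zS <- withStage("back-transform",
                  zToSubjectSpace(zT, transform, gridDim(t1), volAffine(t1)))
  zThr <- withStage("threshold", thresholdZMap(zS, zCut))
  ov <- withStage("fusion", colorizeAndFuse(t1, zS, zCut, zMax, alpha))
  bm <- withStage("qc", brainMask(t1, dilateMM = fwhm))
  qc <- qcOverlayAlignment(withData(zThr, (zThr@data != 0) * 1), bm)

  new("AtrophyMap", zTemplate = zT, zSubject = zS, zThresholded = zThr,
      overlay = ov, zCut = zCut, zMax = zMax, qcFraction = qc$fraction,
      qcPassed = qc$fraction >= qcCutoff, qcNoFindings = qc$noFindings,
      provenance = list(age = age, sex = sex, templateKey = key,
                        fwhm = fwhm, qcCutoff = qcCutoff,
                        transform = if (!is.null(transform)) xfmMatrix(transform)))
}

setMethod("show", "AtrophyMap", function(object) {
  supra <- sum(object@zThresholded@data != 0)
  cat(sprintf("AtrophyMap  (age %s, sex %s)  |z| > %g: %d voxels\n",
              object@provenance$age %||% "?", object@provenance$sex %||% "?",
              object@zCut, supra))
  cat(sprintf("  z range [%.2f, %.2f]; QC aligned fraction %.3f (%s)%s\n",
              min(object@zSubject@data), max(object@zSubject@data),
              object@qcFraction, if (object@qcPassed) "pass" else "FLAGGED",
              if (object@qcNoFindings) " [no findings]" else ""))
})

#' Write the artifacts of an AtrophyMap to a directory
#'
#' Writes `z.nii.gz` (subject-space continuous z), `z_thr.nii.gz`,
#' `z_template.nii.gz`, `overlay.nii.gz` (4D RGB) and `qc.json`.
#'
#' @param x an [AtrophyMap-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeAtrophyMap <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(x@zSubject, file.path(dir, "z.nii.gz"))
  writeVolume(x@zThresholded, file.path(dir, "z_thr.nii.gz"))
  writeVolume(x@zTemplate, file.path(dir, "z_template.nii.gz"))
  writeVolume(x@overlay, file.path(dir, "overlay.nii.gz"))
  jsonlite::write_json(list(qcFraction = x@qcFraction, qcPassed = x@qcPassed,
                            noFindings = x@qcNoFindings, zCut = x@zCut,
                            zMax = x@zMax,
                            suprathresholdVoxels = sum(x@zThresholded@data != 0),
                            age = x@provenance$age, sex = x@provenance$sex),
                       file.path(dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
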