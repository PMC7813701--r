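# The simplified VBM preprocessing chain: segmentation -> affine
# normalization -> resampling to the template grid -> Jacobian modulation
# -> Gaussian smoothing. A bypass ingests externally preprocessed maps.

#' Jacobian modulation of a normalized GM map
#'
#' After warping to template space, GM probabilities are densities; scaling
#' each voxel by the Jacobian determinant of the template-to-subject
#' mapping converts them to volume-equivalents, so total GM volume is
#' preserved. For an affine normalization the Jacobian is a single global
#' factor `1 / |det(A)|` where `A` is the 3x3 part of the subject-to-
#' template transform.
#'
#' @param gm a template-space, unmodulated [GMMap-class].
#' @param transform the subject-to-template [AffineTransform-class].
#' @return The modulated [GMMap-class].
#' @export
modulateGM <- function(gm, transform) {
  if (gm@space != "template")
    stateError("modulation applies to template-space maps (got '%s')", gm@space)
  if (gm@modulated) stateError("map is already modulated")
  M3 <- xfmMatrix(transform)[1:3, 1:3]
  dt <- det(M3)
  if (abs(dt) <= .Machine$double.eps) geometryError("singular transform")
  jac <- 1 / abs(dt)  # |det| of the inverse (template->subject) mapping
  new("GMMap", volume = withData(gm@volume, gm@volume@data * jac),
      space = "template", modulated = TRUE, smoothedFWHM = gm@smoothedFWHM)
}

#' Preprocess one subject's T1 scan to a template-space GM map
#'
#' Runs the full chain used both for template building and for single
#' subjects: brain masking + EM gray-matter segmentation, affine
#' registration to `reference`, resampling onto the reference grid,
#' Jacobian modulation and Gaussian smoothing. Errors are re-raised with
#' the failing stage named.
#'
#' @param t1 subject [BrainVolume-class].
#' @param reference template-space reference [BrainVolume-class] (defines
#'   the target grid and the registration target).
#' @param fwhm smoothing kernel FWHM in mm (default 8).
#' @param init initial transform for the registration.
#' @param mask optional subject brain mask; default [brainMask()] of `t1`.
#' @param seed passed to [segmentGM()].
#' @return A list: `gm` (template-space, modulated, smoothed
#'   [GMMap-class]), `transform` (subject-to-template
#'   [AffineTransform-class]), `segmentation` ([SegmentationModel-class]),
#'   `mask` (subject brain mask).
#' @export
preprocessSubject <- function(t1, reference, fwhm = 8,
                              init = identityTransform(), mask = NULL,
                              seed = NULL) {
  if (is.null(mask)) mask <- withStage("brain-mask", brainMask(t1))
  gmSub <- withStage("segmentation", segmentGM(t1, mask, seed = seed))
  xfm <- withStage("registration", registerAffine(t1, reference, init = init))
  gmT <- withStage("resampling", {
    v <- resampleVolume(gmSub@volume, xfm, gridDim(reference),
                        volAffine(reference), interp = "linear", fill = 0)
    new("GMMap", volume = v, space = "template", modulated = FALSE,
        smoothedFWHM = NA_real_)
  })
  gmM <- withStage("modulation", modulateGM(gmT, xfm))
  gmS <- withStage("smoothing", gaussianSmooth(gmM, fwhm))
  list(gm = gmS, transform = xfm, segmentation = attr(gmSub, "model"),
       mask = mask)
}

#' Bypass ingest of an already-preprocessed GM map
#'
#' Accepts GM maps preprocessed outside the package (e.g. with a nonlinear
#' VBM pipeline). A map that is already smoothed is returned untouched; an
#' unsmoothed template-space map is smoothed to `fwhm`. Subject-space maps
#' are rejected — the bypass cannot normalize.
#'
#' @param gm a template-space [GMMap-class] (or [BrainVolume-class], taken
#'   to be modulated and unsmoothed).
#' @param fwhm target smoothing FWHM in mm.
#' @return A template-space, smoothed [GMMap-class].
#' @export
asPreprocessedGM <- function(gm, fwhm = 8) {
  if (is(gm, "BrainVolume"))
    gm <- new("GMMap", volume = gm, space = "template", modulated = TRUE,
              smoothedFWHM = NA_real_)
  if (gm@space != "template")
    stateError("bypass expects template-space maps (got '%s')", gm@space)
  if (!is.na(gm@smoothedFWHM)) return(gm)
  gaussianSmooth(gm, fwhm)
}

setMethod("show", "GMMap", function(object) {
  cat(sprintf("GMMap  %s space, %smodulated, %s\n", object@space,
              if (object@modulated) "" else "un",
              if (is.na(object@smoothedFWHM)) "unsmoothed"
              else sprintf("smoothed %g mm FWHM", object@smoothedFWHM)))
  show(object@volume)
})

#' @rdname volume-accessors
#' @export
gmVolume <- function(x) x@volume

#' Total gray-matter volume of a map
#'
#' Sum of voxel values times voxel volume; for a modulated map this
#' estimates the subject's total GM volume in mm^3.
#' @param gm a [GMMap-class] or [BrainVolume-class].
#' @export
totalGMVolume <- function(gm) {
  v <- if (is(gm, "GMMap")) gm@volume else gm
  sum(v@data) * voxelVolume(v)
}
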