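# S4 class definitions

#' BrainVolume: a 3D scalar grid with world-space geometry
#'
#' The universal image currency of the package: a 3D numeric array plus the
#' 4x4 voxel-index-to-world-mm affine (RAS+ world coordinates, 0-based voxel
#' indices). Voxel sizes are derived from the affine column norms.
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-to-world matrix; its 3x3 part must be invertible.
#' @export
setClass("BrainVolume",
         representation(data = "array", affine = "matrix"))

setValidity("BrainVolume", function(object) {
  d <- object@data
  A <- object@affine
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (!is.numeric(d)) return("data must be numeric")
  if (!all(dim(A) == c(4L, 4L))) return("affine must be 4x4")
  if (any(abs(A[4, ] - c(0, 0, 0, 1)) > 1e-9))
    return("affine last row must be (0,0,0,1)")
  if (abs(det(A[1:3, 1:3])) <= .Machine$double.eps)
    return("affine 3x3 part must be invertible")
  vs <- sqrt(colSums(A[1:3, 1:3]^2))
  if (any(vs <= 0)) return("voxel sizes must be strictly positive")
  TRUE
})

#' AffineTransform: an invertible 4x4 world-to-world mapping
#'
#' Records the spatial normalization between subject and template world
#' coordinates, with a direction tag so the inverse ("back into subject
#' space") is never applied the wrong way round.
#'
#' @slot matrix 4x4 homogeneous world-to-world matrix, invertible.
#' @slot direction one of `"subject2template"`, `"template2subject"`,
#'   `"none"`.
#' @export
setClass("AffineTransform",
         representation(matrix = "matrix", direction = "character"),
         prototype(matrix = diag(4), direction = "none"))

setValidity("AffineTransform", function(object) {
  M <- object@matrix
  if (!all(dim(M) == c(4L, 4L))) return("matrix must be 4x4")
  if (any(abs(M[4, ] - c(0, 0, 0, 1)) > 1e-9))
    return("last row must be (0,0,0,1)")
  if (abs(det(M[1:3, 1:3])) <= .Machine$double.eps)
    return("transform must be invertible")
  if (!object@direction %in% c("subject2template", "template2subject", "none"))
    return("unknown direction tag")
  TRUE
})

#' GMMap: a gray-matter map with its processing state
#'
#' Values are GM probability (unmodulated) or GM volume-equivalent per voxel
#' (modulated), always non-negative. Unmodulated, unsmoothed maps are
#' probabilities and must not exceed 1.
#'
#' @slot volume a [BrainVolume-class].
#' @slot space `"subject"` or `"template"`.
#' @slot modulated has the map been scaled by the normalization Jacobian?
#' @slot smoothedFWHM smoothing kernel FWHM in mm, `NA` if unsmoothed.
#' @export
setClass("GMMap",
         representation(volume = "BrainVolume", space = "character",
                        modulated = "logical", smoothedFWHM = "numeric"))

setValidity("GMMap", function(object) {
  if (!object@space %in% c("subject", "template"))
    return("space must be 'subject' or 'template'")
  v <- object@volume@data
  if (any(v < -1e-9)) return("GM values must be >= 0")
  if (!object@modulated && is.na(object@smoothedFWHM) && any(v > 1 + 1e-6))
    return("unmodulated, unsmoothed GM values must be probabilities (<= 1)")
  TRUE
})

#' SegmentationModel: fitted tissue-intensity mixture
#'
#' Per-class Gaussian intensity parameters from the EM fit used for tissue
#' segmentation, classes sorted by mean intensity (CSF < GM < WM analog).
#'
#' @slot means,sds,weights per-class intensity mean, SD and mixing weight.
#' @slot logLik log-likelihood trace across EM iterations.
#' @slot converged did EM reach the tolerance within the iteration budget?
#' @export
setClass("SegmentationModel",
         representation(means = "numeric", sds = "numeric",
                        weights = "numeric", logLik = "numeric",
                        converged = "logical"))

setValidity("SegmentationModel", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("mixing weights must sum to 1")
  if (any(object@sds <= 0)) return("class SDs must be > 0")
  if (is.unsorted(object@means)) return("classes must be sorted by mean")
  TRUE
})

#' TemplateSet: the normative gray-matter library
#'
#' One voxel-wise mean and SD map per (age, sex) cell, all on one grid,
#' together with the binary GM mask and the provenance needed to reproduce
#' the build (window half-width, smoothing FWHM, per-cell subject counts).
#'
#' @slot mu,sigma named lists (key `"<age>_<sex>"`) of 3D arrays.
#' @slot nSubjects named integer vector of window sizes, same keys.
#' @slot mask binary 3D array (the GM mask).
#' @slot affine shared voxel-to-world affine.
#' @slot ages integer template ages covered.
#' @slot sexes sex categories covered.
#' @slot provenance list: `halfWidth`, `fwhm`, `dim`, `voxelSize`, `minN`,
#'   `maskMeanThreshold`, `sdFloor`, `version`.
#' @export
setClass("TemplateSet",
         representation(mu = "list", sigma = "list", nSubjects = "integer",
                        mask = "array", affine = "matrix", ages = "integer",
                        sexes = "character", provenance = "list"))

setValidity("TemplateSet", function(object) {
  keys <- as.vector(outer(object@ages, object@sexes, paste, sep = "_"))
  if (!setequal(names(object@mu), keys)) return("mu keys must cover ages x sexes")
  if (!setequal(names(object@sigma), keys)) return("sigma keys must cover ages x sexes")
  d <- dim(object@mask)
  for (k in keys) {
    if (!all(dim(object@mu[[k]]) == d)) return("all maps must share one grid")
    if (!all(dim(object@sigma[[k]]) == d)) return("all maps must share one grid")
    if (any(object@sigma[[k]] < 0)) return("sigma must be >= 0 everywhere")
    if (any(object@mu[[k]] < -1e-9)) return("mu must be >= 0 everywhere")
  }
  TRUE
})

#' AtrophyMap: a single subject mapped against the normative library
#'
#' @slot zTemplate continuous z-map on the template grid (0 outside mask).
#' @slot zSubject continuous z-map resampled to the subject grid.
#' @slot zThresholded subject-space z-map with `|z| <= zCut` set to 0.
#' @slot overlay 4D array (x, y, z, RGB) fusing the T1 with the colored map.
#' @slot zCut,zMax threshold and color saturation point, SD units.
#' @slot qcFraction fraction of colored voxels inside the subject brain mask.
#' @slot qcPassed `qcFraction >= cutoff`?
#' @slot qcNoFindings no suprathreshold voxels at all?
#' @slot provenance parameters of the run (age, sex, cutoffs, transform).
#' @export
setClass("AtrophyMap",
         representation(zTemplate = "BrainVolume", zSubject = "BrainVolume",
                        zThresholded = "BrainVolume", overlay = "array",
                        zCut = "numeric", zMax = "numeric",
                        qcFraction = "numeric", qcPassed = "logical",
                        qcNoFindings = "logical", provenance = "list"))

setValidity("AtrophyMap", function(object) {
  if (object@zMax <= object@zCut) return("zMax must exceed zCut")
  thr <- object@zThresholded@data
  if (any(thr != 0 & abs(thr) <= object@zCut))
    return("thresholded map must be 0 wherever |z| <= zCut")
  if (object@qcFraction < 0 || object@qcFraction > 1)
    return("qcFraction must lie in [0, 1]")
  TRUE
})

#' FourfoldTable: paired 2x2 cross-classification of two binary readings
#'
#' Cell layout follows the paired-test convention: `a` both positive, `b`
#' method-1 positive only, `c` method-2 positive only, `d` both negative.
#' Here method 1 is the map reading and method 2 the visual-scale rating.
#'
#' @slot a,b,c,d non-negative integer counts.
#' @slot cohort,hemisphere stratum labels.
#' @export
setClass("FourfoldTable",
         representation(a = "integer", b = "integer", c = "integer",
                        d = "integer", cohort = "character",
                        hemisphere = "character"))

setValidity("FourfoldTable", function(object) {
  cts <- c(object@a, object@b, object@c, object@d)
  if (any(cts < 0)) return("counts must be >= 0")
  if (sum(cts) <= 0) return("table must contain at least one subject")
  TRUE
})

#' PhantomSpec: parameters of the synthetic brain phantom
#'
#' The phantom is a spherical-shell "brain": a WM core, a GM ribbon, a thin
#' CSF rim and background, with logistic tissue boundaries. GM volume
#' declines linearly with age from a reference age, with an additive sex
#' offset and voxel noise; a T1-like image is rendered from the tissue
#' fractions.
#'
#' @slot dim grid shape (3 integers).
#' @slot voxelSize voxel edge lengths, mm.
#' @slot gmPeak baseline GM amplitude of the ribbon (0..1).
#' @slot rWM,rGM,rBrain radii (mm) of the WM core, outer GM boundary and
#'   outer brain (CSF) boundary.
#' @slot edgeWidth logistic boundary width, mm; 0 gives hard labels.
#' @slot ageSlope fractional GM loss per year past `refAge`.
#' @slot sexOffset additive GM offset applied to sex `"M"`.
#' @slot noiseSD additive voxel noise SD on the GM map.
#' @slot t1Means named tissue intensities (`bg`, `csf`, `gm`, `wm`).
#' @slot t1NoiseSD additive noise SD on the rendered T1.
#' @slot refAge age at which the ribbon equals `gmPeak` (years).
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", voxelSize = "numeric",
                        gmPeak = "numeric", rWM = "numeric", rGM = "numeric",
                        rBrain = "numeric", edgeWidth = "numeric",
                        ageSlope = "numeric", sexOffset = "numeric",
                        noiseSD = "numeric", t1Means = "numeric",
                        t1NoiseSD = "numeric", refAge = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("dim must be 3 integers >= 4")
  if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
  if (object@gmPeak < 0 || object@gmPeak > 1) return("gmPeak must be in [0,1]")
  if (object@ageSlope < 0) return("ageSlope must be >= 0")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (!(object@rWM < object@rGM && object@rGM < object@rBrain))
    return("radii must satisfy rWM < rGM < rBrain")
  if (!all(c("bg", "csf", "gm", "wm") %in% names(object@t1Means)))
    return("t1Means must name bg, csf, gm, wm")
  TRUE
})
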