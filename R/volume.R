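#' Create a BrainVolume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world (RAS+ mm) matrix; voxel indices are
#'   0-based. Defaults to identity (1 mm isotropic voxels at the origin).
#' @return A [BrainVolume-class].
#' @examples
#' v <- brainVolume(array(0, dim = c(8, 8, 8)), diag(c(2, 2, 2, 1)))
#' voxelSize(v)
#' @export
brainVolume <- function(data, affine = diag(4)) {
  storage.mode(data) <- "double"
  new("BrainVolume", data = data, affine = affine)
}

#' Accessors for BrainVolume geometry and data
#'
#' `volData` returns the raw 3D array, `volAffine` the 4x4 voxel-to-world
#' matrix, `voxelSize` the voxel edge lengths in mm (affine column norms)
#' and `gridDim` the grid shape.
#'
#' @param x a [BrainVolume-class] (or [GMMap-class] for `gridDim`).
#' @rdname volume-accessors
#' @export
volData <- function(x) {
  if (is(x, "GMMap")) x <- x@volume
  x@data
}

#' @rdname volume-accessors
#' @export
volAffine <- function(x) {
  if (is(x, "GMMap")) x <- x@volume
  x@affine
}

#' @rdname volume-accessors
#' @export
voxelSize <- function(x) {
  A <- volAffine(x)
  sqrt(colSums(A[1:3, 1:3]^2))
}

#' @rdname volume-accessors
#' @export
gridDim <- function(x) dim(volData(x))

# volume of one voxel in mm^3 (|det| of the 3x3 affine part)
#' @noRd
voxelVolume <- function(x) abs(det(volAffine(x)[1:3, 1:3]))

#' Do two volumes share one grid?
#'
#' Same shape and voxel-to-world affine (within `tol`).
#' @param x,y [BrainVolume-class] or [GMMap-class] objects.
#' @param tol absolute tolerance on affine entries.
#' @export
sameGrid <- function(x, y, tol = 1e-6) {
  all(gridDim(x) == gridDim(y)) &&
    max(abs(volAffine(x) - volAffine(y))) <= tol
}

#' @noRd
assertSameGrid <- function(x, y, what = "volumes") {
  if (!sameGrid(x, y))
    geometryError("%s are not on one grid (dims %s vs %s)", what,
                  paste(gridDim(x), collapse = "x"),
                  paste(gridDim(y), collapse = "x"))
  invisible(TRUE)
}

# Replace the data of a volume, keeping geometry.
#' @noRd
withData <- function(vol, data) {
  dim(data) <- gridDim(vol)
  brainVolume(data, vol@affine)
}

setMethod("show", "BrainVolume", function(object) {
  vs <- voxelSize(object)
  cat(sprintf("BrainVolume  %s voxels, %.3g x %.3g x %.3g mm\n",
              paste(dim(object@data), collapse = " x "), vs[1], vs[2], vs[3]))
  cat(sprintf("  range [%.4g, %.4g]  origin (%.4g, %.4g, %.4g) mm\n",
              min(object@data), max(object@data),
              object@affine[1, 4], object@affine[2, 4], object@affine[3, 4]))
})

#' Read and write volumes as NIfTI-1
#'
#' `readVolume` loads a `.nii`/`.nii.gz` file, taking the sform (falling
#' back to the qform) as the voxel-to-world affine. `writeVolume` writes a
#' [BrainVolume-class] (or a 4D array carrying an `"affine"` attribute, as
#' produced by [colorizeAndFuse()]) preserving the affine; data are stored
#' as float32 by default.
#'
#' @param path file to read / write.
#' @param x a [BrainVolume-class] or 4D numeric array with `affine` attr.
#' @param datatype NIfTI on-disk type, `"float"` (default) or `"double"`.
#' @return `readVolume`: a [BrainVolume-class]. `writeVolume`: `path`,
#'   invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) dataError("no such file: %s", path)
  img <- RNifti::readNifti(path)
  A <- RNifti::xform(img, useQuaternionFirst = FALSE)
  A <- matrix(as.numeric(A), 4, 4)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    dataError("%s is not a 3D volume (dims: %s)", path,
              paste(dim(arr), collapse = "x"))
  attributes(arr) <- list(dim = dim(arr))
  brainVolume(arr, A)
}

#' @rdname readVolume
#' @export
writeVolume <- function(x, path, datatype = "float") {
  if (is(x, "GMMap")) x <- x@volume
  if (is(x, "BrainVolume")) {
    arr <- x@data
    A <- x@affine
  } else {
    arr <- x
    A <- attr(x, "affine")
    if (is.null(A)) argumentError("array input needs an 'affine' attribute")
    attributes(arr) <- list(dim = dim(x))
  }
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(A, code = 2L)
  RNifti::sform(img) <- structure(A, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
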