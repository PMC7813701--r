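#' Create, invert and compose affine world-space transforms
#'
#' `affineTransform` wraps a 4x4 homogeneous matrix mapping world
#' coordinates (mm) between subject and template space.
#' `identityTransform` is the do-nothing mapping. `invertTransform` returns
#' the inverse (flipping the direction tag), and `composeTransforms(A, B)`
#' returns the transform applying `B` first, then `A`.
#'
#' @param matrix 4x4 homogeneous matrix (last row 0 0 0 1), invertible.
#' @param direction `"subject2template"`, `"template2subject"` or `"none"`.
#' @return An [AffineTransform-class].
#' @examples
#' t <- translationTransform(c(3, -2, 1))
#' max(abs(xfmMatrix(composeTransforms(t, invertTransform(t))) - diag(4)))
#' @export
affineTransform <- function(matrix, direction = "none") {
  if (abs(det(matrix[1:3, 1:3])) <= .Machine$double.eps)
    geometryError("singular transform (|det| = %.3g)", det(matrix[1:3, 1:3]))
  new("AffineTransform", matrix = matrix, direction = direction)
}

#' @rdname affineTransform
#' @export
identityTransform <- function(direction = "none")
  affineTransform(diag(4), direction)

#' @rdname affineTransform
#' @param t,a,b [AffineTransform-class] objects.
#' @export
invertTransform <- function(t) {
  dir <- switch(t@direction,
                subject2template = "template2subject",
                template2subject = "subject2template",
                "none")
  affineTransform(solve(t@matrix), dir)
}

#' @rdname affineTransform
#' @export
composeTransforms <- function(a, b)
  affineTransform(a@matrix %*% b@matrix, a@direction)

#' @rdname affineTransform
#' @export
xfmMatrix <- function(t) t@matrix

#' Elementary transform builders
#'
#' Convenience constructors for pure translations, (an)isotropic scalings
#' and rotations about a center point, used by the phantom studies and the
#' registration parametrization.
#'
#' @param shift length-3 translation, mm.
#' @param scale scalar or length-3 scale factors.
#' @param angles length-3 rotation angles (radians) about x, y, z.
#' @param center world point (mm) the scaling/rotation is applied about.
#' @param direction direction tag passed to [affineTransform()].
#' @rdname elementary-transforms
#' @export
translationTransform <- function(shift, direction = "none") {
  M <- diag(4)
  M[1:3, 4] <- shift
  affineTransform(M, direction)
}

#' @rdname elementary-transforms
#' @export
scalingTransform <- function(scale, center = c(0, 0, 0), direction = "none") {
  if (length(scale) == 1L) scale <- rep(scale, 3)
  M <- diag(c(scale, 1))
  M[1:3, 4] <- center - scale * center
  affineTransform(M, direction)
}

#' @rdname elementary-transforms
#' @export
rotationTransform <- function(angles, center = c(0, 0, 0), direction = "none") {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center - R %*% center
  affineTransform(M, direction)
}

setMethod("show", "AffineTransform", function(object) {
  cat(sprintf("AffineTransform (%s)\n", object@direction))
  print(round(object@matrix, 6))
})

# Apply transform to an n x 3 matrix of world points.
#' @noRd
applyTransform <- function(t, pts) {
  M <- if (is(t, "AffineTransform")) t@matrix else t
  out <- cbind(pts, 1) %*% t(M)
  out[, 1:3, drop = FALSE]
}
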