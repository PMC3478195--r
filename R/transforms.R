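# Rigid-transform algebra. All transforms act as x' = R x + t.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation numeric(3) in Angstrom.
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Identity transform
#' @export
identityTransform <- function() rigidTransform()

#' Rotation about an axis through a point
#'
#' Rodrigues rotation by \code{angleDeg} degrees about the line through
#' \code{point} with (unnormalised) direction \code{axis}.
#' @export
rotationAboutAxis <- function(axis, angleDeg, point = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  a <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigidTransform(R, as.numeric(point - R %*% point))
}

#' Apply a rigid transform
#'
#' For a matrix of coordinates (n x 3), returns the transformed matrix; for a
#' \linkS4class{ProteinStructure}, returns the structure with transformed
#' coordinates and all metadata unchanged.
#'
#' @param x coordinates or structure.
#' @param transform a \linkS4class{RigidTransform}.
#' @export
setGeneric("applyTransform", function(x, transform) standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform) {
  validObject(transform)
  t(transform@rotation %*% t(x)) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "ProteinStructure", function(x, transform) {
  xyz <- applyTransform(atomCoords(x), transform)
  x@atoms$x <- xyz[, 1]; x@atoms$y <- xyz[, 2]; x@atoms$z <- xyz[, 3]
  x
})

#' Compose two rigid transforms
#'
#' \code{composeTransforms(t1, t2)} applies \code{t2} first:
#' \code{apply(compose(t1, t2), x) == apply(t1, apply(t2, x))}.
#' @export
composeTransforms <- function(t1, t2) {
  rigidTransform(t1@rotation %*% t2@rotation,
                 as.numeric(t1@rotation %*% t2@translation) + t1@translation)
}

#' Invert a rigid transform
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% t@translation))
}
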