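#' Rigid-body transform
#'
#' A rotation plus translation, applied as `p' = R p + t`. Both molecules in a
#' docking session carry one; the force kernel maps receptor atoms into the
#' ligand's local frame with the inverse ligand transform so the ligand grid
#' never needs rebuilding.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector (Angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity transform
#' @return a `rigid_transform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() rigid_transform()

#' Apply a rigid transform to coordinates
#' @param tr a `rigid_transform`.
#' @param xyz N x 3 coordinate matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(tr, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is "b then a": applying the result equals
#' applying `b` first and `a` second.
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), -as.numeric(t(tr$rotation) %*% tr$translation))
}

#' Rotation about an axis
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @param translation optional translation.
#' @return a `rigid_transform`.
#' @export
axis_angle_transform <- function(axis, angle, translation = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rigid_transform(R, translation)
}

transform_to_list <- function(tr) {
  list(rotation = as.numeric(t(tr$rotation)), translation = tr$translation)
}

transform_from_list <- function(x) {
  rigid_transform(matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
                  as.numeric(x$translation))
}
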