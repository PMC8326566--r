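#' Rigid-body transform parameters
#'
#' Six degrees of freedom: translation in mm and rotations in radians about
#' the world x, y, z axes, composed as `T %*% Rx %*% Ry %*% Rz`.
#'
#' @param translation Length-3 numeric, mm.
#' @param rotation Length-3 numeric, radians.
#' @return A `rigid_params` object (also a `spatial_transform`).
#' @export
rigid_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be 3 finite reals")
  if (length(rotation) != 3L || any(!is.finite(rotation)))
    stop("`rotation` must be 3 finite reals (radians)")
  structure(list(translation = translation, rotation = rotation),
            class = c("rigid_params", "spatial_transform"))
}

#' Affine transform parameters
#'
#' Twelve degrees of freedom factored as `T %*% R %*% Shear %*% Scale`: a
#' rigid part, three positive axis scales, and three shears (xy, xz, yz upper
#' triangle).
#'
#' @param rigid A [rigid_params()].
#' @param scales Length-3 positive numeric.
#' @param shears Length-3 numeric.
#' @return An `affine_params` object (also a `spatial_transform`).
#' @export
affine_params <- function(rigid = rigid_params(), scales = c(1, 1, 1),
                          shears = c(0, 0, 0)) {
  stopifnot(inherits(rigid, "rigid_params"))
  scales <- as.numeric(scales); shears <- as.numeric(shears)
  if (length(scales) != 3L || any(!is.finite(scales)) || any(scales <= 0))
    stop("`scales` must be 3 positive reals")
  if (length(shears) != 3L || any(!is.finite(shears)))
    stop("`shears` must be 3 finite reals")
  structure(list(rigid = rigid, scales = scales, shears = shears),
            class = c("affine_params", "spatial_transform"))
}

rotation_matrix_axis <- function(angle, axis) {
  c <- cos(angle); s <- sin(angle)
  m <- diag(4)
  if (axis == 1L) m[2:3, 2:3] <- matrix(c(c, s, -s, c), 2)
  if (axis == 2L) { m[c(1, 3), c(1, 3)] <- matrix(c(c, -s, s, c), 2) }
  if (axis == 3L) m[1:2, 1:2] <- matrix(c(c, s, -s, c), 2)
  m
}

#' Homogeneous matrix of a rigid transform
#' @param params A [rigid_params()].
#' @return 4x4 matrix `T %*% Rx %*% Ry %*% Rz`.
#' @export
rigid_matrix <- function(params) {
  stopifnot(inherits(params, "rigid_params"))
  tr <- diag(4); tr[1:3, 4] <- params$translation
  tr %*% rotation_matrix_axis(params$rotation[1], 1L) %*%
    rotation_matrix_axis(params$rotation[2], 2L) %*%
    rotation_matrix_axis(params$rotation[3], 3L)
}

#' Homogeneous matrix of an affine transform
#' @param params An [affine_params()].
#' @return 4x4 matrix `T %*% R %*% Shear %*% Scale`.
#' @export
affine_matrix <- function(params) {
  stopifnot(inherits(params, "affine_params"))
  shear <- diag(4)
  shear[1, 2] <- params$shears[1]
  shear[1, 3] <- params$shears[2]
  shear[2, 3] <- params$shears[3]
  scale <- diag(c(params$scales, 1))
  rigid_matrix(params$rigid) %*% shear %*% scale
}

# Any spatial transform -> 4x4 matrix where one exists (not DCT warps).
transform_matrix <- function(tf) {
  if (inherits(tf, "rigid_params")) return(rigid_matrix(tf))
  if (inherits(tf, "affine_params")) return(affine_matrix(tf))
  stop("no homogeneous matrix exists for class ", paste(class(tf), collapse = "/"))
}

#' Invert a rigid transform
#' @param params A [rigid_params()].
#' @return A function mapping n x 3 world points through the inverse matrix.
#' @keywords internal
rigid_inverse_matrix <- function(params) solve(rigid_matrix(params))
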