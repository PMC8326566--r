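#' Image geometry: voxel grid plus voxel-to-world mapping
#'
#' An `image_geometry` couples a 3-D voxel grid to world (scanner) space.
#' World coordinates are millimetres on RAS+ axes; voxel indices are 0-based,
#' so world = `voxel_to_world %*% c(i, j, k, 1)` for voxel `(i, j, k)`.
#'
#' @param shape Integer vector of length 3, voxels per axis (all positive).
#' @param voxel_to_world 4x4 homogeneous matrix mapping 0-based voxel indices
#'   to world mm. Must be invertible with strictly positive voxel sizes
#'   (column norms of the 3x3 block).
#' @return An object of class `image_geometry` with elements `shape` and
#'   `voxel_to_world`.
#' @export
image_geometry <- function(shape, voxel_to_world) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  voxel_to_world <- as.matrix(voxel_to_world)
  if (!identical(dim(voxel_to_world), c(4L, 4L)) || any(!is.finite(voxel_to_world)))
    stop("`voxel_to_world` must be a finite 4x4 matrix")
  vs <- sqrt(colSums(voxel_to_world[1:3, 1:3]^2))
  if (any(vs <= 0) || abs(det(voxel_to_world)) < .Machine$double.eps)
    stop("`voxel_to_world` must be invertible with positive voxel sizes")
  structure(list(shape = shape, voxel_to_world = voxel_to_world),
            class = "image_geometry")
}

#' Voxel sizes of a geometry in mm
#' @param geometry An `image_geometry`.
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
voxel_sizes <- function(geometry) {
  sqrt(colSums(geometry$voxel_to_world[1:3, 1:3]^2))
}

#' Construct a geometry with axis-aligned voxels centred on the world origin
#'
#' Convenience for template and phantom grids: diagonal affine, grid centre at
#' world (0, 0, 0).
#'
#' @param shape Voxels per axis.
#' @param voxel_mm Voxel size per axis in mm (recycled to length 3).
#' @return An `image_geometry`.
#' @export
centered_geometry <- function(shape, voxel_mm) {
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- -(as.numeric(shape) - 1) / 2 * voxel_mm
  image_geometry(shape, aff)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_to_world - b$voxel_to_world)) <= tol
}

#' World coordinates of every voxel of a geometry
#'
#' @param geometry An `image_geometry`.
#' @return n x 3 matrix of world mm coordinates, voxels in array (column-major)
#'   order.
#' @export
grid_world_coords <- function(geometry) {
  sh <- geometry$shape
  ijk <- cbind(
    rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3]),
    rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3]),
    rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  )
  apply_homogeneous(geometry$voxel_to_world, ijk)
}

# Apply a 4x4 homogeneous matrix to an n x 3 coordinate matrix.
apply_homogeneous <- function(mat, pts) {
  out <- pts %*% t(mat[1:3, 1:3])
  out[, 1] <- out[, 1] + mat[1, 4]
  out[, 2] <- out[, 2] + mat[2, 4]
  out[, 3] <- out[, 3] + mat[3, 4]
  out
}

# World mm -> continuous 0-based voxel coordinates.
world_to_voxel <- function(geometry, pts) {
  apply_homogeneous(solve(geometry$voxel_to_world), pts)
}

#' Volumetric image: scalar 3-D array with geometry and payload kind
#'
#' @param voxels 3-D numeric array matching `geometry$shape`.
#' @param geometry An `image_geometry`.
#' @param payload_kind One of `"cbf_ml_per_100g_min"`, `"probability"`,
#'   `"mask"`, `"arbitrary"`. Probability payloads must lie in \[0, 1\] and
#'   mask payloads in \{0, 1\}.
#' @return A `volumetric_image`.
#' @export
volumetric_image <- function(voxels, geometry,
                             payload_kind = c("arbitrary", "cbf_ml_per_100g_min",
                                              "probability", "mask")) {
  payload_kind <- match.arg(payload_kind)
  if (!inherits(geometry, "image_geometry")) stop("`geometry` must be an image_geometry")
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array; got ", length(dim(voxels)), " dimensions")
  if (!identical(as.integer(dim(voxels)), geometry$shape))
    stop("voxel array shape does not match geometry shape")
  if (any(!is.finite(voxels))) stop("voxel values must all be finite")
  if (payload_kind == "probability" && (min(voxels) < -1e-9 || max(voxels) > 1 + 1e-9))
    stop("probability payload must lie in [0, 1]")
  if (payload_kind == "mask" && !all(voxels == 0 | voxels == 1))
    stop("mask payload must contain only 0 and 1")
  structure(list(voxels = voxels, geometry = geometry, payload_kind = payload_kind),
            class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  vs <- voxel_sizes(x$geometry)
  cat(sprintf("<volumetric_image> %s  %dx%dx%d voxels @ %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              x$payload_kind, x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              vs[1], vs[2], vs[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Replace the voxel data of an image, keeping geometry, revalidating payload.
with_voxels <- function(image, voxels, payload_kind = image$payload_kind) {
  volumetric_image(voxels, image$geometry, payload_kind)
}

#' Tissue template: GM/WM(/CSF) probability maps plus brain mask on one grid
#'
#' @param gm,wm Probability `volumetric_image`s.
#' @param csf Optional probability `volumetric_image`.
#' @param brain_mask Optional mask `volumetric_image`. When `NULL`, the mask is
#'   derived as GM + WM (+ CSF) > 0.5.
#' @return A `tissue_template`.
#' @export
tissue_template <- function(gm, wm, csf = NULL, brain_mask = NULL) {
  stopifnot(inherits(gm, "volumetric_image"), inherits(wm, "volumetric_image"))
  if (!same_geometry(gm$geometry, wm$geometry))
    stop("GM and WM maps must share one geometry")
  tot <- gm$voxels + wm$voxels
  if (!is.null(csf)) {
    if (!same_geometry(gm$geometry, csf$geometry))
      stop("CSF map must share the GM/WM geometry")
    tot <- tot + csf$voxels
  }
  if (max(tot) > 1 + 1e-6)
    stop("tissue probabilities must sum to at most 1 voxelwise")
  if (is.null(brain_mask)) {
    brain_mask <- volumetric_image((tot > 0.5) * 1, gm$geometry, "mask")
  } else if (!same_geometry(gm$geometry, brain_mask$geometry)) {
    stop("brain mask must share the tissue-map geometry")
  }
  structure(list(gm = gm, wm = wm, csf = csf, brain_mask = brain_mask,
                 geometry = gm$geometry),
            class = "tissue_template")
}
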