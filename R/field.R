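#' Dense deformation field: per-voxel standard-to-native coordinate map
#'
#' The "single joint transformation" object: for every voxel of a
#' standard-space geometry it stores the native-space world coordinate (mm)
#' that voxel samples from, so a whole chain of parametric transforms can be
#' applied with one interpolation.
#'
#' @param geometry Standard-space [image_geometry()].
#' @param coords shape x 3 array (or n x 3 matrix in array order) of native
#'   world coordinates in mm.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(geometry, coords) {
  stopifnot(inherits(geometry, "image_geometry"))
  n <- prod(geometry$shape)
  cm <- matrix(coords, ncol = 3)
  if (nrow(cm) != n) stop("coords do not cover the geometry's voxel grid")
  if (any(!is.finite(cm))) stop("deformation coordinates must be finite")
  structure(list(geometry = geometry,
                 coords = array(cm, c(geometry$shape, 3)),
                 coords_matrix = cm),
            class = "deformation_field")
}

apply_transform_points <- function(tf, pts, fixed_grid_fastpath = NULL) {
  if (inherits(tf, "dct_warp")) {
    if (!is.null(fixed_grid_fastpath) &&
        same_geometry(tf$fixed_geometry, fixed_grid_fastpath)) {
      u <- matrix(dct_displacement_grid(tf), ncol = 3)
    } else {
      vox <- world_to_voxel(tf$fixed_geometry, pts)
      u <- dct_displacement_at(tf, vox)
    }
    apply_homogeneous(affine_matrix(tf$affine_part), pts + u)
  } else {
    apply_homogeneous(transform_matrix(tf), pts)
  }
}

#' Compose a transform chain into a dense deformation field
#'
#' Starting from each target voxel's world coordinate, the transforms are
#' applied in list order (each mapping the coordinate frame produced by its
#' predecessor) to give the native-space coordinate sampled by that voxel.
#' DCT displacements are evaluated in their fixed grid and added before the
#' warp's affine part is applied.
#'
#' @param chain Nonempty list of spatial transforms ([rigid_params()],
#'   [affine_params()], [dct_warp()]).
#' @param target Target (standard-space) [image_geometry()].
#' @return A [deformation_field()] on `target`.
#' @export
compose_to_field <- function(chain, target) {
  if (inherits(chain, "spatial_transform")) chain <- list(chain)
  if (!is.list(chain) || length(chain) == 0L)
    stop("transform chain must be a nonempty list")
  stopifnot(inherits(target, "image_geometry"))
  pts <- grid_world_coords(target)
  first <- TRUE
  for (tf in chain) {
    pts <- apply_transform_points(tf, pts,
                                  fixed_grid_fastpath = if (first) target else NULL)
    first <- FALSE
  }
  deformation_field(target, pts)
}

#' Identity deformation field on a geometry
#' @param geometry An [image_geometry()].
#' @return A [deformation_field()] whose coordinates are the geometry's own
#'   voxel world coordinates.
#' @export
identity_field <- function(geometry) {
  deformation_field(geometry, grid_world_coords(geometry))
}

# ---- transform container serialization (JSON) -------------------------------

geometry_to_list <- function(g) {
  list(shape = g$shape, voxel_to_world = unname(as.vector(g$voxel_to_world)))
}

geometry_from_list <- function(l) {
  image_geometry(unlist(l$shape),
                 matrix(unlist(l$voxel_to_world), 4, 4))
}

transform_to_list <- function(tf) {
  if (inherits(tf, "dct_warp")) {
    list(kind = "dct_warp", K = tf$K,
         affine_part = transform_to_list(tf$affine_part),
         coeffs = lapply(tf$coeffs, function(cc) unname(as.vector(cc))),
         fixed_geometry = geometry_to_list(tf$fixed_geometry))
  } else if (inherits(tf, "affine_params")) {
    list(kind = "affine", translation = tf$rigid$translation,
         rotation = tf$rigid$rotation, scales = tf$scales, shears = tf$shears)
  } else if (inherits(tf, "rigid_params")) {
    list(kind = "rigid", translation = tf$translation, rotation = tf$rotation)
  } else stop("unknown transform class")
}

transform_from_list <- function(l) {
  switch(l$kind,
    rigid = rigid_params(unlist(l$translation), unlist(l$rotation)),
    affine = affine_params(rigid_params(unlist(l$translation), unlist(l$rotation)),
                           unlist(l$scales), unlist(l$shears)),
    dct_warp = {
      K <- l$K
      dct_warp(transform_from_list(l$affine_part),
               lapply(l$coeffs, function(v) array(unlist(v), c(K, K, K))),
               geometry_from_list(l$fixed_geometry))
    },
    stop("unknown transform kind in container: ", l$kind))
}

#' Write a transform chain to a JSON container
#'
#' Serializes a chain of spatial transforms (rigid, affine, DCT warp) with a
#' format version tag and optional provenance notes so a normalization can be
#' re-applied later without re-estimating it.
#'
#' @param chain List of spatial transforms (a single transform is accepted).
#' @param path Output `.json` path.
#' @param provenance Optional character notes (e.g. strategy, source images).
#' @return Invisibly, `path`.
#' @export
write_transform_chain <- function(chain, path, provenance = character()) {
  if (inherits(chain, "spatial_transform")) chain <- list(chain)
  obj <- list(format = "aslnorm-transform", version = 1L,
              provenance = as.list(provenance),
              chain = lapply(chain, transform_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a transform chain from a JSON container
#' @param path Path written by [write_transform_chain()].
#' @return List with `chain` (list of spatial transforms) and `provenance`.
#' @export
read_transform_chain <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$format) || obj$format != "aslnorm-transform")
    stop("not an aslnorm transform container: ", path)
  prov <- obj$provenance
  list(chain = lapply(obj$chain, transform_from_list),
       provenance = unlist(prov))
}
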