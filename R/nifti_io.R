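#' Read a 3-D NIfTI-1 volume
#'
#' Wraps [RNifti::readNifti()]. The file's sform/qform affine becomes the
#' image geometry; data scaling (slope/intercept) is applied by the reader, so
#' voxel values arrive in physical units.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param payload_kind Payload annotation for the returned image.
#' @return A [volumetric_image()].
#' @export
read_volume <- function(path, payload_kind = "arbitrary") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume but '", path, "' has ", length(d),
         " dimensions (axis 4 length ", if (length(d) >= 4) d[4] else NA, ")")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volumetric_image(array(as.numeric(img), dim = d),
                   image_geometry(d, aff), payload_kind)
}

#' Write a volumetric image to NIfTI-1
#'
#' The geometry's voxel-to-world matrix is stored as the sform (code 2).
#' Mask payloads are written as 8-bit unsigned integers, CBF and probability
#' payloads as 32-bit floats, arbitrary payloads as 64-bit floats.
#'
#' @param image A [volumetric_image()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "volumetric_image"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  dt <- switch(image$payload_kind,
               mask = "uint8",
               cbf_ml_per_100g_min = "float",
               probability = "float",
               arbitrary = "double")
  nii <- RNifti::asNifti(image$voxels)
  aff <- structure(image$geometry$voxel_to_world, code = 2L)
  RNifti::sform(nii) <- aff
  RNifti::writeNifti(nii, path, datatype = dt)
  invisible(path)
}
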