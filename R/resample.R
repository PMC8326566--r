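# Interpolation core. All samplers take continuous 0-based voxel coordinates
# (n x 3) and return values, with coordinates outside the volume yielding 0
# (CBF outside the head is ~0, so zero padding is the physical choice).

# Gather voxel values at integer index triples, 0 outside the array.
gather_voxels <- function(vol, i, j, k) {
  d <- dim(vol)
  ok <- i >= 0L & i < d[1] & j >= 0L & j < d[2] & k >= 0L & k < d[3]
  out <- numeric(length(i))
  idx <- i[ok] + d[1] * (j[ok] + d[2] * k[ok]) + 1
  out[ok] <- vol[idx]
  out
}

sample_nearest <- function(vol, vox) {
  gather_voxels(vol, floor(vox[, 1] + 0.5), floor(vox[, 2] + 0.5),
                floor(vox[, 3] + 0.5))
}

# Trilinear. Fractions within 1e-7 of a lattice plane are snapped so that
# lattice-exact mappings (identity, whole-voxel shifts) reproduce stored
# values bit-for-bit.
sample_trilinear <- function(vol, vox) {
  i0 <- floor(vox[, 1]); j0 <- floor(vox[, 2]); k0 <- floor(vox[, 3])
  fx <- vox[, 1] - i0; fy <- vox[, 2] - j0; fz <- vox[, 3] - k0
  snap <- function(f) { f[f < 1e-7] <- 0; f[f > 1 - 1e-7] <- 1; f }
  fx <- snap(fx); fy <- snap(fy); fz <- snap(fz)
  v <- numeric(length(fx))
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - fz else fz
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - fy else fy
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - fx else fx
        w <- wx * wy * wz
        nz <- which(w != 0)
        if (length(nz))
          v[nz] <- v[nz] + w[nz] *
            gather_voxels(vol, i0[nz] + dx, j0[nz] + dy, k0[nz] + dz)
      }
    }
  }
  v
}

# Trilinear value plus exact partial derivatives of the interpolant with
# respect to the continuous voxel coordinates (piecewise smooth; used by the
# registration gradients so objective and gradient are mutually consistent).
sample_trilinear_grad <- function(vol, vox) {
  i0 <- floor(vox[, 1]); j0 <- floor(vox[, 2]); k0 <- floor(vox[, 3])
  fx <- vox[, 1] - i0; fy <- vox[, 2] - j0; fz <- vox[, 3] - k0
  n <- length(fx)
  v <- d1 <- d2 <- d3 <- numeric(n)
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - fz else fz
    sz <- if (dz == 0) -1 else 1
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - fy else fy
      sy <- if (dy == 0) -1 else 1
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - fx else fx
        sx <- if (dx == 0) -1 else 1
        g <- gather_voxels(vol, i0 + dx, j0 + dy, k0 + dz)
        v <- v + wx * wy * wz * g
        d1 <- d1 + sx * wy * wz * g
        d2 <- d2 + wx * sy * wz * g
        d3 <- d3 + wx * wy * sz * g
      }
    }
  }
  list(value = v, d = cbind(d1, d2, d3))
}

# Keys cubic-convolution kernel (a = -0.5, Catmull-Rom); interpolating, so no
# prefilter is needed, and weights sum to 1.
keys_weights <- function(f) {
  # distances of the 4 taps at offsets -1, 0, 1, 2 from the sample point
  w <- matrix(0, length(f), 4)
  t0 <- 1 + f; t1 <- f; t2 <- 1 - f; t3 <- 2 - f
  a <- -0.5
  w[, 1] <- a * t0^3 - 5 * a * t0^2 + 8 * a * t0 - 4 * a
  w[, 2] <- (a + 2) * t1^3 - (a + 3) * t1^2 + 1
  w[, 3] <- (a + 2) * t2^3 - (a + 3) * t2^2 + 1
  w[, 4] <- a * t3^3 - 5 * a * t3^2 + 8 * a * t3 - 4 * a
  w
}

sample_cubic <- function(vol, vox) {
  i0 <- floor(vox[, 1]); j0 <- floor(vox[, 2]); k0 <- floor(vox[, 3])
  wx <- keys_weights(vox[, 1] - i0)
  wy <- keys_weights(vox[, 2] - j0)
  wz <- keys_weights(vox[, 3] - k0)
  v <- numeric(nrow(vox))
  for (dz in 0:3) for (dy in 0:3) for (dx in 0:3) {
    w <- wx[, dx + 1] * wy[, dy + 1] * wz[, dz + 1]
    v <- v + w * gather_voxels(vol, i0 + dx - 1, j0 + dy - 1, k0 + dz - 1)
  }
  v
}

sample_volume <- function(vol, vox, order) {
  switch(as.character(order),
         "0" = sample_nearest(vol, vox),
         "1" = sample_trilinear(vol, vox),
         "3" = sample_cubic(vol, vox),
         stop("unsupported interpolation order: ", order,
              " (supported: 0, 1, 3)"))
}

# Resolve a mapping argument into n x 3 native (moving-space) world
# coordinates for the given fixed-space world coordinates / geometry.
mapping_to_native_world <- function(mapping, target) {
  if (inherits(mapping, "deformation_field")) {
    if (!same_geometry(mapping$geometry, target))
      stop("deformation field geometry does not match the target geometry")
    matrix(mapping$coords, ncol = 3)
  } else {
    compose_to_field(list(mapping), target)$coords_matrix
  }
}

#' Resample an image onto a target geometry through a spatial mapping
#'
#' Pull-back resampling: each target voxel's world coordinate is pushed
#' through `mapping` (a standard-to-native transform or a dense
#' [deformation_field()]) into the source image's world frame and the source
#' is interpolated there. However many parametric steps the mapping composes,
#' exactly one interpolation is performed. Coordinates falling outside the
#' source volume yield 0.
#'
#' @param image Source [volumetric_image()] (the moving image).
#' @param target Target [image_geometry()].
#' @param mapping A [deformation_field()] on `target`, or any single spatial
#'   transform (`rigid_params`, `affine_params`, `dct_warp`), mapping target
#'   world coordinates into `image` world coordinates.
#' @param order Interpolation order: 0 (nearest), 1 (trilinear) or 3 (cubic).
#' @return A [volumetric_image()] on `target`.
#' @export
resample <- function(image, target, mapping, order = 1) {
  stopifnot(inherits(image, "volumetric_image"), inherits(target, "image_geometry"))
  if (!order %in% c(0, 1, 3))
    stop("unsupported interpolation order: ", order, " (supported: 0, 1, 3)")
  native_world <- mapping_to_native_world(mapping, target)
  vox <- world_to_voxel(image$geometry, native_world)
  vals <- sample_volume(image$voxels, vox, order)
  kind <- if (image$payload_kind == "mask" && order != 0) "arbitrary" else image$payload_kind
  if (image$payload_kind == "probability") vals <- pmin(pmax(vals, 0), 1)
  volumetric_image(array(vals, dim = target$shape), target, kind)
}
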