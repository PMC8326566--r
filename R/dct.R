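#' Orthonormal discrete cosine (DCT-II) basis matrix
#'
#' Column `k` (0-based) evaluated at sample `i` (0-based) is
#' `sqrt(1/N)` for `k = 0` and `sqrt(2/N) * cos(pi * (2 i + 1) * k / (2 N))`
#' otherwise, giving orthonormal columns. These low-frequency cosines are the
#' classic parameterization for small-deformation nonlinear normalization of
#' brain images.
#'
#' @param K Number of basis functions, `1 <= K <= N`.
#' @param N Grid length.
#' @param at Optional continuous 0-based sample positions (default `0:(N-1)`);
#'   the cosine expressions extend naturally off-lattice.
#' @return `length(at)` x `K` matrix.
#' @export
dct_basis <- function(K, N, at = NULL) {
  K <- as.integer(K); N <- as.integer(N)
  if (K < 1L) stop("basis order K must be >= 1")
  if (K > N) stop("basis order K = ", K, " exceeds grid length N = ", N)
  if (is.null(at)) at <- seq_len(N) - 1
  B <- matrix(0, length(at), K)
  B[, 1] <- sqrt(1 / N)
  if (K > 1L)
    for (k in seq_len(K - 1L))
      B[, k + 1L] <- sqrt(2 / N) * cos(pi * (2 * at + 1) * k / (2 * N))
  B
}

#' DCT warp: low-frequency nonlinear deformation with an affine part
#'
#' The warp maps a fixed-space world coordinate `w` at fixed-grid voxel `v`
#' to `Affine(w + u(v))`, where the displacement `u` is a separable
#' tensor-product expansion of `K^3` DCT coefficients per world axis (mm).
#' Displacements are expressed in the fixed grid and composed inside the
#' affine. With all-zero coefficients the warp reduces exactly to its affine
#' part.
#'
#' @param affine_part An [affine_params()] applied after the displacement.
#' @param coeffs List of three `K x K x K` arrays (mm per world axis).
#' @param fixed_geometry [image_geometry()] of the grid the basis lives on.
#' @return A `dct_warp` object (also a `spatial_transform`).
#' @export
dct_warp <- function(affine_part = affine_params(), coeffs, fixed_geometry) {
  stopifnot(inherits(affine_part, "affine_params"),
            inherits(fixed_geometry, "image_geometry"))
  if (!is.list(coeffs) || length(coeffs) != 3L)
    stop("`coeffs` must be a list of three K x K x K arrays")
  K <- dim(as.array(coeffs[[1]]))
  coeffs <- lapply(coeffs, function(cc) {
    cc <- as.array(cc)
    if (length(dim(cc)) != 3L || !identical(dim(cc), K))
      stop("all coefficient arrays must share one K x K x K shape")
    if (any(!is.finite(cc))) stop("DCT coefficients must be finite")
    cc
  })
  if (K[1] < 1L) stop("basis order must be >= 1")
  if (any(K > fixed_geometry$shape))
    stop("basis order exceeds the fixed grid length on some axis")
  structure(list(affine_part = affine_part, coeffs = coeffs,
                 fixed_geometry = fixed_geometry, K = K[1]),
            class = c("dct_warp", "spatial_transform"))
}

#' Zero-coefficient DCT warp of a given order
#' @param fixed_geometry Fixed-grid [image_geometry()].
#' @param K Basis order per axis (default 16).
#' @param affine_part Affine part (default identity).
#' @return A [dct_warp()].
#' @export
zero_dct_warp <- function(fixed_geometry, K = 16, affine_part = affine_params()) {
  z <- array(0, c(K, K, K))
  dct_warp(affine_part, list(z, z, z), fixed_geometry)
}

# Displacement (n x 3 mm) of a DCT warp at continuous fixed-grid voxel
# coordinates (n x 3). Vectorized over points: for each axis coefficient
# array C, u = sum_k Bx[,k] * rowSums((By %*% C[k,,]) * Bz).
dct_displacement_at <- function(warp, vox) {
  vox <- matrix(vox, ncol = 3)
  K <- warp$K
  sh <- warp$fixed_geometry$shape
  Bx <- dct_basis(K, sh[1], at = vox[, 1])
  By <- dct_basis(K, sh[2], at = vox[, 2])
  Bz <- dct_basis(K, sh[3], at = vox[, 3])
  out <- matrix(0, nrow(vox), 3)
  for (d in 1:3) {
    C <- warp$coeffs[[d]]
    u <- numeric(nrow(vox))
    for (k in seq_len(K))
      u <- u + Bx[, k] * rowSums((By %*% C[k, , ]) * Bz)
    out[, d] <- u
  }
  out
}

# Displacement on the full fixed grid, computed separably (fast path).
# Returns a shape x 3 array, voxels in array order.
dct_displacement_grid <- function(warp) {
  sh <- warp$fixed_geometry$shape
  K <- warp$K
  Bx <- dct_basis(K, sh[1]); By <- dct_basis(K, sh[2]); Bz <- dct_basis(K, sh[3])
  out <- array(0, c(sh, 3))
  for (d in 1:3)
    out[, , , d] <- dct_expand(warp$coeffs[[d]], Bx, By, Bz)
  out
}

# Expand a K x K x K coefficient array onto the grid spanned by the three
# basis matrices (Nx x K etc.): U[i,j,l] = sum C[k,m,n] Bx[i,k] By[j,m] Bz[l,n].
dct_expand <- function(C, Bx, By, Bz) {
  K <- dim(C)
  t1 <- Bx %*% matrix(C, K[1], K[2] * K[3])              # Nx x (K K)
  t1 <- array(t1, c(nrow(Bx), K[2], K[3]))
  t2 <- apply(t1, c(1, 3), function(v) By %*% v)         # Ny x Nx x Kz
  t2 <- aperm(t2, c(2, 1, 3))                            # Nx x Ny x Kz
  t3 <- matrix(t2, nrow(Bx) * nrow(By), K[3]) %*% t(Bz)  # (Nx Ny) x Nz
  array(t3, c(nrow(Bx), nrow(By), nrow(Bz)))
}

# Project a gridded scalar field (Nx x Ny x Nz) onto the K-order DCT basis:
# C = Bx' U By(Bz')..., the adjoint of dct_expand; exact least squares by
# orthonormality.
dct_project <- function(U, Bx, By, Bz) {
  dct_expand(U, t(Bx), t(By), t(Bz))
}

#' Evaluate a DCT warp's displacement at voxel indices
#'
#' Returns the separable tensor-basis displacement (mm, per world axis) of a
#' [dct_warp()] at the requested fixed-grid voxel indices.
#'
#' @param warp A [dct_warp()].
#' @param voxel_indices n x 3 matrix of 0-based integer voxel indices within
#'   the warp's fixed grid.
#' @return n x 3 matrix of displacements in mm.
#' @export
warp_displacement <- function(warp, voxel_indices) {
  stopifnot(inherits(warp, "dct_warp"))
  vox <- matrix(as.numeric(voxel_indices), ncol = 3)
  sh <- warp$fixed_geometry$shape
  if (any(vox < 0) || any(vox[, 1] > sh[1] - 1) || any(vox[, 2] > sh[2] - 1) ||
      any(vox[, 3] > sh[3] - 1))
    stop("voxel index outside the warp's fixed grid")
  dct_displacement_at(warp, vox)
}
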