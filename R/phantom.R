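#' Specification of a synthetic pediatric brain phantom
#'
#' The phantom emulates the features that drive perfusion-based spatial
#' normalization of infant ASL data: a smooth ellipsoidal brain with a
#' cortical GM shell and WM core (GM perfusion about three times WM, defaults
#' 60 and 20 ml/100 g/min), coarse native ASL voxels (3.75 x 3.75 x 4.0 mm),
#' additive Gaussian noise, a seeded smooth low-frequency deformation, and an
#' optional trigonocephaly-like frontal narrowing.
#'
#' @param grid_shape Template grid (default 64^3).
#' @param template_voxel_mm Template voxel size, mm (default 2 isotropic).
#' @param native_shape Native ASL grid (default 34 x 34 x 32).
#' @param native_voxel_mm Native ASL voxel size (default 3.75, 3.75, 4.0 mm).
#' @param v_gm,v_wm Tissue perfusion, ml/100 g/min (defaults 60, 20).
#' @param noise_sd Additive Gaussian noise SD on native CBF (default 5).
#' @param warp_amplitude_mm Peak displacement of the random smooth warp
#'   (default 4 mm; 0 disables it).
#' @param warp_order DCT order of the ground-truth warp (default 8).
#' @param trigono_severity Trigonocephaly severity in \[0, 1\] (default 0).
#' @param rigid_offset Optional [rigid_params()] ground-truth pose offset;
#'   `NULL` draws one from the seed (components up to ~3 mm / 3 degrees).
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), template_voxel_mm = 2,
                         native_shape = c(34, 34, 32),
                         native_voxel_mm = c(3.75, 3.75, 4.0),
                         v_gm = 60, v_wm = 20, noise_sd = 5,
                         warp_amplitude_mm = 4, warp_order = 8,
                         trigono_severity = 0, rigid_offset = NULL,
                         seed = 1L) {
  if (warp_amplitude_mm < 0) stop("warp amplitude must be >= 0")
  if (trigono_severity < 0 || trigono_severity > 1)
    stop("trigonocephaly severity must lie in [0, 1]")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 template_voxel_mm = rep_len(template_voxel_mm, 3),
                 native_shape = as.integer(native_shape),
                 native_voxel_mm = rep_len(native_voxel_mm, 3),
                 v_gm = v_gm, v_wm = v_wm, noise_sd = noise_sd,
                 warp_amplitude_mm = warp_amplitude_mm,
                 warp_order = as.integer(warp_order),
                 trigono_severity = trigono_severity,
                 rigid_offset = rigid_offset, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Brain ellipsoid radii (mm): right-left, posterior-anterior, inferior-superior.
.phantom_radii <- c(45, 55, 42)

# Normalized ellipsoidal radius field on a geometry (world origin = centre).
ellipsoid_rho <- function(geometry, radii, center = c(0, 0, 0)) {
  w <- grid_world_coords(geometry)
  r <- sqrt(((w[, 1] - center[1]) / radii[1])^2 +
            ((w[, 2] - center[2]) / radii[2])^2 +
            ((w[, 3] - center[3]) / radii[3])^2)
  array(r, geometry$shape)
}

#' Build the phantom tissue template
#'
#' A smooth ellipsoidal brain: WM core, cortical GM shell, CSF rim and two
#' ellipsoidal ventricles, with probabilities obtained by Gaussian smoothing
#' of the tissue indicator functions (so GM + WM + CSF <= 1 voxelwise) and a
#' brain mask at total tissue probability > 0.5. Deterministic: the same spec
#' always yields a bit-identical template.
#'
#' @param spec A [phantom_spec()].
#' @return A [tissue_template()].
#' @export
make_template <- function(spec = phantom_spec()) {
  geom <- centered_geometry(spec$grid_shape, spec$template_voxel_mm)
  rho0 <- ellipsoid_rho(geom, .phantom_radii)
  # smooth angular lobulation of the brain surface (low-order harmonics of
  # the normalized direction): without it the shell is rotationally
  # ambiguous and intensity-driven registration cannot pin down tangential
  # displacement, which no real cortex permits
  w <- grid_world_coords(geom)
  nx <- array(w[, 1] / .phantom_radii[1], geom$shape) / pmax(rho0, 1e-6)
  ny <- array(w[, 2] / .phantom_radii[2], geom$shape) / pmax(rho0, 1e-6)
  nz <- array(w[, 3] / .phantom_radii[3], geom$shape) / pmax(rho0, 1e-6)
  mod <- 1 + 0.10 * nx * ny + 0.08 * ny * nz - 0.08 * nx * nz +
    0.10 * ny * (nx^2 - 0.5 * nz^2) + 0.08 * nz * (3 * ny^2 - 1) / 2
  rho <- rho0 / mod
  vent <- pmin(ellipsoid_rho(geom, c(7, 16, 7), center = c(-9, -8, 2)),
               ellipsoid_rho(geom, c(7, 16, 7), center = c(9, -8, 2)))
  # deep GM nuclei (basal-ganglia-like), interior intensity structure
  nuclei <- pmin(ellipsoid_rho(geom, c(8, 11, 8), center = c(-15, 8, 0)),
                 ellipsoid_rho(geom, c(8, 11, 8), center = c(15, 8, 0)))
  wm_ind <- (rho <= 0.70 & vent > 1 & nuclei > 1) * 1
  gm_ind <- ((rho > 0.70 & rho <= 0.92) | (rho <= 0.70 & nuclei <= 1 & vent > 1)) * 1
  csf_ind <- ((rho > 0.92 & rho <= 1.0) | (rho <= 0.70 & vent <= 1)) * 1
  sm <- function(ind) gaussian_smooth(
    volumetric_image(ind, geom, "arbitrary"), c(3, 3, 3))$voxels
  gm <- sm(gm_ind); wm <- sm(wm_ind); csf <- sm(csf_ind)
  tissue_template(
    gm = volumetric_image(pmin(pmax(gm, 0), 1), geom, "probability"),
    wm = volumetric_image(pmin(pmax(wm, 0), 1), geom, "probability"),
    csf = volumetric_image(pmin(pmax(csf, 0), 1), geom, "probability"))
}

#' Trigonocephaly-like ground-truth warp
#'
#' A smooth displacement field with the shape motif of metopic
#' craniosynostosis: medially-directed lateral compression confined to the
#' anterior third of the head, a small anterior midline (forehead ridge)
#' protrusion, and mild posterior biparietal widening. The field is built
#' analytically, projected exactly onto an order-8 DCT basis (so nonlinear
#' DCT registration can represent the truth), and rescaled so the peak
#' displacement magnitude equals `severity * 8` mm. The lateral component is
#' left-right antisymmetric about the midsagittal plane.
#'
#' @param severity Severity in \[0, 1\].
#' @param geometry Fixed-grid [image_geometry()] (default: phantom template
#'   grid).
#' @return A [dct_warp()] with identity affine part.
#' @export
trigono_warp <- function(severity, geometry = NULL) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (is.null(geometry)) geometry <- centered_geometry(c(64, 64, 64), 2)
  K <- 8L
  sh <- geometry$shape
  w <- grid_world_coords(geometry)
  x <- w[, 1]; y <- w[, 2]; z <- w[, 3]
  odd_bump <- function(x, s) (x / s) * exp(0.5 - x^2 / (2 * s^2))  # max |.| = 1
  gz <- exp(-z^2 / (2 * 30^2))
  ux <- -1.00 * odd_bump(x, 25) * exp(-(y - 40)^2 / (2 * 15^2)) * gz +  # frontal narrowing
         0.30 * odd_bump(x, 28) * exp(-(y + 30)^2 / (2 * 20^2)) * gz    # biparietal widening
  uy <-  0.45 * exp(-x^2 / (2 * 10^2)) * exp(-(y - 45)^2 / (2 * 12^2)) * gz  # midline ridge
  Bx <- dct_basis(K, sh[1]); By <- dct_basis(K, sh[2]); Bz <- dct_basis(K, sh[3])
  Cx <- dct_project(array(ux, sh), Bx, By, Bz)
  Cy <- dct_project(array(uy, sh), Bx, By, Bz)
  Cz <- array(0, c(K, K, K))
  if (severity == 0) {
    Cx[] <- 0; Cy[] <- 0
    return(dct_warp(affine_params(), list(Cx, Cy, Cz), geometry))
  }
  Ux <- dct_expand(Cx, Bx, By, Bz)
  Uy <- dct_expand(Cy, Bx, By, Bz)
  peak <- max(sqrt(Ux^2 + Uy^2))
  scale <- severity * 8 / peak
  dct_warp(affine_params(), list(Cx * scale, Cy * scale, Cz), geometry)
}

# Seeded random smooth warp: decaying random DCT coefficients rescaled so the
# peak displacement magnitude *within the region of interest* (the brain, when
# a mask is given) equals the requested amplitude.
random_smooth_warp <- function(amplitude_mm, K, geometry, seed, mask = NULL) {
  sh <- geometry$shape
  set.seed(seed)
  decay <- function() {
    k <- 0:(K - 1)
    w <- outer(outer(exp(-k), exp(-k)), exp(-k))
    array(stats::rnorm(K^3) * w, c(K, K, K))
  }
  Cs <- list(decay(), decay(), decay())
  if (amplitude_mm == 0) {
    Cs <- lapply(Cs, function(C) { C[] <- 0; C })
    return(dct_warp(affine_params(), Cs, geometry))
  }
  Bx <- dct_basis(K, sh[1]); By <- dct_basis(K, sh[2]); Bz <- dct_basis(K, sh[3])
  U <- lapply(Cs, dct_expand, Bx = Bx, By = By, Bz = Bz)
  mag <- sqrt(U[[1]]^2 + U[[2]]^2 + U[[3]]^2)
  peak <- if (is.null(mask)) max(mag) else max(mag[mask == 1])
  dct_warp(affine_params(), lapply(Cs, `*`, amplitude_mm / peak), geometry)
}

# Merge two DCT warps (identity affines) on one geometry by embedding their
# coefficients into a common basis order and adding.
add_dct_warps <- function(a, b) {
  K <- max(a$K, b$K)
  embed <- function(C, K) {
    out <- array(0, c(K, K, K))
    d <- dim(C)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- C
    out
  }
  dct_warp(affine_params(),
           lapply(1:3, function(d) embed(a$coeffs[[d]], K) + embed(b$coeffs[[d]], K)),
           a$fixed_geometry)
}

# Numerically invert phi(s) = R(s + u(s)) at the given world points:
# y = R^-1(x), then fixed-point iteration s <- y - u(s).
invert_truth_chain <- function(warp, rig, pts, tol = 0.01, max_iter = 20L) {
  y <- apply_homogeneous(solve(rigid_matrix(rig)), pts)
  s <- y
  for (it in seq_len(max_iter)) {
    u <- dct_displacement_at(warp, world_to_voxel(warp$fixed_geometry, s))
    s_new <- y - u
    if (max(abs(s_new - s)) < tol) { s <- s_new; break }
    s <- s_new
  }
  s
}

#' Generate a synthetic subject: native CBF plus ground-truth transform
#'
#' The template tissues are deformed by the ground-truth chain (DCT warp
#' followed by a rigid pose offset), converted to CBF at the spec's tissue
#' perfusion values, blurred to the ASL point-spread (Gaussian at the native
#' voxel FWHM), resampled to the coarse native ASL grid, and corrupted with
#' seeded additive Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @param with_structural Also return `native_tissues` (the subject's own
#'   tissue maps in native space, standing in for an external structural
#'   segmentation) and `m0` (a synthetic proton-density-like calibration
#'   image on the ASL grid), the inputs of the structural-mediated baseline.
#' @return A `synthetic_subject`: `native_cbf`, `true_chain` (list: DCT warp,
#'   rigid), `true_field` (the standard-to-native [deformation_field()]),
#'   `template`, `spec`, and optionally `native_tissues` and `m0`.
#' @export
make_subject <- function(spec = phantom_spec(), with_structural = FALSE) {
  template <- make_template(spec)
  geom <- template$geometry
  warp <- add_dct_warps(
    random_smooth_warp(spec$warp_amplitude_mm, spec$warp_order, geom,
                       seed = spec$seed * 13L + 1L,
                       mask = template$brain_mask$voxels),
    trigono_warp(spec$trigono_severity, geom))
  rig <- spec$rigid_offset
  if (is.null(rig)) {
    set.seed(spec$seed * 13L + 2L)
    rig <- rigid_params(stats::runif(3, -2.8, 2.8),
                        stats::runif(3, -3, 3) * pi / 180)
  }
  true_chain <- list(warp, rig)
  # native image: pull template tissue through the inverse truth map on a
  # fine native-space grid, then blur and downsample
  fine_geom <- geom
  psi <- invert_truth_chain(warp, rig, grid_world_coords(fine_geom))
  psi_field <- deformation_field(fine_geom, psi)
  gm_f <- resample(template$gm, fine_geom, psi_field, order = 1)
  wm_f <- resample(template$wm, fine_geom, psi_field, order = 1)
  cbf_f <- volumetric_image(spec$v_gm * gm_f$voxels + spec$v_wm * wm_f$voxels,
                            fine_geom, "cbf_ml_per_100g_min")
  cbf_b <- gaussian_smooth(cbf_f, spec$native_voxel_mm)
  native_geom <- centered_geometry(spec$native_shape, spec$native_voxel_mm)
  cbf_n <- resample(cbf_b, native_geom, rigid_params(), order = 1)
  set.seed(spec$seed * 13L + 3L)
  noisy <- cbf_n$voxels + stats::rnorm(length(cbf_n$voxels), 0, spec$noise_sd)
  out <- list(
    native_cbf = volumetric_image(noisy, native_geom, "cbf_ml_per_100g_min"),
    true_chain = true_chain,
    true_field = compose_to_field(true_chain, geom),
    template = template, spec = spec)
  if (with_structural) {
    csf_f <- resample(template$csf, fine_geom, psi_field, order = 1)
    out$native_tissues <- tissue_template(gm = gm_f, wm = wm_f, csf = csf_f)
    # proton-density-like calibration image: near-uniform over brain tissue,
    # brighter CSF, blurred to the ASL point-spread, on the ASL grid
    m0_f <- volumetric_image(
      100 * (gm_f$voxels + wm_f$voxels) + 130 * csf_f$voxels,
      fine_geom, "arbitrary")
    m0_b <- gaussian_smooth(m0_f, spec$native_voxel_mm)
    out$m0 <- resample(m0_b, native_geom, rigid_params(), order = 1)
  }
  structure(out, class = "synthetic_subject")
}

#' Displacement error between two deformation fields
#'
#' Voxelwise Euclidean distance (mm) between the native-space coordinates of
#' two standard-to-native deformation fields, summarized over a mask. This is
#' the geometric oracle for registration-recovery experiments.
#'
#' @param estimated,truth [deformation_field()]s on one geometry.
#' @param mask Mask [volumetric_image()] on the same geometry.
#' @return List with `mean_mm` and `max_mm`.
#' @export
displacement_error <- function(estimated, truth, mask) {
  stopifnot(inherits(estimated, "deformation_field"),
            inherits(truth, "deformation_field"))
  if (!same_geometry(estimated$geometry, truth$geometry) ||
      !same_geometry(estimated$geometry, mask$geometry))
    stop("fields and mask must share one geometry")
  idx <- which(mask$voxels == 1)
  d <- estimated$coords_matrix[idx, , drop = FALSE] -
       truth$coords_matrix[idx, , drop = FALSE]
  e <- sqrt(rowSums(d^2))
  list(mean_mm = mean(e), max_mm = max(e))
}
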