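#' Separable Gaussian smoothing in millimetre units
#'
#' FWHM is converted to a per-axis sigma in voxels through the geometry's
#' voxel sizes: sigma = FWHM / (2 sqrt(2 ln 2)) / voxel_size. The kernel is
#' truncated at 4 sigma and normalized to unit sum, so interior mass is
#' conserved; volume edges are zero-padded. FWHM 0 on an axis leaves that
#' axis untouched.
#'
#' @param image A [volumetric_image()].
#' @param fwhm_mm Full width at half maximum per axis, mm (recycled to 3).
#' @return Smoothed [volumetric_image()] (payload preserved).
#' @export
gaussian_smooth <- function(image, fwhm_mm) {
  stopifnot(inherits(image, "volumetric_image"))
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0))
    stop("FWHM must be nonnegative and finite on every axis")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_sizes(image$geometry)
  vol <- image$voxels
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    r <- max(1L, ceiling(4 * sigma_vox[ax]))
    k <- exp(-0.5 * ((-r:r) / sigma_vox[ax])^2)
    k <- k / sum(k)
    vol <- convolve_axis(vol, k, ax)
  }
  kind <- image$payload_kind
  if (kind == "mask") kind <- "arbitrary"
  if (kind == "probability") vol <- pmin(pmax(vol, 0), 1)
  volumetric_image(vol, image$geometry, kind)
}

# Zero-padded 1-D convolution of a 3-D array along one axis.
convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  m <- matrix(aperm(vol, perm), nrow = d[axis])
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(kernel)) {
    off <- t - 1L - r
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[t] * m[src[ok], ]
  }
  back <- order(perm)
  aperm(array(out, d[perm]), back)
}

#' Percentile intensity normalization within a mask
#'
#' Negative values are clipped to 0, the `p`-th percentile of the clipped
#' values inside `mask` is found by linear interpolation between order
#' statistics, the image is divided by it, and voxels whose clipped value
#' exceeds the percentile are dropped from the returned inclusion mask. This
#' is the normalization step used by the real-valued Tanimoto QC metric.
#'
#' @param image A [volumetric_image()].
#' @param mask A mask [volumetric_image()] on the same geometry, nonempty.
#' @param p Percentile in (0, 100\]; default 97.
#' @return List with `normalized` (image divided by the percentile, clipped at
#'   0), `included` (mask minus above-percentile voxels) and `percentile_value`.
#' @export
percentile_normalize <- function(image, mask, p = 97) {
  stopifnot(inherits(image, "volumetric_image"), inherits(mask, "volumetric_image"))
  if (!same_geometry(image$geometry, mask$geometry))
    stop("image and mask geometries differ")
  if (mask$payload_kind != "mask") stop("`mask` must carry a mask payload")
  if (p <= 0 || p > 100) stop("percentile must lie in (0, 100]")
  inside <- mask$voxels == 1
  if (!any(inside)) stop("mask is empty")
  clipped <- pmax(image$voxels, 0)
  vals <- clipped[inside]
  P <- as.numeric(stats::quantile(vals, p / 100, type = 7, names = FALSE))
  if (P <= 0)
    stop("degenerate input: values within the mask are all <= 0")
  included <- mask$voxels
  included[clipped > P] <- 0
  list(normalized = volumetric_image(clipped / P, image$geometry, "arbitrary"),
       included = volumetric_image(included, image$geometry, "mask"),
       percentile_value = P)
}
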