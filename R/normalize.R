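new_normalization_result <- function(strategy, chain, field, cbf_std,
                                     tissue_cbf_used, cost_trace) {
  structure(list(strategy = strategy, transform_chain = chain, field = field,
                 cbf_std = cbf_std, tissue_cbf_used = tissue_cbf_used,
                 cost_trace = cost_trace),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> strategy %s, chain of %d transform(s), tissue CBF (%.1f, %.1f)\n",
              x$strategy, length(x$transform_chain),
              x$tissue_cbf_used[1], x$tissue_cbf_used[2]))
  invisible(x)
}

strip_affine <- function(warp) {
  dct_warp(affine_params(), warp$coeffs, warp$fixed_geometry)
}

finalize_result <- function(strategy, chain, cbf_native, template,
                            tissue_cbf_used, cost_trace, order = 3) {
  field <- compose_to_field(chain, template$geometry)
  cbf_std <- resample(cbf_native, template$geometry, field, order = order)
  new_normalization_result(strategy, chain, field, cbf_std,
                           tissue_cbf_used, cost_trace)
}

#' Normalize a native ASL CBF image directly to template space
#'
#' Direct perfusion-contrast spatial normalization: the native CBF image is
#' registered to a pseudo-CBF target built from the template's GM and WM
#' probability maps (reference perfusion 60/20 ml/100 g/min), using a rigid,
#' rigid+affine, or rigid+affine+DCT-nonlinear transform chain. The `dct`
#' strategy runs in two iterations: after a rough rigid+affine alignment the
#' subject's GM and WM perfusion are estimated by least squares and the
#' pseudo-CBF target is rebuilt with those values before the nonlinear stage.
#' All estimated steps are composed into a single deformation field and the
#' native image is interpolated exactly once.
#'
#' @param cbf_native Native-space CBF [volumetric_image()].
#' @param template Standard-space [tissue_template()].
#' @param strategy `"rigid"`, `"affine"` or `"dct"`.
#' @param params [pseudo_cbf_params()] for the first-iteration target.
#' @param opts [registration_options()].
#' @return A `normalization_result`: `strategy`, `transform_chain`, `field`
#'   (the single joint [deformation_field()]), `cbf_std` (CBF in template
#'   space, one cubic interpolation), `tissue_cbf_used` and per-stage
#'   `cost_trace`.
#' @export
normalize_asl <- function(cbf_native, template,
                          strategy = c("dct", "affine", "rigid"),
                          params = pseudo_cbf_params(),
                          opts = registration_options()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cbf_native, "volumetric_image"),
            inherits(template, "tissue_template"))
  pseudo0 <- build_pseudo_cbf(template, params)
  mask <- template$brain_mask
  rig <- register_rigid(cbf_native, pseudo0, opts, mask = mask)
  traces <- list(rigid = attr(rig, "cost_trace"))
  defaults <- c(v_gm = params$v_gm, v_wm = params$v_wm)
  if (strategy == "rigid")
    return(finalize_result("asl_rigid", list(rig), cbf_native, template,
                           defaults, traces))
  aff <- register_affine(cbf_native, pseudo0, opts, init = rig, mask = mask)
  traces$affine <- attr(aff, "cost_trace")
  if (strategy == "affine")
    return(finalize_result("asl_affine", list(aff), cbf_native, template,
                           defaults, traces))
  # iteration 1: rough rigid+affine alignment, subject tissue CBF estimate
  rough <- resample(cbf_native, template$geometry, compose_to_field(list(aff),
                    template$geometry), order = 1)
  # effective resolution of the rough image: acquisition point-spread plus the
  # trilinear resampling kernel (triangle of one native voxel; its
  # Gaussian-equivalent FWHM is 2*sqrt(2 log 2)/sqrt(6) ~ 0.96 voxel)
  native_vox <- voxel_sizes(cbf_native$geometry)
  eff_fwhm <- sqrt(params$smoothing_fwhm_mm^2 +
                     (2 * sqrt(2 * log(2)) / sqrt(6) * native_vox)^2)
  est <- tryCatch(estimate_tissue_cbf(rough, template,
                                      resolution_fwhm_mm = eff_fwhm),
                  error = function(e) {
                    warning("tissue CBF estimation failed (", conditionMessage(e),
                            "); using default pseudo-CBF values")
                    list(v_gm = params$v_gm, v_wm = params$v_wm, fallback = TRUE)
                  })
  params2 <- pseudo_cbf_params(est$v_gm, est$v_wm, params$smoothing_fwhm_mm)
  # iteration 2: subject-realistic pseudo-CBF target, nonlinear DCT stage
  pseudo2 <- build_pseudo_cbf(template, params2)
  warp <- register_dct(cbf_native, pseudo2, opts, init = aff, mask = mask)
  traces$dct <- attr(warp, "cost_trace")
  finalize_result("asl_dct", list(strip_affine(warp), warp$affine_part),
                  cbf_native, template,
                  c(v_gm = est$v_gm, v_wm = est$v_wm), traces)
}

#' Normalize ASL to template space via a structural image
#'
#' The structural-mediated baseline: the M0 calibration image is rigidly
#' aligned to the subject's (externally segmented) structural tissue maps via
#' a synthetic 60/20 perfusion image, the structural tissue maps are then
#' registered to the template with affine + DCT stages on pseudo-CBF images,
#' and the joint chain (DCT displacement, affine, rigid) is applied to the
#' native CBF with one interpolation.
#'
#' @param cbf_native Native ASL CBF [volumetric_image()] (same grid as `m0`).
#' @param m0 M0 calibration [volumetric_image()].
#' @param subject_tissues [tissue_template()] of the subject's own GM/WM maps
#'   in native structural space (external segmentation).
#' @param template Standard-space [tissue_template()].
#' @param params [pseudo_cbf_params()].
#' @param opts [registration_options()].
#' @return A `normalization_result` (strategy `"structural"`).
#' @export
normalize_via_structural <- function(cbf_native, m0, subject_tissues, template,
                                     params = pseudo_cbf_params(),
                                     opts = registration_options()) {
  if (is.null(subject_tissues) || !inherits(subject_tissues, "tissue_template"))
    stop("subject tissue segmentations are required for the structural ",
         "strategy; without them use normalize_asl() (direct ASL strategies)")
  stopifnot(inherits(cbf_native, "volumetric_image"),
            inherits(m0, "volumetric_image"))
  if (!same_geometry(cbf_native$geometry, m0$geometry))
    stop("CBF and M0 must share the native ASL grid")
  # rigid: M0 -> structural space, matched through a synthetic perfusion image
  pseudo_native <- build_pseudo_cbf(subject_tissues, params)
  rig_m0 <- register_rigid(m0, pseudo_native, opts,
                           mask = subject_tissues$brain_mask)
  # structural -> template on pseudo-CBF contrast
  pseudo_tpl <- build_pseudo_cbf(template, params)
  rig_s <- register_rigid(pseudo_native, pseudo_tpl, opts,
                          mask = template$brain_mask)
  aff <- register_affine(pseudo_native, pseudo_tpl, opts, init = rig_s,
                         mask = template$brain_mask)
  warp <- register_dct(pseudo_native, pseudo_tpl, opts, init = aff,
                       mask = template$brain_mask)
  chain <- list(strip_affine(warp), warp$affine_part, rig_m0)
  finalize_result("structural", chain, cbf_native, template,
                  c(v_gm = params$v_gm, v_wm = params$v_wm),
                  list(rigid = attr(rig_m0, "cost_trace"),
                       affine = attr(aff, "cost_trace"),
                       dct = attr(warp, "cost_trace")))
}
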