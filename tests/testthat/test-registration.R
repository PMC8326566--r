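test_that("scaled-SSD cost is zero for self-alignment and scale-invariant", {
  tpl <- small_template()
  p <- build_pseudo_cbf(tpl)
  mask <- tpl$brain_mask
  expect_lt(registration_cost(p, p, rigid_params(), mask), 1e-10)
  doubled <- volumetric_image(2 * p$voxels, p$geometry, "cbf_ml_per_100g_min")
  expect_lt(registration_cost(doubled, p, rigid_params(), mask), 1e-10)
  g <- centered_geometry(c(5, 5, 5), 2)
  expect_error(registration_cost(p, p, rigid_params(),
                                 volumetric_image(array(0, c(32, 32, 32)),
                                                  tpl$geometry, "mask")),
               "empty")
})

test_that("misalignment strictly increases the cost", {
  g <- centered_geometry(c(9, 9, 9), 2)
  v <- array(0, c(9, 9, 9)); v[4:6, 5, 5] <- c(1, 2, 1)
  img <- volumetric_image(v, g)
  mask <- full_mask(g)
  aligned <- registration_cost(img, img, rigid_params(), mask)
  shifted <- registration_cost(img, img, rigid_params(translation = c(2, 0, 0)), mask)
  expect_gt(shifted, aligned)
})

test_that("rigid registration recovers known pose offsets", {
  opts <- registration_options()
  recover <- function(t_true, r_true, seed) {
    spec <- phantom_spec(seed = seed, warp_amplitude_mm = 0, noise_sd = 0,
                         rigid_offset = rigid_params(t_true, r_true))
    subj <- make_subject(spec)
    register_rigid(subj$native_cbf, build_pseudo_cbf(subj$template), opts,
                   mask = subj$template$brain_mask)
  }
  # pure translation
  est <- recover(c(5, -3, 2), c(0, 0, 0), seed = 101)
  expect_lt(max(abs(est$translation - c(5, -3, 2))), 0.5)
  # pure in-plane rotation of 5 degrees
  est <- recover(c(0, 0, 0), c(0, 0, 5 * pi / 180), seed = 102)
  expect_lt(abs(est$rotation[3] - 5 * pi / 180) * 180 / pi, 0.5)
  # combined six-degree-of-freedom offset
  t_true <- c(3, -4, 2); r_true <- c(4, -3, 5) * pi / 180
  est <- recover(t_true, r_true, seed = 103)
  expect_lt(sqrt(sum((est$translation - t_true)^2)), 1)
  expect_lt(max(abs(est$rotation - r_true)) * 180 / pi, 1)
})

test_that("an already aligned image is a rigid fixed point", {
  spec <- small_spec(seed = 31, warp_amplitude_mm = 0,
                     rigid_offset = rigid_params(), noise_sd = 0)
  subj <- make_subject(spec)
  pseudo <- build_pseudo_cbf(subj$template)
  est <- register_rigid(subj$native_cbf, pseudo,
                        mask = subj$template$brain_mask)
  expect_lt(max(abs(est$translation)), 0.2)
  expect_lt(max(abs(est$rotation)) * 180 / pi, 0.2)
})

test_that("affine stage is anchored and never worse than its rigid init", {
  spec <- small_spec(seed = 32, warp_amplitude_mm = 0,
                     rigid_offset = rigid_params(c(2, -1, 1), c(0, 0, 0.03)))
  subj <- make_subject(spec)
  tpl <- subj$template
  pseudo <- build_pseudo_cbf(tpl)
  opts <- registration_options()
  rig <- register_rigid(subj$native_cbf, pseudo, opts, mask = tpl$brain_mask)
  aff <- register_affine(subj$native_cbf, pseudo, opts, init = rig,
                         mask = tpl$brain_mask)
  expect_lt(max(abs(aff$scales - 1)), 0.02)
  expect_lt(max(abs(aff$shears)), 0.02)
  # nested models on the same smoothed pair
  expect_lte(attr(aff, "cost"), attr(rig, "cost") + 1e-12)
  mv <- gaussian_smooth(subj$native_cbf, opts$presmooth_fwhm_mm)
  fx <- gaussian_smooth(pseudo, opts$presmooth_fwhm_mm)
  expect_lte(registration_cost(mv, fx, aff, tpl$brain_mask),
             registration_cost(mv, fx, rig, tpl$brain_mask) + 1e-12)
})

test_that("DCT stage cost never exceeds the affine-only cost and shrinks with lambda", {
  spec <- small_spec(seed = 33, warp_amplitude_mm = 3)
  subj <- make_subject(spec)
  tpl <- subj$template
  pseudo <- build_pseudo_cbf(tpl)
  opts <- registration_options()
  rig <- register_rigid(subj$native_cbf, pseudo, opts, mask = tpl$brain_mask)
  aff <- register_affine(subj$native_cbf, pseudo, opts, init = rig,
                         mask = tpl$brain_mask)
  mv <- gaussian_smooth(subj$native_cbf, opts$presmooth_dct_fwhm_mm)
  fx <- gaussian_smooth(pseudo, opts$presmooth_dct_fwhm_mm)
  cost_aff <- registration_cost(mv, fx, aff, tpl$brain_mask)
  norms <- c()
  for (lam in c(0.5, 50)) {
    w <- register_dct(subj$native_cbf, pseudo,
                      registration_options(lambda_reg = lam),
                      init = aff, mask = tpl$brain_mask)
    expect_lte(attr(w, "cost"), cost_aff + 1e-12)
    norms <- c(norms, sqrt(sum(unlist(lapply(w$coeffs, function(C) sum(C^2))))))
  }
  expect_lte(norms[2], norms[1])
  # accepted-step cost traces are nonincreasing
  expect_true(all(diff(attr(w, "cost_trace")) <= 0))
})

test_that("the dct strategy is a fixed point on an undeformed subject", {
  spec <- phantom_spec(seed = 34, warp_amplitude_mm = 0,
                       rigid_offset = rigid_params(), noise_sd = 0)
  subj <- make_subject(spec)
  res <- normalize_asl(subj$native_cbf, subj$template, strategy = "dct")
  de <- displacement_error(res$field, identity_field(subj$template$geometry),
                           subj$template$brain_mask)
  expect_lt(de$mean_mm, 1)
  # single interpolation: the returned volume is exactly one resampling of
  # the native image through the composed field
  redo <- resample(subj$native_cbf, subj$template$geometry, res$field, order = 3)
  expect_identical(res$cbf_std$voxels, redo$voxels)
})

test_that("the two-iteration scheme adopts subject-specific tissue CBF", {
  spec <- small_spec(seed = 35, v_gm = 50, v_wm = 15)
  subj <- make_subject(spec)
  res <- normalize_asl(subj$native_cbf, subj$template, strategy = "dct")
  expect_lt(abs(res$tissue_cbf_used[["v_gm"]] - 50), 5)
  expect_lt(abs(res$tissue_cbf_used[["v_wm"]] - 15), 5)
  expect_gt(abs(res$tissue_cbf_used[["v_gm"]] - 60), 2)  # not the default
})

test_that("normalization results are deterministic", {
  spec <- small_spec(seed = 36)
  subj <- make_subject(spec)
  r1 <- normalize_asl(subj$native_cbf, subj$template, strategy = "affine")
  r2 <- normalize_asl(subj$native_cbf, subj$template, strategy = "affine")
  expect_identical(r1$cbf_std$voxels, r2$cbf_std$voxels)
  expect_identical(r1$field$coords_matrix, r2$field$coords_matrix)
  expect_identical(r1$cost_trace, r2$cost_trace)
})

test_that("the structural pathway records a 3-transform chain and needs segmentations", {
  spec <- small_spec(seed = 37, warp_amplitude_mm = 0,
                     rigid_offset = rigid_params(), noise_sd = 0)
  subj <- make_subject(spec, with_structural = TRUE)
  tpl <- subj$template
  expect_error(normalize_via_structural(subj$native_cbf, subj$m0, NULL, tpl),
               "normalize_asl")
  res <- normalize_via_structural(subj$native_cbf, subj$m0,
                                  subj$native_tissues, tpl)
  expect_equal(length(res$transform_chain), 3)
  expect_equal(res$strategy, "structural")
  de <- displacement_error(res$field, identity_field(tpl$geometry),
                           tpl$brain_mask)
  expect_lt(de$mean_mm, 1)
})

test_that("degraded structural segmentations lose to direct perfusion registration", {
  spec <- small_spec(seed = 38, warp_amplitude_mm = 3, trigono_severity = 0.4)
  subj <- make_subject(spec, with_structural = TRUE)
  tpl <- subj$template
  ref <- build_pseudo_cbf(tpl)
  # blurred, gamma-biased tissue maps: the low-contrast structural regime
  degrade <- function(img) {
    v <- gaussian_smooth(img, c(8, 8, 8))$voxels
    volumetric_image(0.45 * pmin(pmax(v, 0), 1)^0.6, img$geometry, "probability")
  }
  tis_deg <- tissue_template(degrade(subj$native_tissues$gm),
                             degrade(subj$native_tissues$wm))
  res_struct <- normalize_via_structural(subj$native_cbf, subj$m0, tis_deg, tpl)
  res_dct <- normalize_asl(subj$native_cbf, tpl, strategy = "dct")
  tc_struct <- real_valued_tc(res_struct$cbf_std, ref, tpl$brain_mask)$tc_percent
  tc_dct <- real_valued_tc(res_dct$cbf_std, ref, tpl$brain_mask)$tc_percent
  expect_gt(tc_dct, tc_struct)
})
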