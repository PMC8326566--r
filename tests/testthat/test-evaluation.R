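test_that("Tanimoto coefficient anchors: identity is 100, disjoint is 0", {
  tpl <- small_template()
  p <- build_pseudo_cbf(tpl)
  mask <- tpl$brain_mask
  sc <- real_valued_tc(p, p, mask)
  expect_equal(sc$tc_percent, 100, tolerance = 1e-9)
  expect_gte(sc$n_voxels_included, 1)
  # disjoint supports within the mask
  g <- tpl$geometry
  left <- array(0, g$shape); right <- array(0, g$shape)
  half <- g$shape[1] / 2
  left[1:half, , ] <- 50 * mask$voxels[1:half, , ]
  right[(half + 1):g$shape[1], , ] <- 50 * mask$voxels[(half + 1):g$shape[1], , ]
  sc0 <- real_valued_tc(volumetric_image(left, g), volumetric_image(right, g), mask)
  expect_equal(sc0$tc_percent, 0)
})

test_that("TC matches the real-valued formula on a hand-computed pair", {
  g <- centered_geometry(c(1, 1, 2), 2)
  a <- volumetric_image(array(c(1, 1), c(1, 1, 2)), g)
  b <- volumetric_image(array(c(1, 0), c(1, 1, 2)), g)
  # p = 100 keeps both vectors as given (normalization by their maximum 1)
  sc <- real_valued_tc(a, b, full_mask(g), p = 100)
  expect_equal(sc$tc_percent, 50)
})

test_that("TC is symmetric, scale-free and bounded", {
  tpl <- small_template()
  mask <- tpl$brain_mask
  g <- tpl$geometry
  set.seed(7)
  for (i in 1:5) {
    a <- volumetric_image(array(stats::rexp(prod(g$shape), 1 / 40), g$shape), g)
    b <- volumetric_image(array(stats::rexp(prod(g$shape), 1 / 40), g$shape), g)
    ab <- real_valued_tc(a, b, mask)$tc_percent
    expect_identical(ab, real_valued_tc(b, a, mask)$tc_percent)
    expect_gte(ab, 0); expect_lte(ab, 100)
    expect_equal(real_valued_tc(a, volumetric_image(3.7 * a$voxels, g), mask)$tc_percent,
                 100, tolerance = 1e-9)
  }
})

test_that("joint exclusion of hyperintense voxels raises the TC", {
  tpl <- small_template()
  p <- build_pseudo_cbf(tpl)
  mask <- tpl$brain_mask
  v <- p$voxels
  hot <- which(mask$voxels == 1)[1:20]
  v[hot] <- 400  # arterial-artifact-like hot voxels in one image only
  a <- volumetric_image(v, tpl$geometry)
  with_excl <- real_valued_tc(a, p, mask, p = 97)$tc_percent
  without <- real_valued_tc(a, p, mask, p = 100)$tc_percent
  expect_gte(with_excl, without)
})

test_that("regional CBF means are per-label arithmetic means", {
  g <- centered_geometry(c(2, 2, 1), 2)
  cbf <- volumetric_image(array(c(10, 10, 40, 20), c(2, 2, 1)), g,
                          "cbf_ml_per_100g_min")
  atlas <- volumetric_image(array(c(1, 1, 1, 2), c(2, 2, 1)), g)
  tab <- region_mean_cbf(cbf, atlas)
  expect_equal(tab$mean_cbf, c(20, 20))
  expect_equal(tab$n_voxels, c(3, 1))
  # constant image: every region mean equals the constant
  cbf60 <- volumetric_image(array(60, c(2, 2, 1)), g, "cbf_ml_per_100g_min")
  expect_true(all(region_mean_cbf(cbf60, atlas)$mean_cbf == 60))
  # absent labels reported as absent, not zero
  tab2 <- region_mean_cbf(cbf, atlas, labels = c(1, 5))
  expect_equal(tab2$label_id, 1L)
  expect_equal(attr(tab2, "absent_labels"), 5L)
  bad <- volumetric_image(array(c(1, 1.5, 2, 2), c(2, 2, 1)), g)
  expect_error(region_mean_cbf(cbf, bad), "integer")
})

test_that("strategy comparison tables carry one row per subject-strategy pair", {
  tpl <- small_template()
  p <- build_pseudo_cbf(tpl)
  mask <- tpl$brain_mask
  shifted <- resample(p, tpl$geometry, rigid_params(translation = c(6, 0, 0)))
  results <- list(
    s1 = list(rigid = shifted, dct = p),
    s2 = list(rigid = shifted, dct = p))
  csv <- withr::local_tempfile(fileext = ".csv")
  scsv <- withr::local_tempfile(fileext = ".csv")
  cmp <- strategy_comparison(results, p, mask, csv = csv, summary_csv = scsv)
  expect_equal(nrow(cmp$table), 4)
  expect_equal(nrow(utils::read.csv(csv)), 4)
  # identical volumes across subjects give identical TC per strategy
  expect_equal(cmp$table$tc_percent[cmp$table$strategy == "dct"], c(100, 100),
               tolerance = 1e-9)
  # quartiles agree with an independent quantile computation
  rigid_tc <- cmp$table$tc_percent[cmp$table$strategy == "rigid"]
  expect_equal(cmp$summary$median[cmp$summary$strategy == "rigid"],
               as.numeric(stats::quantile(rigid_tc, 0.5, type = 7)))
})

test_that("overlay montages are complete, correct at the contour and deterministic", {
  tpl <- small_template()
  p <- build_pseudo_cbf(tpl)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_overlay(p, tpl$wm, out = f1)
  render_overlay(p, tpl$wm, out = f2)
  expect_true(file.exists(f1))
  img <- png::readPNG(f1)
  # 12 axial + 12 sagittal panels in a 4 x 6 grid of 32 x 32 tiles
  expect_equal(dim(img)[1:2], c(4 * 32, 6 * 32))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(render_overlay(p, tpl$wm, threshold = 1.2, out = f1), "threshold")
  # red contour pixels sit exactly on the WM > 0.5 boundary of a block phantom
  g <- centered_geometry(c(16, 16, 3), 2)
  wmv <- array(0, c(16, 16, 3)); wmv[5:10, 6:12, 2] <- 1
  wm <- volumetric_image(wmv, g, "probability")
  cbf <- volumetric_image(array(30, c(16, 16, 3)), g, "cbf_ml_per_100g_min")
  f3 <- withr::local_tempfile(fileext = ".png")
  render_overlay(cbf, wm, n_axial = 1, n_sagittal = 1, out = f3)
  inside <- wmv[, , 2] > 0.5
  ring <- inside & !(rbind(inside[-1, ], FALSE) & rbind(FALSE, inside[-16, ]) &
                     cbind(inside[, -1], FALSE) & cbind(FALSE, inside[, -16]))
  m <- png::readPNG(f3)
  red <- m[, , 1] == 1 & m[, , 2] == 0 & m[, , 3] == 0
  expect_equal(sum(red[1:16, 1:16]), sum(ring))
})
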