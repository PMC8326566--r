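test_that("rigid matrices behave as T Rx Ry Rz", {
  expect_equal(rigid_matrix(rigid_params()), diag(4))
  m <- rigid_matrix(rigid_params(translation = c(5, 0, 0)))
  expect_equal(as.numeric(m %*% c(0, 0, 0, 1)), c(5, 0, 0, 1))
  m <- rigid_matrix(rigid_params(rotation = c(0, 0, pi / 2)))
  expect_equal(as.numeric(m %*% c(1, 0, 0, 1)), c(0, 1, 0, 1), tolerance = 1e-12)
  R <- m[1:3, 1:3]
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(11)
  pts <- matrix(stats::rnorm(30, sd = 40), ncol = 3)
  for (i in 1:5) {
    p <- rigid_params(stats::runif(3, -20, 20), stats::runif(3, -pi / 4, pi / 4))
    moved <- pts %*% t(rigid_matrix(p)[1:3, 1:3]) +
      matrix(p$translation, 10, 3, byrow = TRUE)
    expect_equal(as.numeric(dist(moved)), as.numeric(dist(pts)),
                 tolerance = 1e-9)
  }
})

test_that("affine matrices factor as T R Shear Scale", {
  expect_equal(affine_matrix(affine_params()), diag(4))
  m <- affine_matrix(affine_params(scales = c(1.1, 1, 1)))
  expect_equal(as.numeric(m %*% c(2, 0, 0, 1)), c(2.2, 0, 0, 1))
  p <- affine_params(rigid_params(c(1, 2, 3), c(0.2, -0.1, 0.3)),
                     scales = c(1.2, 0.8, 1.05), shears = c(0.1, -0.05, 0.2))
  expect_equal(det(affine_matrix(p)[1:3, 1:3]), prod(p$scales), tolerance = 1e-12)
  expect_error(affine_params(scales = c(0, 1, 1)), "positive")
})

test_that("DCT basis columns are orthonormal and match the closed form", {
  for (cfg in list(c(16, 64), c(1, 5), c(8, 8), c(12, 256), c(5, 33))) {
    B <- dct_basis(cfg[1], cfg[2])
    expect_equal(crossprod(B), diag(cfg[1]), tolerance = 1e-10)
  }
  expect_equal(dct_basis(1, 9), matrix(sqrt(1 / 9), 9, 1))
  expect_equal(dct_basis(2, 4)[1, 2], sqrt(2 / 4) * cos(pi / 8), tolerance = 1e-14)
  expect_error(dct_basis(10, 4), "exceeds")
})

test_that("warp displacement equals the brute-force triple sum", {
  set.seed(21)
  g <- centered_geometry(c(16, 16, 16), 4)
  K <- 3
  coeffs <- lapply(1:3, function(d) array(stats::rnorm(K^3), c(K, K, K)))
  w <- dct_warp(affine_params(), coeffs, g)
  vox <- cbind(sample(0:15, 10, TRUE), sample(0:15, 10, TRUE), sample(0:15, 10, TRUE))
  u <- warp_displacement(w, vox)
  B <- dct_basis(K, 16)
  for (pt in 1:10) for (d in 1:3) {
    s <- 0
    for (k in 1:K) for (m in 1:K) for (n in 1:K)
      s <- s + coeffs[[d]][k, m, n] * B[vox[pt, 1] + 1, k] *
        B[vox[pt, 2] + 1, m] * B[vox[pt, 3] + 1, n]
    expect_equal(u[pt, d], s, tolerance = 1e-10)
  }
  expect_error(warp_displacement(w, cbind(20, 0, 0)), "outside")
})

test_that("single constant DCT coefficient gives a uniform displacement", {
  g <- centered_geometry(c(8, 10, 12), 2)
  cx <- array(0, c(2, 2, 2)); cx[1, 1, 1] <- 5
  z <- array(0, c(2, 2, 2))
  w <- dct_warp(affine_params(), list(cx, z, z), g)
  u <- warp_displacement(w, cbind(c(0, 3, 7), c(0, 5, 9), c(0, 6, 11)))
  expect_equal(u[, 1], rep(5 * sqrt(1 / (8 * 10 * 12)), 3), tolerance = 1e-12)
  expect_equal(u[, 2:3], matrix(0, 3, 2))
})

test_that("zero-coefficient warps reduce to their affine part", {
  g <- centered_geometry(c(12, 12, 12), 4)
  aff <- affine_params(rigid_params(c(3, -1, 2), c(0.1, 0, -0.05)),
                       scales = c(1.05, 0.97, 1))
  w <- zero_dct_warp(g, K = 6, affine_part = aff)
  f_warp <- compose_to_field(list(w), g)
  f_aff <- compose_to_field(list(aff), g)
  expect_equal(f_warp$coords_matrix, f_aff$coords_matrix, tolerance = 1e-12)
})

test_that("composed fields match single-matrix application", {
  g <- centered_geometry(c(10, 10, 10), 4)
  f_id <- compose_to_field(list(rigid_params()), g)
  expect_equal(f_id$coords_matrix, grid_world_coords(g))
  t1 <- rigid_params(translation = c(1, 2, 3))
  t2 <- rigid_params(translation = c(-4, 1, 0.5))
  f12 <- compose_to_field(list(t1, t2), g)
  expect_equal(f12$coords_matrix,
               grid_world_coords(g) + matrix(c(-3, 3, 3.5), 1000, 3, byrow = TRUE),
               tolerance = 1e-12)
  A <- affine_params(rigid_params(c(1, 2, 3), c(0.1, 0, 0.05)), scales = c(1.1, 1, 0.9))
  R <- rigid_params(c(-2, 0, 1), c(0, 0.2, 0))
  fc <- compose_to_field(list(A, R), g)
  M <- rigid_matrix(R) %*% affine_matrix(A)
  direct <- grid_world_coords(g) %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], 1000, 3, byrow = TRUE)
  expect_equal(fc$coords_matrix, direct, tolerance = 1e-9)
  expect_error(compose_to_field(list(), g), "nonempty")
})

test_that("transform chains serialize to JSON and back", {
  g <- centered_geometry(c(8, 8, 8), 4)
  set.seed(3)
  chain <- list(
    dct_warp(affine_params(), lapply(1:3, function(d) array(stats::rnorm(8), c(2, 2, 2))), g),
    affine_params(rigid_params(c(1, -2, 0.5), c(0.05, 0, 0.1)),
                  scales = c(1.02, 0.98, 1), shears = c(0.01, 0, -0.02)),
    rigid_params(c(4, 0, -1), c(0, 0.1, 0)))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_chain(chain, path, provenance = c(strategy = "test"))
  back <- read_transform_chain(path)
  expect_equal(length(back$chain), 3)
  f1 <- compose_to_field(chain, g)
  f2 <- compose_to_field(back$chain, g)
  expect_equal(f1$coords_matrix, f2$coords_matrix, tolerance = 1e-12)
  expect_match(back$provenance[["strategy"]], "test")
})
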