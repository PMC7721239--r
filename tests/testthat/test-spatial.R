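make_grid_affine <- function(d, vox = 1) {
  A <- diag(c(rep(vox, 3), 1))
  A[1:3, 4] <- -vox * (d - 1) / 2
  A
}

test_that("deformation resampling: identity, translation, nearest on masks", {
  d <- c(12, 12, 12)
  A <- make_grid_affine(d)
  set.seed(1)
  v <- volume3d(array(rnorm(prod(d)), d), A)
  zero <- array(0, d)
  f0 <- deformation_field(zero, zero, zero, A)
  out <- apply_deformation(v, f0)
  expect_equal(out$data, v$data, tolerance = 1e-12)
  expect_equal(attr(out, "n_outside"), 0)

  # translation by exactly one voxel along x
  f1 <- deformation_field(zero + 1, zero, zero, A)
  sh <- apply_deformation(v, f1)
  expect_equal(sh$data[1:11, , ], v$data[2:12, , ], tolerance = 1e-12)
  expect_true(all(sh$data[12, , ] == 0))   # outside -> 0
  expect_equal(attr(sh, "n_outside"), 144)

  mk <- volume3d(array(rbinom(prod(d), 1, 0.5), d), A, kind = "mask")
  half <- deformation_field(zero + 0.4, zero + 0.2, zero, A)
  nn <- apply_deformation(mk, half, interpolation = "nearest")
  expect_true(all(nn$data %in% c(0, 1)))

  bad <- f0; bad$dx[1] <- Inf
  expect_error(deformation_field(bad$dx, bad$dy, bad$dz, A), "finite")
})

test_that("jacobian determinants match analytic fields", {
  d <- c(16, 16, 16)
  A <- make_grid_affine(d)
  xyz <- neuraxis:::grid_world(d, A)
  zero <- array(0, d)
  jac0 <- jacobian_determinant(deformation_field(zero, zero, zero, A))
  expect_equal(jac0$data, array(1, d))

  # uniform 10% dilation: det = 1.1^3 in the interior
  f <- deformation_field(array(0.1 * xyz[, 1], d), array(0.1 * xyz[, 2], d),
                         array(0.1 * xyz[, 3], d), A)
  jac <- jacobian_determinant(f)
  expect_equal(jac$data[8, 8, 8], 1.1^3, tolerance = 1e-10)

  # shear field d = (0.05 y, 0.03 x, 0): det(I + grad d) = 1 - 0.0015
  fs <- deformation_field(array(0.05 * xyz[, 2], d),
                          array(0.03 * xyz[, 1], d), zero, A)
  js <- jacobian_determinant(fs)
  expect_equal(js$data[8, 8, 8], 1 - 0.05 * 0.03, tolerance = 1e-3)
})

test_that("modulation scales probabilities and conserves warped volume", {
  d <- c(32, 32, 32)
  A <- make_grid_affine(d)
  xyz <- neuraxis:::grid_world(d, A)
  # smooth, well-resolved blob: trilinear pull-back then loses < 1% mass
  rr <- sqrt(rowSums(xyz[, 1:3]^2))
  blob <- volume3d(array(exp(-rr^2 / 40), d), A, kind = "probability")
  jac1 <- volume3d(array(1, d), A, kind = "jacobian")
  expect_equal(modulate(blob, jac1)$data, blob$data)
  jach <- volume3d(array(0.5, d), A, kind = "jacobian")
  expect_equal(modulate(blob, jach)$data, blob$data * 0.5)

  # pull-back through a 5% contraction plus modulation conserves volume
  f <- deformation_field(array(0.05 * xyz[, 1], d),
                         array(0.05 * xyz[, 2], d),
                         array(0.05 * xyz[, 3], d), A)
  warped <- apply_deformation(blob, f)
  warped <- volume3d(pmin(pmax(warped$data, 0), 1), A,
                     kind = "probability")
  mod <- modulate(warped, jacobian_determinant(f))
  expect_lt(abs(sum(mod$data) / sum(blob$data) - 1), 0.01)
})

test_that("gaussian smoothing: identity at 0, unit mass, exact sigma", {
  expect_equal(fwhm_to_sigma(6), 2.5480, tolerance = 1e-4)
  d <- c(15, 15, 15)
  A <- make_grid_affine(d)
  set.seed(2)
  v <- volume3d(array(rnorm(prod(d)), d), A)
  expect_identical(gaussian_smooth(v, 0), v)

  delta <- array(0, d); delta[8, 8, 8] <- 1
  sm <- gaussian_smooth(volume3d(delta, A), 4)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)   # kernel normalised

  blob <- array(0, d); blob[6:10, 6:10, 6:10] <- 1
  smb <- gaussian_smooth(volume3d(blob, A), 3)
  expect_lt(abs(sum(smb$data) / sum(blob) - 1), 1e-3)  # mass preserved

  # sheared grids are rejected
  Ash <- A; Ash[1, 2] <- 0.3
  vs <- volume3d(array(0, d), Ash)
  expect_error(gaussian_smooth(vs, 4), "orthogonal")
})

test_that("vbq smoothing preserves constants and tissue-map scale invariance", {
  d <- c(16, 16, 16)
  A <- make_grid_affine(d)
  xyz <- neuraxis:::grid_world(d, A)
  rr <- sqrt(rowSums(xyz[, 1:3]^2))
  tis <- volume3d(array(as.numeric(rr < 4), d), A, kind = "probability")
  q <- volume3d(array(2.93, d), A, kind = "mt_pu")
  out <- vbq_smooth(q, tis, 6)
  expect_lt(max(abs(out$data - 2.93), na.rm = TRUE), 1e-6)

  # fwhm 0: qmap restricted to tissue support
  out0 <- vbq_smooth(q, tis, 0)
  expect_true(all(is.na(out0$data[tis$data == 0])))
  expect_true(all(out0$data[tis$data == 1] == 2.93))

  # scaling the tissue map by a positive constant changes nothing
  set.seed(3)
  qr_ <- volume3d(array(rnorm(prod(d), 2, 0.3), d), A, kind = "mt_pu")
  tis_scaled <- tis; tis_scaled$data <- tis$data * 0.37
  a <- vbq_smooth(qr_, tis, 5)
  b <- vbq_smooth(qr_, tis_scaled, 5)
  expect_equal(a$data, b$data, tolerance = 1e-10)

  allzero <- volume3d(array(0, d), A, kind = "probability")
  expect_error(vbq_smooth(q, allzero, 5), "all zero")
})

test_that("scale-space sweep returns one stack per FWHM", {
  d <- c(10, 10, 10)
  A <- make_grid_affine(d)
  set.seed(4)
  vols <- lapply(1:3, function(i)
    volume3d(array(rnorm(prod(d), 2, 0.1), d), A, kind = "mt_pu"))
  tis <- lapply(1:3, function(i)
    volume3d(array(0.8, d), A, kind = "probability"))
  sw <- scale_space_sweep(vols, tis, fwhms = 0:6)
  expect_length(sw, 7)
  expect_equal(attr(sw$fwhm_0, "fwhm"), 0)
  one <- scale_space_sweep(vols, tis, fwhms = 0)
  v1 <- vbq_smooth(vols[[1]], tis[[1]], 0)
  expect_equal(one$fwhm_0[, , , 1], v1$data)
  expect_error(scale_space_sweep(vols, tis, fwhms = c(3, 2)),
               "increasing")
})
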