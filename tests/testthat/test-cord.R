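test_that("binarize_nt applies an inclusive threshold and keeps the largest blob", {
  d <- c(12, 12, 4)
  nt <- array(0, d)
  nt[5:8, 5:8, ] <- 0.9
  nt[6, 6, 2] <- 0.5            # exactly at threshold, connected
  nt[1, 1, 1] <- 0.8            # 1-voxel speckle
  v <- volume3d(nt, diag(4), kind = "probability")
  m <- binarize_nt(v)
  expect_equal(m$data[6, 6, 2], 1)    # >= policy
  expect_equal(m$data[1, 1, 1], 0)    # speckle removed
  expect_equal(sum(m$data), 16 * 4)

  flat <- volume3d(array(0.4, d), diag(4), kind = "probability")
  expect_error(binarize_nt(flat), "z-range")
})

test_that("slice contours track an analytic disc to sub-voxel accuracy", {
  v <- disc_volume(n = 40, nz = 3, r = 4, vox = 0.5)
  ct <- slice_contour(v, 1)
  expect_true(ct$valid)
  rad <- sqrt(rowSums(ct$points^2))
  expect_true(all(abs(rad - 4) < 0.05))

  # all-background slice: invalid flag, not an error
  bg <- volume3d(array(0, c(8, 8, 2)), diag(4), kind = "probability")
  expect_false(slice_contour(bg, 0)$valid)
})

test_that("with several contours the longest perimeter wins", {
  d <- c(40, 40, 1)
  A <- diag(4); A[1:2, 4] <- -19.5
  xs <- -19.5 + 0:39
  big <- outer(xs, xs, function(x, y)
    pmin(1, pmax(0, 2 - sqrt((x + 8)^2 + y^2) / 3)))
  small <- outer(xs, xs, function(x, y)
    pmin(1, pmax(0, 2 - sqrt((x - 10)^2 + y^2) / 1.2)))
  v <- volume3d(array(pmax(big, small), d), A, kind = "probability")
  ct <- slice_contour(v, 0)
  expect_true(ct$valid)
  ctr <- colMeans(ct$points[-nrow(ct$points), ])
  expect_lt(abs(ctr[1] - (-8)), 0.5)   # picked the big blob
})

test_that("ellipse fits are exact on noise-free conics", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  fc <- fit_ellipse(cbind(4 * cos(th) + 2, 4 * sin(th) - 1))
  expect_equal(fc$semi_a, 4, tolerance = 1e-9)
  expect_equal(fc$semi_b, 4, tolerance = 1e-9)
  expect_lt(fc$residual, 1e-9)
  expect_equal(fc$center, c(2, -1), tolerance = 1e-9)

  fe <- fit_ellipse(cbind(5 * cos(th), 3.5 * sin(th)))
  sm <- slice_metrics(fe, 0)
  expect_equal(sm$sca, pi * 17.5, tolerance = 1e-9)
  expect_equal(sm$lrw, 10, tolerance = 1e-9)
  expect_equal(sm$apw, 7, tolerance = 1e-9)

  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))), "degenerate|collinear")
  expect_error(fit_ellipse(cbind(1:4, c(1, 2, 1, 2))), "at least 5")
})

test_that("noisy ellipse axes are recovered within 2% over 100 replicates", {
  th <- seq(0, 2 * pi, length.out = 81)[-81]
  a_hat <- b_hat <- numeric(100)
  set.seed(7)
  for (r in 1:100) {
    pts <- cbind(5 * cos(th), 3.5 * sin(th)) + matrix(rnorm(160, 0, 0.1),
                                                      ncol = 2)
    f <- fit_ellipse(pts)
    a_hat[r] <- f$semi_a; b_hat[r] <- f$semi_b
  }
  expect_lt(abs(mean(a_hat) / 5 - 1), 0.02)
  expect_lt(abs(mean(b_hat) / 3.5 - 1), 0.02)
  expect_lt(max(abs(a_hat / 5 - 1)), 0.02)
  expect_lt(max(abs(b_hat / 3.5 - 1)), 0.02)
})

test_that("widths respond to tilt as extents along anatomical axes", {
  f <- list(center = c(0, 0), semi_a = 5, semi_b = 3.5, tilt = 0,
            residual = 0, n_points = 40)
  class(f) <- "ellipse_fit"
  sm0 <- slice_metrics(f, 0)
  expect_equal(c(sm0$lrw, sm0$apw), c(10, 7))
  f$tilt <- pi / 2
  sm90 <- slice_metrics(f, 0)
  expect_equal(c(sm90$lrw, sm90$apw), c(7, 10), tolerance = 1e-12)
  f$tilt <- pi / 4; f$semi_a <- 4; f$semi_b <- 4
  sm45 <- slice_metrics(f, 0)
  expect_equal(c(sm45$lrw, sm45$apw), c(8, 8), tolerance = 1e-12)
})

test_that("cord summaries recover phantom truth and ignore values outside the mask", {
  spec <- phantom_spec(dim = c(32L, 32L, 8L), cord_z = c(0L, 7L),
                       subject_area_cv = 0, intensity_noise_sd = 0,
                       qmap_noise_sd = c(mt = 0, r1 = 0, r2star = 0))
  s <- make_subject(spec, "control", 1)
  nt <- combine_nt(s$truth)
  cs <- cord_summary(nt, s$qmaps, z_range = spec$cord_z)
  expect_lt(abs(cs$summary$mean_sca / s$truth_metrics$mean_sca - 1), 0.02)
  expect_lt(abs(cs$summary$mean_apw / s$truth_metrics$mean_apw - 1), 0.02)
  expect_lt(abs(cs$summary$mean_lrw / s$truth_metrics$mean_lrw - 1), 0.02)
  expect_equal(cs$summary$n_valid_slices, 8)

  # masked qmap means are invariant to values outside the mask
  mask <- binarize_nt(nt, z_range = spec$cord_z)
  mt2 <- s$qmaps$mt
  mt2$data[mask$data == 0] <- 999
  cs2 <- cord_summary(nt, list(mt = mt2), z_range = spec$cord_z)
  expect_equal(cs2$summary$mt, cs$summary$mt)

  # uniform MT inside the cord: masked mean is that constant
  mt3 <- s$qmaps$mt
  mt3$data[mask$data == 1] <- 2.93
  cs3 <- cord_summary(nt, list(mt = mt3), z_range = spec$cord_z)
  expect_equal(cs3$summary$mt, 2.93)
})

test_that("morphometric bias shrinks as voxels shrink", {
  err <- sapply(c(1, 0.5), function(vx) {
    n <- as.integer(28 / vx)
    spec <- phantom_spec(dim = c(n, n, 4L), vox = rep(vx, 3),
                         cord_z = c(0L, 3L), cord_taper = 0, cord_bow = 0,
                         subject_area_cv = 0, cord_a_lr = 4, cord_b_ap = 3)
    s <- make_subject(spec, "control", 1)
    nt <- combine_nt(s$truth)
    cs <- cord_summary(nt, z_range = spec$cord_z)
    abs(cs$summary$mean_sca / s$truth_metrics$mean_sca - 1)
  })
  expect_lt(err[1], 0.02)
  expect_lt(err[2], err[1] + 1e-12)
})

test_that("group cord ROI uses a strict threshold on the mean NT map", {
  d <- c(8, 8, 4)
  a <- array(0, d); b <- array(0, d)
  a[4, 4, ] <- 1; b[4, 4, ] <- 1       # mean 1 -> in
  a[5, 5, ] <- 1; b[5, 5, ] <- 0       # mean 0.5 exactly -> out
  va <- volume3d(a, diag(4), kind = "probability")
  vb <- volume3d(b, diag(4), kind = "probability")
  roi <- group_cord_roi(list(va, vb), z_range = c(0, 3))
  expect_equal(roi$data[4, 4, 1], 1)
  expect_equal(roi$data[5, 5, 1], 0)
  # identical maps: ROI equals the single-subject strict superlevel set
  roi2 <- group_cord_roi(list(va, va), z_range = c(0, 3))
  expect_equal(roi2$data, array(as.numeric(a > 0.5), d))
  # disjoint cords: empty ROI warns
  c2 <- array(0, d); c2[1, 1, ] <- 1
  vc <- volume3d(c2, diag(4), kind = "probability")
  expect_warning(group_cord_roi(list(va, vc), z_range = c(0, 3)), "empty")
})

test_that("percent group difference matches its definition and rounding", {
  expect_equal(percent_group_difference(71.05, 65.91), 7.23)
  expect_equal(percent_group_difference(2.93, 2.69), 8.19)
  expect_equal(percent_group_difference(5, 5), 0)
  expect_error(percent_group_difference(0, 1), "nonzero")
})
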