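test_that("design matrices encode groups, centred covariates and contrasts", {
  covs <- as_covariate_table(data.frame(
    subject_id = sprintf("s%d", 1:6),
    group = rep(c("control", "patient"), each = 3),
    age = c(30, 45, 52, 28, 61, 39),
    gender = c("f", "m", "f", "m", "f", "m"),
    scanner = c("A", "A", "B", "B", "A", "B"),
    stringsAsFactors = FALSE))
  des <- build_design(covs)
  expect_equal(des$n, 6)
  expect_equal(des$df_error, 6 - qr(des$X)$rank)
  expect_true(all(c("control", "patient") %in% des$regressors))
  expect_equal(sum(des$contrasts$control_gt_patient), 0)
  expect_equal(abs(des$X[, "control"] + des$X[, "patient"]),
               rep(1, 6))                      # intercept-free two-group
  expect_equal(mean(des$X[, "age"]), 0, tolerance = 1e-12)

  # constant scanner column dropped with a warning
  covs2 <- covs; covs2$scanner <- factor(rep("A", 6))
  expect_warning(build_design(covs2), "scanner")

  # collinear covariate raises a rank error naming a column
  covs3 <- as.data.frame(covs)
  covs3$tiv <- covs3$age * 2
  expect_error(suppressWarnings(build_design(as_covariate_table(covs3))),
               "rank deficient")

  # score model: subject with missing score is excluded
  covs4 <- as.data.frame(toy_covariates(4))
  covs4$scim <- c(10, 20, NA, 40, 15, 25, 35, 45)
  expect_message(des4 <- build_design(as_covariate_table(covs4),
                                      model = "score_assoc",
                                      score_name = "scim"),
                 "excluding 1")
  expect_equal(des4$n, 7)
  expect_true("intercept" %in% des4$regressors)
})

test_that("the covariate-free GLM t-map equals the pooled two-sample t", {
  set.seed(11)
  d <- c(4, 4, 4); n <- 20
  covs <- toy_covariates(10)
  des <- build_design(covs, covariates = character(0))
  stack <- array(rnorm(prod(d) * n, 5, 2), c(d, n))
  attr(stack, "affine") <- diag(4)
  stat <- glm_t_map(stack, des, fwhm = 1)
  g <- covs$group
  for (idx in list(c(1, 1, 1), c(2, 3, 4), c(4, 4, 4))) {
    y <- stack[idx[1], idx[2], idx[3], ]
    tt <- t.test(y[g == "control"], y[g == "patient"], var.equal = TRUE)
    expect_equal(stat$t$data[idx[1], idx[2], idx[3]],
                 unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(stat$df, 18)

  # zero-variance voxels are masked out, not reported
  stack[1, 1, 1, ] <- 7
  attr(stack, "affine") <- diag(4)
  stat2 <- glm_t_map(stack, des, fwhm = 1)
  expect_true(is.na(stat2$t$data[1, 1, 1]))
  expect_equal(stat2$mask$data[1, 1, 1], 0)
})

test_that("a contrast orthogonal to the effect stays centred at zero", {
  set.seed(12)
  covs <- toy_covariates(8)
  des <- build_design(covs, covariates = character(0))
  d <- c(3, 3, 3)
  tbar <- replicate(60, {
    stack <- array(rnorm(prod(d) * 16), c(d, 16))
    # inject an effect common to both groups (orthogonal to the contrast)
    stack <- stack + array(rep(2, prod(d) * 16), c(d, 16))
    attr(stack, "affine") <- diag(4)
    mean(glm_t_map(stack, des, fwhm = 1)$t$data)
  })
  expect_lt(abs(mean(tbar)), 3 * sd(tbar) / sqrt(length(tbar)) + 0.05)
})

test_that("smoothness estimation recovers known kernels", {
  set.seed(13)
  d <- c(20, 20, 20)
  mask <- array(TRUE, d)
  # white noise: estimate clamps at the voxel size
  wn <- array(rnorm(prod(d) * 10), c(d, 10))
  fw <- estimate_smoothness(wn, mask, vox = c(1, 1, 1))
  expect_true(all(abs(fw - 1) < 0.15))

  # pre-smoothed noise at 6 mm on a 2 mm grid: recover within 15%
  sigma <- fwhm_to_sigma(6) / 2     # in voxels
  pad <- 8; big <- d + 2 * pad; sel <- lapply(d, function(n) pad + 1:n)
  sm <- array(NA_real_, c(d, 8))
  for (j in 1:8) {
    f <- neuraxis:::smooth_array(array(rnorm(prod(big)), big),
                                 rep(sigma, 3))
    sm[, , , j] <- f[sel[[1]], sel[[2]], sel[[3]]]
  }
  fw6 <- estimate_smoothness(sm, mask, vox = c(2, 2, 2))
  expect_true(all(abs(fw6 / 6 - 1) < 0.15))

  # anisotropic smoothing recovered per axis
  anis <- array(NA_real_, c(d, 8))
  for (j in 1:8) {
    f <- neuraxis:::smooth_array(array(rnorm(prod(big)), big),
                                 c(2.5, 1.2, 0.8))
    anis[, , , j] <- f[sel[[1]], sel[[2]], sel[[3]]]
  }
  fwa <- estimate_smoothness(anis, mask, vox = c(1, 1, 1))
  expected <- 2 * sqrt(2 * log(2)) * c(2.5, 1.2, 0.8)
  expect_true(all(abs(fwa / expected - 1) < 0.15))

  expect_error(estimate_smoothness(wn, array(FALSE, d)), "mask too small")
})

test_that("resel counts are exact for box regions", {
  m <- array(TRUE, c(10, 8, 6))
  r <- resel_counts(m, vox = c(1, 1, 1), fwhm = c(2, 2, 2))
  f <- c(9, 7, 5) / 2
  expect_equal(unname(r), c(1, sum(f), f[1] * f[2] + f[1] * f[3] +
                              f[2] * f[3], prod(f)))
  # single voxel: R0 = 1, higher orders 0
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(unname(resel_counts(one, c(1, 1, 1), 3)), c(1, 0, 0, 0))
})

test_that("peak FWE p-values behave as RFT prescribes", {
  resels <- resel_counts(array(TRUE, c(16, 16, 16)), c(1, 1, 1), 4)
  ts <- seq(3, 10, by = 0.25)
  ps <- vapply(ts, rft_p_fwe, numeric(1), resels = resels, df = 20)
  expect_true(all(diff(ps) <= 0))           # monotone non-increasing
  expect_true(all(diff(ps[ps < 1]) < 0))    # strictly below the clamp
  expect_true(all(ps > 0 & ps <= 1))
  thr <- rft_threshold(resels, df = 20, alpha = 0.05)
  expect_equal(rft_p_fwe(thr, resels, 20), 0.05, tolerance = 1e-6)

  # single-voxel ROI: corrected p equals the uncorrected upper tail
  r1 <- c(1, 0, 0, 0)
  expect_equal(rft_p_fwe(3.2, r1, 20), pt(3.2, 20, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("peak tables report sorted local maxima with z-equivalents", {
  d <- c(12, 12, 12)
  set.seed(14)
  covs <- toy_covariates(8)
  des <- build_design(covs, covariates = character(0))
  stack <- array(rnorm(prod(d) * 16), c(d, 16))
  eff <- array(0, d); eff[4, 4, 4] <- 3; eff[9, 9, 9] <- 2
  for (s in 1:8) stack[, , , s] <- stack[, , , s] + eff
  attr(stack, "affine") <- diag(4)
  stat <- glm_t_map(stack, des, fwhm = 2)
  roi <- volume3d(array(1, d), diag(4), kind = "mask")
  pk <- rft_peak_fwe(stat, roi)
  expect_true(all(diff(pk$t) <= 0))
  expect_true(all(pk$p_fwe > 0 & pk$p_fwe <= 1))
  expect_true(all(pk$z <= 8))
  expect_equal(pk$x_mm[1], 3)   # strongest effect at voxel (4,4,4), 0-based
  empty <- volume3d(array(0, d), diag(4), kind = "mask")
  expect_error(rft_peak_fwe(stat, empty), "empty ROI")
})

test_that("ANCOVA reduces to the two-sample t-test without informative covariates", {
  set.seed(15)
  n <- 16
  covs <- as_covariate_table(data.frame(
    subject_id = sprintf("s%d", 1:n),
    group = rep(c("control", "patient"), each = n / 2),
    age = rep(40, n), gender = rep("f", n), scanner = rep("A", n),
    stringsAsFactors = FALSE))
  y <- rnorm(n, 70, 5) - 3 * (covs$group == "patient")
  res <- suppressWarnings(ancova_metric(y, covs))
  tt <- t.test(y[covs$group == "control"], y[covs$group == "patient"],
               var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$effect, unname(diff(rev(tt$estimate))),
               tolerance = 1e-12)
  # sign convention: controls above patients -> positive effect
  expect_gt(res$effect, 0)
  expect_equal(unname(res$adjusted_means["control"] -
                        res$adjusted_means["patient"]),
               res$effect, tolerance = 1e-12)
  expect_error(ancova_metric(y[1:5], covs[1:5, ]), ">= 3")
})

test_that("ICC(A,1) matches a brute-force ANOVA oracle on random matrices", {
  set.seed(16)
  for (i in 1:100) {
    m <- matrix(rnorm(10, sd = runif(1, 0.5, 3)) +
                  rep(rnorm(5, sd = 2), 2), 5, 2)
    m[, 2] <- m[, 2] + rnorm(1, 0, 1)     # method offset
    expect_equal(icc_a1(m)$icc, icc_a1_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC edge behaviour: perfect agreement, offsets, categories", {
  m <- cbind(1:6, 1:6)
  r <- icc_a1(m)
  expect_equal(r$icc, 1)
  expect_identical(r$category, "excellent")

  # large constant offset: absolute agreement penalised
  off <- cbind(1:6, 1:6 + 100)
  expect_lt(icc_a1(off)$icc, 0.01)

  # independent noise columns: ICC near 0 on average
  set.seed(17)
  iccs <- replicate(200, icc_a1(matrix(rnorm(12), 6, 2))$icc)
  expect_lt(abs(mean(iccs)), 0.1)

  # category boundaries honoured exactly at 0.5 / 0.75 / 0.9: bisect a
  # noise scale to straddle each threshold
  base <- rep(rnorm(8, sd = 2), 2)
  noise <- rnorm(16)
  icc_at <- function(l) icc_a1(matrix(base + l * noise, 8, 2))$icc
  for (thr in c(0.5, 0.75, 0.9)) {
    lam <- uniroot(function(l) icc_at(l) - thr, c(1e-6, 10),
                   tol = 1e-12)$root
    below <- icc_a1(matrix(base + (lam + 1e-6) * noise, 8, 2))
    above <- icc_a1(matrix(base + (lam - 1e-6) * noise, 8, 2))
    expect_lt(below$icc, thr); expect_gte(above$icc, thr)
    expect_false(identical(below$category, above$category))
  }

  expect_error(icc_a1(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)), "missing")
  expect_error(icc_a1(matrix(1:4, 2, 2)), "at least 3")
})

test_that("roi_mean_table averages maps inside ROIs per subject and method", {
  d <- c(6, 6, 6)
  roi <- array(0, d); roi[2:3, 2:3, 2:3] <- 1
  rois <- list(cube = volume3d(roi, diag(4), kind = "mask"))
  mk <- function(val) volume3d(array(val, d), diag(4))
  maps <- list(a = list(mk(1), mk(2), mk(3)),
               b = list(mk(1), mk(2), mk(3)))
  tab <- roi_mean_table(maps, rois)
  expect_equal(tab$cube[, "a"], c(1, 2, 3))
  # identical methods give ICC 1 downstream
  expect_equal(icc_a1(tab$cube)$icc, 1)
  empty <- list(none = volume3d(array(0, d), diag(4), kind = "mask"))
  expect_error(roi_mean_table(maps, empty), "empty ROI")
})
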