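# Hand-crafted NIfTI-1 writer used to exercise scl_slope/scl_inter and 4D
# handling without relying on the reader's own writer.
write_raw_nifti <- function(path, data_int16, dims, slope = 1, inter = 0,
                            ndim = 3L, n_t = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(c(ndim, dims, n_t, 1L, 1L, 1L)), con, size = 2)
  writeBin(raw(14), con)
  writeBin(4L, con, size = 2)     # datatype int16
  writeBin(16L, con, size = 2)    # bitpix
  writeBin(0L, con, size = 2)
  writeBin(c(1, 1, 1, 1, 1, 0, 0, 0), con, size = 4)
  writeBin(352, con, size = 4)
  writeBin(as.numeric(slope), con, size = 4)
  writeBin(as.numeric(inter), con, size = 4)
  writeBin(raw(224), con)
  writeBin("n+1", con)
  writeBin(raw(4), con)
  writeBin(as.integer(data_int16), con, size = 2)
  invisible(path)
}

# analytic supersampled disc probability volume: per-voxel fraction inside a
# circle of radius r (mm), on nz identical slices
disc_volume <- function(n = 32, nz = 3, r = 4, vox = 1, ss = 5) {
  A <- diag(c(vox, vox, vox, 1))
  A[1, 4] <- -vox * (n - 1) / 2
  A[2, 4] <- -vox * (n - 1) / 2
  xs <- A[1, 4] + vox * (0:(n - 1))
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * vox
  acc <- matrix(0, n, n)
  for (ox in offs) for (oy in offs)
    acc <- acc + outer(xs + ox, xs + oy,
                       function(x, y) as.numeric(x^2 + y^2 <= r^2))
  sl <- acc / ss^2
  volume3d(array(rep(sl, nz), c(n, n, nz)), A, kind = "probability")
}

# small cord-only phantom spec used by simulation-heavy checks; defaults
# can be overridden
metric_spec <- function(...) {
  args <- utils::modifyList(list(dim = c(24L, 24L, 10L),
                                 cord_z = c(0L, 9L), n_per_group = 10L),
                            list(...))
  do.call(phantom_spec, args)
}

# textbook 2-component GMM EM (independent oracle for prior-weighted
# segmentation with flat priors); deterministic k-means-style init
gmm2_oracle <- function(y, max_iter = 500, tol = 1e-12) {
  mu <- c(min(y), max(y))
  s2 <- rep(var(y) / 4, 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    r <- cbind(w[1] * dnorm(y, mu[1], sqrt(s2[1])),
               w[2] * dnorm(y, mu[2], sqrt(s2[2])))
    ll <- sum(log(rowSums(r)))
    r <- r / rowSums(r)
    nk <- colSums(r)
    mu <- colSums(r * y) / nk
    s2 <- colSums(r * (y - rep(mu, each = length(y)))^2) / nk
    w <- nk / length(y)
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(z = r, mean = mu, var = s2, weight = w)
}

# brute-force ICC(A,1) through stats::aov mean squares (independent oracle)
icc_a1_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   row = factor(rep(seq_len(n), times = k)),
                   col = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ row + col, data = df))[[1]]
  msr <- tab["row", "Mean Sq"]
  msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

toy_covariates <- function(n_per_group = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  as_covariate_table(data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", "patient"), each = n_per_group),
    age = round(runif(n, 20, 70), 1),
    gender = sample(c("f", "m"), n, replace = TRUE),
    scanner = sample(c("A", "B"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}
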