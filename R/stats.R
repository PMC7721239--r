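#' Build a GLM design matrix from a covariate table
#'
#' For `model = "group_diff"`: intercept-free two-group encoding (one
#' indicator column per group) plus mean-centred continuous covariates
#' (age, and TIV when present) and 0/1 indicator columns for gender and
#' scanner (first level = 0); the default contrast is control minus
#' patient (and its reverse). For `model = "score_assoc"`: intercept +
#' the (mean-centred) clinical score + the same covariates, contrast on
#' the score. Constant covariate columns are dropped with a warning;
#' subjects with missing values in used columns are excluded and reported.
#'
#' @param covs a `covariate_table`.
#' @param model `"group_diff"` or `"score_assoc"`.
#' @param score_name clinical score column (required for
#'   `"score_assoc"`).
#' @param include_tiv include TIV as a covariate when a `tiv` column is
#'   present (default TRUE).
#' @param covariates nuisance covariates to include (default age, gender,
#'   scanner); pass `character(0)` for a covariate-free model.
#' @return list of class `design_matrix`: `X`, `regressors`, `contrasts`
#'   (named list of vectors), `df_error`, `n`, `subjects` (ids used).
#' @export
build_design <- function(covs, model = c("group_diff", "score_assoc"),
                         score_name = NULL, include_tiv = TRUE,
                         covariates = c("age", "gender", "scanner")) {
  model <- match.arg(model)
  covs <- as.data.frame(covs)
  used <- covariates
  if (include_tiv && "tiv" %in% names(covs)) used <- c(used, "tiv")
  if (model == "score_assoc") {
    if (is.null(score_name) || !score_name %in% names(covs))
      stop("build_design: score_assoc requires an existing score column")
    used <- c(used, score_name)
  }
  keep <- complete.cases(covs[, used, drop = FALSE])
  if (!all(keep))
    message("build_design: excluding ", sum(!keep),
            " subject(s) with missing values: ",
            paste(covs$subject_id[!keep], collapse = ", "))
  covs <- covs[keep, , drop = FALSE]
  n <- nrow(covs)

  cols <- list()
  cn <- character(0)
  if (model == "group_diff") {
    cols$control <- as.numeric(covs$group == "control")
    cols$patient <- as.numeric(covs$group == "patient")
    cn <- c("control", "patient")
  } else {
    cols$intercept <- rep(1, n)
    sc <- covs[[score_name]]
    cols$score <- sc - mean(sc)
    cn <- c("intercept", "score")
  }
  add_num <- function(name, v) {
    if (sd(v) < 1e-12) {
      warning("build_design: dropping constant covariate '", name, "'")
      return(invisible(NULL))
    }
    cols[[name]] <<- v - mean(v)
    cn <<- c(cn, name)
  }
  add_ind <- function(name, f) {
    v <- as.numeric(f != levels(factor(f))[1])
    if (sd(v) < 1e-12) {
      warning("build_design: dropping constant covariate '", name, "'")
      return(invisible(NULL))
    }
    cols[[name]] <<- v - mean(v)
    cn <<- c(cn, name)
  }
  if ("age" %in% covariates) add_num("age", covs$age)
  if ("gender" %in% covariates) add_ind("gender", covs$gender)
  if ("scanner" %in% covariates) add_ind("scanner", covs$scanner)
  if (include_tiv && "tiv" %in% names(covs)) add_num("tiv", covs$tiv)

  X <- do.call(cbind, cols[cn])
  colnames(X) <- cn
  r <- qr(X)$rank
  if (r < ncol(X)) {
    # identify an offending column for the message
    bad <- cn[which(!(cn %in% cn[qr(X)$pivot[seq_len(r)]]))]
    stop("build_design: design matrix is rank deficient (collinear: ",
         paste(bad, collapse = ", "), ")")
  }
  contrasts <- if (model == "group_diff") {
    cvec <- setNames(numeric(ncol(X)), cn)
    cvec["control"] <- 1; cvec["patient"] <- -1
    list(control_gt_patient = cvec, patient_gt_control = -cvec)
  } else {
    cvec <- setNames(numeric(ncol(X)), cn)
    cvec["score"] <- 1
    list(score_pos = cvec, score_neg = -cvec)
  }
  structure(list(X = X, regressors = cn, contrasts = contrasts,
                 df_error = n - r, n = n, subjects = covs$subject_id),
            class = "design_matrix")
}

#' Voxel-wise GLM t-map
#'
#' Ordinary least squares at every voxel:
#' `t = c' beta / sqrt(sigma2 * c' (X'X)^-1 c)` with `df = n - rank(X)`.
#' The analysis mask is the set of voxels with finite values for all
#' subjects and non-zero residual variance. Residual smoothness (FWHM per
#' axis, mm) is estimated from the standardised residuals and stored for
#' random field theory.
#'
#' @param stack 4D array (x, y, z, subject) with attribute `affine` (as
#'   produced by [scale_space_sweep()]), or a list of per-subject
#'   `volume3d`s in design order.
#' @param design a [build_design()] result; subject order must match.
#' @param contrast contrast vector, or the name of one of the design's
#'   contrasts.
#' @param fwhm optional known smoothness (per-axis mm); when supplied the
#'   residual-based estimate is skipped.
#' @return list of class `stat_map`: `t` (`volume3d`, NA outside mask),
#'   `df`, `fwhm` (per-axis mm), `mask` (`volume3d`), `n`.
#' @export
glm_t_map <- function(stack, design, contrast = "control_gt_patient",
                      fwhm = NULL) {
  if (is.list(stack) && is_volume3d(stack[[1]])) {
    aff <- stack[[1]]$affine
    stack4 <- array(NA_real_, c(dim(stack[[1]]$data), length(stack)))
    for (s in seq_along(stack)) stack4[, , , s] <- stack[[s]]$data
    attr(stack4, "affine") <- aff
    stack <- stack4
  }
  aff <- attr(stack, "affine")
  if (is.null(aff)) stop("glm_t_map: stack needs an 'affine' attribute")
  d4 <- dim(stack)
  if (d4[4] != design$n)
    stop("glm_t_map: stack has ", d4[4], " subjects but design has ",
         design$n)
  if (is.character(contrast)) contrast <- design$contrasts[[contrast]]
  cvec <- as.numeric(contrast)
  X <- design$X
  nvox <- prod(d4[1:3])
  Y <- t(matrix(stack, nrow = nvox, ncol = d4[4]))   # subjects x voxels
  mask <- colSums(!is.finite(Y)) == 0
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)
  df <- design$df_error
  tvals <- rep(NA_real_, nvox)
  known_fwhm <- fwhm
  fwhm <- NULL
  if (any(mask)) {
    Ym <- Y[, mask, drop = FALSE]
    B <- H %*% Ym
    R <- Ym - X %*% B
    rss <- colSums(R^2)
    sigma2 <- rss / df
    zero_var <- sigma2 <= 1e-24
    se <- sqrt(sigma2 * as.numeric(t(cvec) %*% XtXinv %*% cvec))
    tv <- as.numeric(cvec %*% B) / se
    tv[zero_var] <- NA_real_
    tvals[mask] <- tv
    mask[mask] <- !zero_var
    if (is.null(known_fwhm)) {
      # smoothness from standardised residuals inside the final mask
      rfull <- matrix(NA_real_, nrow = d4[4], ncol = nvox)
      rfull[, which(mask)] <- R[, !zero_var, drop = FALSE]
      resid4 <- array(t(rfull), d4)
      mask_arr <- array(mask, d4[1:3])
      fwhm <- tryCatch(
        estimate_smoothness(resid4, mask_arr,
                            vox = sqrt(colSums(aff[1:3, 1:3]^2))),
        error = function(e) sqrt(colSums(aff[1:3, 1:3]^2)))
    } else {
      fwhm <- if (length(known_fwhm) == 1) rep(known_fwhm, 3)
              else known_fwhm
    }
  }
  if (!any(mask)) stop("glm_t_map: empty analysis mask")
  tvol <- volume3d_allow_na(array(tvals, d4[1:3]), aff, "tstat", "")
  maskvol <- volume3d(array(as.numeric(mask), d4[1:3]), aff, kind = "mask")
  structure(list(t = tvol, df = df, fwhm = fwhm, mask = maskvol,
                 n = d4[4]),
            class = "stat_map")
}

#' Estimate residual field smoothness (FWHM per axis)
#'
#' Standard resel estimator: residuals are standardised voxel-wise (unit
#' sum of squares across volumes), the variance of their spatial forward
#' differences gives the lag-one autocorrelation
#' `rho = 1 - s^2 / 2` per axis, and a Gaussian autocorrelation model maps
#' it to `FWHM = step * 2 sqrt(2 ln 2) / (2 sqrt(-ln rho))`. Estimates are
#' clamped below at one voxel size.
#'
#' @param residuals 4D array (x, y, z, volume), >= 2 volumes.
#' @param mask 3D logical/0-1 array of analysis voxels (>= 27 voxels).
#' @param vox voxel sizes in mm (length 3).
#' @return FWHM per axis in mm (length 3).
#' @export
estimate_smoothness <- function(residuals, mask, vox = c(1, 1, 1)) {
  d4 <- dim(residuals)
  if (length(d4) != 4 || d4[4] < 2)
    stop("estimate_smoothness: need a 4D residual stack with >= 2 volumes")
  mask <- array(as.logical(mask), d4[1:3])
  if (sum(mask) < 27)
    stop("estimate_smoothness: mask too small (", sum(mask), " voxels)")
  rm_ <- matrix(residuals, prod(d4[1:3]), d4[4])
  ss <- sqrt(rowSums(rm_^2))
  ss[ss == 0 | !is.finite(ss)] <- NA
  U <- array(rm_ / ss, d4)             # standardised residuals
  fwhm <- numeric(3)
  for (ax in 1:3) {
    n <- d4[ax]
    if (n < 2) { fwhm[ax] <- vox[ax]; next }
    idx_lo <- lapply(d4[1:3], seq_len); idx_hi <- idx_lo
    idx_lo[[ax]] <- seq_len(n - 1); idx_hi[[ax]] <- seq_len(n - 1) + 1
    pair_mask <- mask[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]] &
      mask[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]]
    # per pair: sum the squared differences of the standardised residuals
    # over volumes (the voxel-wise normalisation makes that sum estimate
    # 2(1 - rho) directly), then average over pairs
    tot <- 0
    for (v in seq_len(d4[4])) {
      Uv <- U[, , , v]
      dU <- Uv[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] -
        Uv[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]
      tot <- tot + dU^2
    }
    vals <- tot[pair_mask]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) { fwhm[ax] <- vox[ax]; next }
    rho <- 1 - mean(vals) / 2
    if (rho <= 0) { fwhm[ax] <- vox[ax]; next }
    fwhm[ax] <- vox[ax] * 2 * sqrt(2 * log(2)) / (2 * sqrt(-log(rho)))
  }
  pmax(fwhm, vox)
}

#' Resel counts of a region of interest
#'
#' Worsley lattice (voxel-counting) approximation: points, edges, faces
#' and cubes of the ROI's voxel lattice combined with the per-axis
#' voxel-to-FWHM ratios give the d-dimensional resel counts R0..R3.
#'
#' @param mask 3D logical/0-1 ROI array.
#' @param vox voxel sizes mm (length 3).
#' @param fwhm smoothness FWHM mm (length 3, or scalar).
#' @return numeric length-4 vector `c(R0, R1, R2, R3)`.
#' @export
resel_counts <- function(mask, vox, fwhm) {
  if (length(fwhm) == 1) fwhm <- rep(fwhm, 3)
  m <- array(as.logical(mask), dim(mask))
  d <- dim(m)
  shift_and <- function(a, axes) {
    out <- a
    for (ax in axes) {
      idx_lo <- lapply(dim(a), seq_len); idx_hi <- idx_lo
      idx_lo[[ax]] <- seq_len(dim(a)[ax] - 1)
      idx_hi[[ax]] <- seq_len(dim(a)[ax] - 1) + 1
      out <- out[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]], drop = FALSE] &
        out[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]], drop = FALSE]
      # note: after first shrink, recompute index templates on new dims
      a <- out
      idx_lo <- NULL
    }
    out
  }
  P <- sum(m)
  Ex <- sum(shift_and(m, 1)); Ey <- sum(shift_and(m, 2))
  Ez <- sum(shift_and(m, 3))
  Fxy <- sum(shift_and(m, c(1, 2))); Fxz <- sum(shift_and(m, c(1, 3)))
  Fyz <- sum(shift_and(m, c(2, 3)))
  C <- sum(shift_and(m, c(1, 2, 3)))
  r <- vox / fwhm
  R0 <- P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C
  R1 <- (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
    (Ez - Fxz - Fyz + C) * r[3]
  R2 <- (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] +
    (Fyz - C) * r[2] * r[3]
  R3 <- C * r[1] * r[2] * r[3]
  c(R0 = R0, R1 = R1, R2 = R2, R3 = R3)
}

# Euler characteristic densities of a t-field (d = 0..3)
ec_density_t <- function(t, df, d) {
  a <- 4 * log(2)
  cc <- (1 + t^2 / df)^((1 - df) / 2)
  switch(d + 1,
         pt(t, df, lower.tail = FALSE),
         sqrt(a) / (2 * pi) * cc,
         a / (2 * pi)^1.5 * cc * t / sqrt(df / 2) *
           exp(lgamma((df + 1) / 2) - lgamma(df / 2)),
         a^1.5 / (2 * pi)^2 * cc * ((df - 1) * t^2 / df - 1))
}

#' Peak-level FWE-corrected p-value for a t threshold
#'
#' Expected-Euler-characteristic bound
#' `p = min(1, sum_d R_d rho_d(t))` with t-field EC densities at the map's
#' degrees of freedom.
#'
#' @param t peak height.
#' @param resels R0..R3 resel counts of the search region.
#' @param df error degrees of freedom.
#' @return corrected p-value in (0, 1].
#' @export
rft_p_fwe <- function(t, resels, df) {
  p <- sum(vapply(0:3, function(d) resels[d + 1] * ec_density_t(t, df, d),
                  numeric(1)))
  min(1, max(p, .Machine$double.xmin))
}

#' RFT peak-FWE threshold
#'
#' The t threshold at which the expected-EC corrected p equals `alpha`.
#'
#' @param resels R0..R3 resel counts.
#' @param df degrees of freedom.
#' @param alpha target FWE level (default 0.05).
#' @return t threshold.
#' @export
rft_threshold <- function(resels, df, alpha = 0.05) {
  # the expected-EC bound is only monotone in its decreasing tail; bracket
  # from the largest t still above alpha
  ts <- seq(0.5, 100, by = 0.25)
  pv <- vapply(ts, rft_p_fwe, numeric(1), resels = resels, df = df)
  above <- which(pv > alpha)
  if (length(above) == 0) return(ts[1])
  lo <- ts[max(above)]
  uniroot(function(t) rft_p_fwe(t, resels, df) - alpha,
          lower = lo, upper = 100, tol = 1e-10)$root
}

# local maxima of a 3D array within a mask, 18-connectivity
local_maxima_18 <- function(a, mask) {
  d <- dim(a)
  av <- a; av[!mask | !is.finite(a)] <- -Inf
  is_max <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    if (abs(di) + abs(dj) + abs(dk) == 3) next   # 18-connectivity
    src_i <- pmin(pmax(seq_len(d[1]) + di, 1), d[1])
    src_j <- pmin(pmax(seq_len(d[2]) + dj, 1), d[2])
    src_k <- pmin(pmax(seq_len(d[3]) + dk, 1), d[3])
    nb <- av[src_i, src_j, src_k, drop = FALSE]
    # border clamping compares a voxel to itself; treat as not larger
    same <- outer(outer(src_i == seq_len(d[1]), src_j == seq_len(d[2]),
                        "&"), src_k == seq_len(d[3]), "&")
    larger <- nb > av
    larger[same] <- FALSE
    is_max <- is_max & !larger
  }
  which(is_max & mask & is.finite(a))
}

#' Peak-level FWE inference within an ROI
#'
#' Finds local maxima (18-connectivity, ties kept) of the t-map inside the
#' ROI and assigns each an FWE-corrected p-value from Gaussian random
#' field theory using the ROI's resel counts and the map's estimated
#' smoothness. z-equivalents are the probit of the t upper-tail
#' probability, clamped at 8.
#'
#' @param stat a `stat_map` from [glm_t_map()].
#' @param roi a `volume3d` mask within the analysis mask.
#' @param roi_name label carried into the result.
#' @return `data.frame` of class `peak_result` with columns roi, t, z,
#'   x/y/z_mm, p_fwe, sorted by t descending; resel counts in attribute
#'   `"resels"`.
#' @export
rft_peak_fwe <- function(stat, roi, roi_name = "roi") {
  stopifnot(inherits(stat, "stat_map"), is_volume3d(roi))
  if (!same_grid(roi, stat$t)) stop("rft_peak_fwe: ROI grid mismatch")
  rmask <- roi$data > 0
  if (!any(rmask)) stop("rft_peak_fwe: empty ROI")
  vox <- vox_sizes(stat$t)
  resels <- resel_counts(rmask, vox, stat$fwhm)
  inmask <- rmask & stat$mask$data > 0
  if (!any(inmask)) stop("rft_peak_fwe: ROI does not intersect the mask")
  pk <- local_maxima_18(stat$t$data, inmask)
  tv <- stat$t$data[pk]
  ord <- order(tv, decreasing = TRUE)
  pk <- pk[ord]; tv <- tv[ord]
  ijk <- arrayInd(pk, dim(stat$t$data)) - 1
  xyz <- voxel_to_world(stat$t, ijk)
  pvals <- vapply(tv, rft_p_fwe, numeric(1), resels = resels, df = stat$df)
  zeq <- qnorm(pt(tv, stat$df, lower.tail = FALSE), lower.tail = FALSE)
  zeq <- pmin(zeq, 8)
  out <- data.frame(roi = roi_name, t = tv, z = zeq,
                    x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
                    p_fwe = pvals)
  attr(out, "resels") <- resels
  class(out) <- c("peak_result", "data.frame")
  out
}

#' ANCOVA on a scalar cord metric
#'
#' Linear model `value ~ group + age + gender + scanner` (TIV deliberately
#' excluded for native-space cord metrics). The group effect is reported
#' as control minus patient (positive = reduced in patients) with its
#' two-sided p-value and covariate-adjusted group means.
#'
#' @param values numeric vector, one value per subject (same order as
#'   `covs`).
#' @param covs a `covariate_table`.
#' @return list: `effect` (control - patient, adjusted), `p`,
#'   `adjusted_means` (named), `n_per_group`, `model` (the `lm` fit).
#' @export
ancova_metric <- function(values, covs) {
  covs <- as.data.frame(covs)
  stopifnot(length(values) == nrow(covs))
  if (min(table(covs$group)) < 3)
    stop("ancova_metric: need >= 3 subjects per group")
  df <- data.frame(value = values,
                   group = factor(covs$group,
                                  levels = c("patient", "control")),
                   age = covs$age - mean(covs$age),
                   gender = covs$gender, scanner = covs$scanner)
  form <- value ~ group + age
  if (nlevels(factor(df$gender)) > 1) form <- update(form, . ~ . + gender)
  else warning("ancova_metric: dropping constant covariate 'gender'")
  if (nlevels(factor(df$scanner)) > 1) form <- update(form, . ~ . + scanner)
  else warning("ancova_metric: dropping constant covariate 'scanner'")
  fit <- lm(form, data = df)
  sm <- summary(fit)$coefficients
  effect <- sm["groupcontrol", "Estimate"]
  pval <- sm["groupcontrol", "Pr(>|t|)"]
  nd <- df; nd$age <- 0
  if ("gender" %in% all.vars(form))
    nd$gender <- factor(levels(factor(df$gender))[1],
                        levels = levels(factor(df$gender)))
  if ("scanner" %in% all.vars(form))
    nd$scanner <- factor(levels(factor(df$scanner))[1],
                         levels = levels(factor(df$scanner)))
  nd$group <- factor("control", levels = levels(df$group))
  mc <- predict(fit, newdata = nd[1, , drop = FALSE])
  nd$group <- factor("patient", levels = levels(df$group))
  mp <- predict(fit, newdata = nd[1, , drop = FALSE])
  list(effect = unname(effect), p = unname(pval),
       adjusted_means = c(control = unname(mc), patient = unname(mp)),
       n_per_group = table(df$group), model = fit)
}

#' Two-way absolute-agreement single-measurement ICC, ICC(A,1)
#'
#' Two-way ANOVA mean squares (rows = subjects, columns = methods) give
#' `ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
#' Absolute agreement: systematic offsets between methods lower the ICC.
#' Reliability categories: poor < 0.5, moderate [0.5, 0.75), good
#' [0.75, 0.9), excellent >= 0.9.
#'
#' @param m n x k numeric matrix (n subjects, k methods), no missing
#'   cells.
#' @return list of class `icc_result`: `icc`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `n`, `k`, `category`.
#' @export
icc_a1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2)
    stop("icc_a1: need at least 3 subjects and 2 methods")
  if (any(!is.finite(m)))
    stop("icc_a1: missing cells are not allowed (no imputation)")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_err) /
    (ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err))
  category <- if (icc < 0.5) "poor"
              else if (icc < 0.75) "moderate"
              else if (icc < 0.9) "good"
              else "excellent"
  structure(list(icc = icc, ms_rows = ms_rows, ms_cols = ms_cols,
                 ms_error = ms_err, n = n, k = k, category = category),
            class = "icc_result")
}

#' Per-ROI mean tables across subjects and methods
#'
#' For every ROI, computes the mean map value inside the ROI for each
#' subject and each method, producing the n x k matrices that feed
#' [icc_a1()].
#'
#' @param maps_by_method named list (method -> list of per-subject
#'   `volume3d`s, same subject order).
#' @param rois named list of `volume3d` masks.
#' @return named list (one n x k matrix per ROI, columns = methods).
#' @export
roi_mean_table <- function(maps_by_method, rois) {
  stopifnot(length(maps_by_method) >= 2, length(rois) >= 1)
  methods <- names(maps_by_method)
  nsub <- length(maps_by_method[[1]])
  out <- list()
  for (rn in names(rois)) {
    rmask <- rois[[rn]]$data > 0
    if (!any(rmask)) stop("roi_mean_table: empty ROI '", rn, "'")
    M <- matrix(NA_real_, nsub, length(methods),
                dimnames = list(NULL, methods))
    for (mi in seq_along(methods)) {
      maps <- maps_by_method[[mi]]
      if (length(maps) != nsub)
        stop("roi_mean_table: methods have different subject counts")
      for (s in seq_len(nsub))
        M[s, mi] <- mean(maps[[s]]$data[rmask], na.rm = TRUE)
    }
    out[[rn]] <- M
  }
  out
}
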