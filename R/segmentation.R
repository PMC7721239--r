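#' A set of tissue probability maps on a shared grid
#'
#' Container for per-class probability volumes (typically the 7 classes GM,
#' WM, CSF, fat, non-neural, soft, bone/air) sharing one grid, with the
#' number of mixture Gaussians assigned to each class.
#'
#' @param maps named list of `volume3d` (kind `"probability"`) on one grid.
#' @param gaussians_per_class integer vector (>= 1 each), one per class.
#'   Default `c(1,1,1,1,2,3,3)` for the standard 7-class model: one
#'   Gaussian each for GM, WM, CSF and fat, two for non-neural tissue and
#'   three each for soft tissue and bone/air.
#' @return object of class `tissue_set`.
#' @export
tissue_set <- function(maps, gaussians_per_class = NULL) {
  stopifnot(length(maps) >= 1, !is.null(names(maps)))
  ref <- maps[[1]]
  for (m in maps) {
    if (!is_volume3d(m)) stop("tissue_set: maps must be volume3d objects")
    if (!same_grid(m, ref)) stop("tissue_set: maps must share one grid")
  }
  if (is.null(gaussians_per_class)) {
    gaussians_per_class <-
      if (length(maps) == 7) c(1L, 1L, 1L, 1L, 2L, 3L, 3L)
      else rep(1L, length(maps))
  }
  if (length(gaussians_per_class) != length(maps) ||
      any(gaussians_per_class < 1))
    stop("tissue_set: gaussians_per_class must have one entry >= 1 per class")
  total <- Reduce(`+`, lapply(maps, function(m) m$data))
  if (max(total) > 1 + 1e-6)
    stop("tissue_set: per-voxel class sum exceeds 1 (max ",
         signif(max(total), 6), ")")
  structure(list(maps = maps, gaussians_per_class = gaussians_per_class),
            class = "tissue_set")
}

#' @export
print.tissue_set <- function(x, ...) {
  cat("<tissue_set> classes:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Prior-weighted Gaussian mixture tissue segmentation
#'
#' EM on a spatially-prior-weighted Gaussian mixture of image intensities:
#' each tissue class k is modelled by `gaussians_per_class[k]` Gaussians and
#' voxel responsibilities are proportional to
#' `prior(k, voxel) * sum_g w_g N(y; mu_g, sigma_g^2)`. Class posteriors are
#' the summed responsibilities of the class's Gaussians, rescaled so that
#' the per-voxel posterior sum equals the per-voxel prior sum (<= 1).
#'
#' Initialisation is deterministic: Gaussian means are placed at
#' prior-weighted intensity quantiles within each class, within-class
#' weights start uniform. No bias-field model is included (inputs are
#' assumed inhomogeneity-corrected upstream) and priors are assumed already
#' aligned to the image grid.
#'
#' @param image a `volume3d` of intensities.
#' @param priors a `tissue_set` on the same grid, per-voxel sum <= 1.
#' @param gaussians_per_class optional override of the prior's counts.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @return list with `posterior` (a `tissue_set`) and `model` (per-Gaussian
#'   `means`, `variances`, `weights`, `class` assignment and the
#'   log-likelihood trace, which is non-decreasing).
#' @export
segment <- function(image, priors, gaussians_per_class = NULL,
                    max_iter = 100L, tol = 1e-6) {
  stopifnot(is_volume3d(image), inherits(priors, "tissue_set"))
  if (!same_grid(image, priors$maps[[1]]))
    stop("segment: image and priors are not on the same grid")
  if (any(!is.finite(image$data)))
    stop("segment: image contains non-finite intensities")
  G <- if (is.null(gaussians_per_class)) priors$gaussians_per_class
       else as.integer(gaussians_per_class)
  classes <- names(priors$maps)
  nc <- length(classes)
  if (length(G) != nc || any(G < 1))
    stop("segment: gaussians_per_class must have one entry >= 1 per class")

  P <- sapply(priors$maps, function(m) as.vector(m$data))
  s <- rowSums(P)
  head_idx <- which(s > 1e-6)
  if (length(head_idx) == 0) stop("segment: empty prior support")
  Ph <- P[head_idx, , drop = FALSE] / s[head_idx]
  y <- as.vector(image$data)[head_idx]

  gclass <- rep(seq_len(nc), G)          # class of each Gaussian
  ng <- length(gclass)
  mu <- numeric(ng); sg2 <- numeric(ng); w <- numeric(ng)
  vfloor <- max(var(y), 1) * 1e-8
  for (k in seq_len(nc)) {
    gk <- which(gclass == k)
    pk <- Ph[, k]
    if (sum(pk) < 1e-8) {
      # class absent from the prior support: park it harmlessly
      mu[gk] <- mean(y); sg2[gk] <- var(y) + vfloor
    } else {
      # prior-weighted quantile positions; the global Gaussian rank breaks
      # symmetry when priors are uninformative (flat) across classes
      qs <- (gk - 0.5) / ng
      ord <- order(y)
      cw <- cumsum(pk[ord]) / sum(pk)
      mu[gk] <- y[ord][pmax(1, findInterval(qs, cw))]
      m1 <- sum(pk * y) / sum(pk)
      v1 <- sum(pk * (y - m1)^2) / sum(pk)
      sg2[gk] <- max(v1 / length(gk), vfloor)
    }
    w[gk] <- 1 / length(gk)
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    R <- matrix(0, nrow = length(y), ncol = ng)
    for (g in seq_len(ng))
      R[, g] <- Ph[, gclass[g]] * w[g] *
        dnorm(y, mu[g], sqrt(sg2[g]))
    rs <- rowSums(R)
    ll <- sum(log(rs + 1e-300))
    ll_trace <- c(ll_trace, ll)
    R <- R / pmax(rs, 1e-300)
    for (g in seq_len(ng)) {
      n_g <- sum(R[, g])
      if (n_g > 1e-8) {
        mu[g] <- sum(R[, g] * y) / n_g
        sg2[g] <- max(sum(R[, g] * (y - mu[g])^2) / n_g, vfloor)
      }
    }
    for (k in seq_len(nc)) {
      gk <- which(gclass == k)
      tot <- sum(R[, gk])
      w[gk] <- if (tot > 1e-12) colSums(R[, gk, drop = FALSE]) / tot
               else 1 / length(gk)
    }
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
  }

  # final E-step responsibilities with converged parameters
  R <- matrix(0, nrow = length(y), ncol = ng)
  for (g in seq_len(ng))
    R[, g] <- Ph[, gclass[g]] * w[g] * dnorm(y, mu[g], sqrt(sg2[g]))
  R <- R / pmax(rowSums(R), 1e-300)

  post <- lapply(seq_len(nc), function(k) {
    v <- numeric(length(s))
    v[head_idx] <- rowSums(R[, gclass == k, drop = FALSE]) * s[head_idx]
    volume3d(array(pmin(pmax(v, 0), 1), dim = dim(image$data)),
             image$affine, kind = "probability")
  })
  names(post) <- classes
  list(posterior = tissue_set(post, gaussians_per_class = G),
       model = list(means = mu, variances = sg2, weights = w,
                    class = classes[gclass], loglik = ll_trace))
}

#' Combine GM and WM posteriors into a neural tissue (NT) map
#'
#' `NT = clip(GM + WM, 0, 1)`. GM/WM separation is unreliable in the cord,
#' so cord analyses operate on this combined class.
#'
#' @param posterior a `tissue_set` containing classes `gm` and `wm`.
#' @return a `volume3d` of kind `"probability"`.
#' @export
combine_nt <- function(posterior) {
  if (!all(c("gm", "wm") %in% names(posterior$maps)))
    stop("combine_nt: posterior must contain 'gm' and 'wm' classes")
  gm <- posterior$maps$gm
  wm <- posterior$maps$wm
  if (!same_grid(gm, wm)) stop("combine_nt: gm/wm grid mismatch")
  volume3d(pmin(pmax(gm$data + wm$data, 0), 1), gm$affine,
           kind = "probability")
}

#' Total intracranial volume from tissue posteriors
#'
#' `TIV = (sum of GM + WM + CSF probabilities) * voxel volume`, in mm^3.
#'
#' @param posterior a `tissue_set` with classes `gm`, `wm`, `csf`.
#' @return TIV in mm^3.
#' @export
compute_tiv <- function(posterior) {
  need <- c("gm", "wm", "csf")
  if (!all(need %in% names(posterior$maps)))
    stop("compute_tiv: posterior must contain gm, wm and csf classes")
  tot <- sum(posterior$maps$gm$data) + sum(posterior$maps$wm$data) +
    sum(posterior$maps$csf$data)
  tot * vox_volume(posterior$maps$gm)
}

#' Dice overlap between two binary masks
#' @param a,b `volume3d` masks or 0/1 arrays on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  av <- if (is_volume3d(a)) a$data else a
  bv <- if (is_volume3d(b)) b$data else b
  2 * sum(av * bv) / (sum(av) + sum(bv))
}
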