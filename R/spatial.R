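#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm full width at half maximum.
#' @return `fwhm / (2 * sqrt(2 * ln 2))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' A dense displacement field in world mm
#'
#' Carries three displacement components (world-frame mm) defined on the
#' target grid. Field *generation* (diffeomorphic registration) is out of
#' scope; fields are supplied externally or built analytically.
#'
#' @param dx,dy,dz 3D arrays of displacements (mm, world frame).
#' @param affine 4x4 voxel-to-world affine of the target grid.
#' @param provenance free-text provenance tag.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, dz, affine, provenance = "") {
  if (!all(dim(dx) == dim(dy)) || !all(dim(dx) == dim(dz)))
    stop("deformation_field: components must share one grid")
  if (any(!is.finite(dx)) || any(!is.finite(dy)) || any(!is.finite(dz)))
    stop("deformation_field: displacements must be finite")
  structure(list(dx = dx, dy = dy, dz = dz,
                 affine = unname(as.matrix(affine)),
                 provenance = provenance),
            class = "deformation_field")
}

# world coordinates of every voxel of a grid (n x 3)
grid_world <- function(dims, affine) {
  i <- rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3])
  j <- rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3])
  k <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  cbind(i, j, k, 1) %*% t(affine)
}

# sample a volume at world points; returns list(values, inside)
sample_volume <- function(vol, xyz, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(vol$data)
  ijk <- cbind(xyz[, 1:3, drop = FALSE], 1) %*% t(solve(vol$affine))
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  if (method == "nearest") {
    ii <- round(i); jj <- round(j); kk <- round(k)
    inside <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 &
      kk >= 0 & kk <= d[3] - 1
    val <- numeric(length(i))
    lin <- (pmin(pmax(kk, 0), d[3] - 1)) * d[1] * d[2] +
      (pmin(pmax(jj, 0), d[2] - 1)) * d[1] +
      pmin(pmax(ii, 0), d[1] - 1) + 1
    val <- vol$data[lin]
    val[!inside] <- 0
    return(list(values = val, inside = inside))
  }
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  i0 <- pmin(floor(i), d[1] - 2); j0 <- pmin(floor(j), d[2] - 2)
  k0 <- pmin(floor(k), d[3] - 2)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  at <- function(a, b, cc) vol$data[cc * d[1] * d[2] + b * d[1] + a + 1]
  val <-
    at(i0,     j0,     k0)     * (1 - fi) * (1 - fj) * (1 - fk) +
    at(i0 + 1, j0,     k0)     * fi       * (1 - fj) * (1 - fk) +
    at(i0,     j0 + 1, k0)     * (1 - fi) * fj       * (1 - fk) +
    at(i0 + 1, j0 + 1, k0)     * fi       * fj       * (1 - fk) +
    at(i0,     j0,     k0 + 1) * (1 - fi) * (1 - fj) * fk +
    at(i0 + 1, j0,     k0 + 1) * fi       * (1 - fj) * fk +
    at(i0,     j0 + 1, k0 + 1) * (1 - fi) * fj       * fk +
    at(i0 + 1, j0 + 1, k0 + 1) * fi       * fj       * fk
  val[!inside] <- 0
  list(values = val, inside = inside)
}

#' Resample a volume through a deformation field
#'
#' Pull-back resampling: `output(x) = vol(x + d(x))` for every voxel centre
#' `x` of the field's grid, with trilinear or nearest-neighbour
#' interpolation. Points falling outside the source volume are set to 0 and
#' counted in the `n_outside` attribute.
#'
#' @param vol source `volume3d`.
#' @param field a [deformation_field()] on the target grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"` (use for
#'   masks and labels).
#' @return a `volume3d` on the field's grid.
#' @export
apply_deformation <- function(vol, field,
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_volume3d(vol), inherits(field, "deformation_field"))
  dims <- dim(field$dx)
  xyz <- grid_world(dims, field$affine)[, 1:3, drop = FALSE]
  xyz[, 1] <- xyz[, 1] + as.vector(field$dx)
  xyz[, 2] <- xyz[, 2] + as.vector(field$dy)
  xyz[, 3] <- xyz[, 3] + as.vector(field$dz)
  sm <- sample_volume(vol, xyz, method = interpolation)
  out <- volume3d(array(sm$values, dims), field$affine,
                  kind = vol$kind, units = vol$units)
  attr(out, "n_outside") <- sum(!sm$inside)
  out
}

# central differences of a 3D array along one axis, one-sided at edges,
# in units of 1/voxel
diff_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1, n)
  idx_m <- pmax(seq_len(n) - 1, 1)
  den <- idx_p - idx_m
  sel <- function(idx) {
    args <- list(a, TRUE, TRUE, TRUE)
    args[[axis + 1]] <- idx
    do.call(`[`, args)
  }
  den_arr <- switch(axis,
                    array(den, d),
                    aperm(array(den, d[c(2, 1, 3)]), c(2, 1, 3)),
                    aperm(array(den, d[c(3, 1, 2)]), c(2, 3, 1)))
  (sel(idx_p) - sel(idx_m)) / den_arr
}

#' Jacobian determinant of a deformation
#'
#' `det(I + grad d)` with the displacement gradient taken with respect to
#' world coordinates, via central differences on the grid (one-sided at
#' edges).
#'
#' @param field a [deformation_field()].
#' @return a `volume3d` of kind `"jacobian"`.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  Ainv <- solve(field$affine[1:3, 1:3])   # dvoxel/dworld
  comps <- list(field$dx, field$dy, field$dz)
  # gv[[c]][[ax]] = d d_c / d voxel_ax
  gv <- lapply(comps, function(cc) lapply(1:3, function(ax) diff_axis(cc, ax)))
  d <- dim(field$dx)
  # world-frame gradient: G[c, w] = sum_ax gv[c][ax] * Ainv[ax, w]
  G <- vector("list", 9)
  for (ci in 1:3) for (wi in 1:3) {
    acc <- 0
    for (ax in 1:3) acc <- acc + gv[[ci]][[ax]] * Ainv[ax, wi]
    G[[(ci - 1) * 3 + wi]] <- acc
  }
  g <- function(ci, wi) G[[(ci - 1) * 3 + wi]] + (ci == wi)
  det_arr <- g(1, 1) * (g(2, 2) * g(3, 3) - g(2, 3) * g(3, 2)) -
    g(1, 2) * (g(2, 1) * g(3, 3) - g(2, 3) * g(3, 1)) +
    g(1, 3) * (g(2, 1) * g(3, 2) - g(2, 2) * g(3, 1))
  volume3d(det_arr, field$affine, kind = "jacobian")
}

#' Modulate a probability map by Jacobian determinants
#'
#' Voxel-wise product, preserving total tissue volume under deformation.
#' The result is a probability-derived tissue density (values may exceed 1)
#' and therefore carries kind `"intensity"`.
#'
#' @param prob a `volume3d` of kind `"probability"`.
#' @param jac a `volume3d` of kind `"jacobian"` on the same grid.
#' @return modulated `volume3d`.
#' @export
modulate <- function(prob, jac) {
  stopifnot(is_volume3d(prob), is_volume3d(jac))
  if (prob$kind != "probability")
    stop("modulate: prob must be of kind 'probability'")
  if (!same_grid(prob, jac)) stop("modulate: grid mismatch")
  volume3d(prob$data * jac$data, prob$affine, kind = "intensity",
           units = prob$units)
}

orthogonal_grid_check <- function(vol) {
  B <- vol$affine[1:3, 1:3]
  M <- t(B) %*% B
  if (max(abs(M - diag(diag(M)))) > 1e-6 * max(diag(M)))
    stop("gaussian_smooth: only orthogonal (shear-free) grids are supported")
}

# dense 1D convolution matrix for a normalised Gaussian, zero padding
conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  taps <- dnorm(seq(-r, r), sd = sigma_vox)
  taps <- taps / sum(taps)
  K <- matrix(0, n, n)
  for (t in seq_along(taps)) {
    off <- t - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + taps[t]
  }
  K
}

# separable smoothing of a 3D array, sigma per axis in voxels
smooth_array <- function(a, sigma_vox) {
  d <- dim(a)
  if (sigma_vox[1] > 0) {
    K <- conv_matrix(d[1], sigma_vox[1])
    a <- array(K %*% matrix(a, d[1]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- conv_matrix(d[2], sigma_vox[2])
    ap <- aperm(a, c(2, 1, 3))
    ap <- array(K %*% matrix(ap, d[2]), c(d[2], d[1], d[3]))
    a <- aperm(ap, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- conv_matrix(d[3], sigma_vox[3])
    ap <- aperm(a, c(3, 1, 2))
    ap <- array(K %*% matrix(ap, d[3]), c(d[3], d[1], d[2]))
    a <- aperm(ap, c(2, 3, 1))
  }
  a
}

#' Isotropic Gaussian smoothing
#'
#' Separable convolution with a Gaussian of the given FWHM (mm), converted
#' per axis to voxel units via the affine
#' (`sigma = fwhm / (2 sqrt(2 ln 2))`). `fwhm = 0` is the identity.
#' Boundaries are zero-padded. Only orthogonal grids are supported.
#'
#' @param vol a `volume3d`.
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @return smoothed `volume3d`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(is_volume3d(vol), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  orthogonal_grid_check(vol)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / vox_sizes(vol)
  out <- smooth_array(vol$data, sigma_vox)
  kind <- if (vol$kind %in% c("probability", "mask")) "intensity" else vol$kind
  volume3d(out, vol$affine, kind = kind, units = vol$units)
}

#' Tissue-weighted (VBQ) smoothing of a quantitative map
#'
#' Computes `G * (tissue x qmap) / G * (tissue)` so that quantitative units
#' are preserved and values are not diluted by neighbouring tissue-free
#' voxels (e.g. cord surrounded by CSF). Voxels whose smoothed tissue
#' weight falls at or below `support_threshold` are flagged missing (NA)
#' rather than zero-filled, which would bias quantitative means. The
#' tissue weight is normalised by its maximum before thresholding, so the
#' output is invariant to rescaling the tissue map by a positive constant.
#' `fwhm_mm = 0` returns the qmap restricted to tissue support.
#'
#' @param qmap quantitative `volume3d` (MT, R1, R2*, ...).
#' @param tissue `volume3d` of kind `"probability"` on the same grid.
#' @param fwhm_mm kernel FWHM in mm.
#' @param support_threshold minimum smoothed (max-normalised) tissue
#'   weight, default 0.05.
#' @return smoothed `volume3d` with NA outside tissue support.
#' @export
vbq_smooth <- function(qmap, tissue, fwhm_mm, support_threshold = 0.05) {
  stopifnot(is_volume3d(qmap), is_volume3d(tissue))
  if (!same_grid(qmap, tissue)) stop("vbq_smooth: grid mismatch")
  if (tissue$kind != "probability")
    stop("vbq_smooth: tissue must be of kind 'probability'")
  wmax <- max(tissue$data)
  if (wmax <= 0) stop("vbq_smooth: tissue map is all zero")
  w <- tissue$data / wmax
  if (fwhm_mm == 0) {
    out <- qmap$data
    out[w <= support_threshold] <- NA_real_
    return(volume3d_allow_na(out, qmap$affine, qmap$kind, qmap$units))
  }
  orthogonal_grid_check(qmap)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / vox_sizes(qmap)
  num <- smooth_array(w * qmap$data, sigma_vox)
  den <- smooth_array(w, sigma_vox)
  out <- num / den
  out[den <= support_threshold] <- NA_real_
  volume3d_allow_na(out, qmap$affine, qmap$kind, qmap$units)
}

# volume3d constructor bypassing the NaN check: used for maps with an
# explicit missing-data convention (NA outside tissue support)
volume3d_allow_na <- function(data, affine, kind, units) {
  v <- volume3d(array(0, dim(data)), affine, kind = "intensity",
                units = units)
  v$data <- data
  v$kind <- kind
  v
}

#' Smoothing scale-space sweep
#'
#' Applies plain or tissue-weighted smoothing at every FWHM of the plan to
#' each subject's map, returning one subjects-stack per FWHM — the inputs
#' to the per-scale group statistics used to choose a cord-appropriate
#' smoothing scale.
#'
#' @param vols list (one per subject) of `volume3d` maps on a common grid.
#' @param tissues list of per-subject tissue probability maps (required
#'   for `mode = "vbq"`).
#' @param fwhms increasing vector of FWHM values in mm (default 0:6, the
#'   0-6 mm sweep in 1 mm steps).
#' @param mode `"vbq"` (default) or `"plain"`.
#' @param support_threshold passed to [vbq_smooth()].
#' @return named list (one entry per FWHM, names `"fwhm_<f>"`) of 4D arrays
#'   (x, y, z, subject), with attributes `affine` and `fwhm`.
#' @export
scale_space_sweep <- function(vols, tissues = NULL, fwhms = 0:6,
                              mode = c("vbq", "plain"),
                              support_threshold = 0.05) {
  mode <- match.arg(mode)
  if (any(diff(fwhms) <= 0) || any(fwhms < 0))
    stop("scale_space_sweep: fwhms must be >= 0 and strictly increasing")
  ref <- vols[[1]]
  for (v in vols[-1])
    if (!same_grid(v, ref)) stop("scale_space_sweep: grid mismatch")
  if (mode == "vbq" && (is.null(tissues) || length(tissues) != length(vols)))
    stop("scale_space_sweep: vbq mode needs one tissue map per subject")
  out <- list()
  for (f in fwhms) {
    stack <- array(NA_real_, c(dim(ref$data), length(vols)))
    for (s in seq_along(vols)) {
      sv <- if (mode == "vbq")
        vbq_smooth(vols[[s]], tissues[[s]], f,
                   support_threshold = support_threshold)
      else if (f == 0) vols[[s]]
      else gaussian_smooth(vols[[s]], f)
      stack[, , , s] <- sv$data
    }
    attr(stack, "affine") <- ref$affine
    attr(stack, "fwhm") <- f
    out[[paste0("fwhm_", f)]] <- stack
  }
  out
}
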