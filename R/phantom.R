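#' Specification of a synthetic brain + cervical cord phantom cohort
#'
#' Defines the geometry, tissue intensity model, quantitative-map (qMRI)
#' model, group effects and cohort design of a synthetic phantom study.
#' The cord is a tapered elliptical cylinder with per-slice semi-axes
#' `a_LR(z)`, `b_AP(z)` (mm); the brain is a set of concentric ellipsoidal
#' shells (WM core, GM shell, CSF rim, skull, scalp fat, soft tissue); the
#' neck surrounds the cord with a CSF-filled canal, non-neural tissue,
#' vertebral bone, soft tissue and a fat shell. Seven tissue classes are
#' emulated (GM, WM, CSF, fat, non-neural, soft, bone/air).
#'
#' Ground-truth cord metrics are analytic: `SCA(z) = pi*a(z)*b(z)`,
#' `APW = 2*b`, `LRW = 2*a` — the recovery oracle for cord morphometry.
#'
#' Default cord semi-axes (5.74 / 3.94 mm) give a control-group mean
#' cross-sectional area of ~71 mm^2, APW ~7.9 mm and LRW ~11.5 mm, matching
#' healthy cervical cord values; default group effects are a 7% cord area
#' reduction (`area_scale = 0.93`) and an 8% cord MT reduction
#' (`cord_mt_scale = 0.92`). Between-subject variability is a log-normal
#' factor on cord area with coefficient of variation `subject_area_cv`
#' (default 0.05, representing residual covariate-adjusted anatomical
#' variability).
#'
#' @param dim grid dimensions (voxels), length 3.
#' @param vox voxel sizes in mm, length 3.
#' @param cord_a_lr,cord_b_ap cord semi-axes at the top of the cord (mm).
#' @param cord_taper fractional linear reduction of both semi-axes from the
#'   top to the bottom cord slice.
#' @param cord_z inclusive 0-based slice range occupied by the cord.
#' @param cord_bow amplitude (mm) of a sinusoidal left-right centerline bow.
#' @param canal_margin CSF canal thickness around the cord (mm).
#' @param gm_core_frac fractional size of the central cord GM core.
#' @param neck_radius,fat_thickness neck soft-tissue radius and outer fat
#'   shell thickness (mm).
#' @param brain_radii ellipsoid radii of the brain (mm).
#' @param brain_shells named fractions of the brain ellipsoid radius at
#'   which WM, GM, CSF, skull, fat and soft shells end.
#' @param intensity_means,intensity_noise_sd structural intensity means per
#'   tissue class (arbitrary T1w-like units) and additive noise SD.
#' @param qmap_means list with elements `mt`, `r1`, `r2star`, each a named
#'   vector of per-class means plus a `cord` entry overriding values inside
#'   the cord. Units follow the reporting convention: MT in p.u., R1 and
#'   R2* on the scale used in the cohort tables.
#' @param qmap_noise_sd named vector of additive noise SDs for the qmaps.
#' @param area_scale multiplicative cord cross-sectional area factor for
#'   patients (0.93 = 7% atrophy); semi-axes are scaled by its square root.
#' @param cord_mt_scale,cord_r1_scale,cord_r2star_scale multiplicative
#'   patient effects on cord qmap values.
#' @param brain_mt_scale,brain_r1_scale multiplicative patient effects in a
#'   spherical brain ROI (`brain_roi_center` world mm, `brain_roi_radius`).
#' @param brain_roi_center,brain_roi_radius brain effect ROI (world mm).
#' @param subject_area_cv between-subject CV of true cord area.
#' @param n_per_group subjects per group.
#' @param seed base seed; subject seeds are `seed + index`.
#' @param age_range,gender_p,scanner_p covariate sampling parameters.
#' @param supersample per-axis sub-voxel sampling factor used to build soft
#'   partial-volume tissue probabilities (3 means 27 samples per voxel).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(
    dim = c(48L, 48L, 64L),
    vox = c(1, 1, 1),
    cord_a_lr = 5.74, cord_b_ap = 3.94,
    cord_taper = 0.05,
    cord_z = c(0L, 23L),
    cord_bow = 0.3,
    canal_margin = 2.5,
    gm_core_frac = 0.45,
    neck_radius = 20, fat_thickness = 2,
    brain_radii = c(18, 18, 16),
    brain_shells = c(wm = 0.55, gm = 0.85, csf = 0.92, boneair = 0.97,
                     fat = 1.03, soft = 1.10),
    intensity_means = c(gm = 80, wm = 100, csf = 30, fat = 110,
                        nonneural = 60, soft = 70, boneair = 20),
    intensity_noise_sd = 4,
    qmap_means = list(
      mt = c(gm = 1.0, wm = 1.9, csf = 0.2, fat = 0.5, nonneural = 0.8,
             soft = 0.9, boneair = 0.1, cord = 2.93),
      r1 = c(gm = 650, wm = 1000, csf = 150, fat = 400, nonneural = 500,
             soft = 550, boneair = 100, cord = 876.88),
      r2star = c(gm = 0.015, wm = 0.020, csf = 0.005, fat = 0.012,
                 nonneural = 0.010, soft = 0.011, boneair = 0.002,
                 cord = 0.02)),
    qmap_noise_sd = c(mt = 0.08, r1 = 25, r2star = 0.002),
    area_scale = 0.93,
    cord_mt_scale = 0.92, cord_r1_scale = 1.0, cord_r2star_scale = 1.0,
    brain_mt_scale = 1.0, brain_r1_scale = 1.0,
    brain_roi_center = c(8, 0, 45), brain_roi_radius = 6,
    subject_area_cv = 0.05,
    n_per_group = 10L,
    seed = 1L,
    age_range = c(20, 70), gender_p = 0.5, scanner_p = 0.35,
    supersample = 3L) {
  spec <- as.list(environment())
  stopifnot(length(spec$dim) == 3, length(spec$vox) == 3)
  if (cord_a_lr <= 0 || cord_b_ap <= 0)
    stop("phantom_spec: cord semi-axes must be > 0")
  if (area_scale <= 0 || area_scale > 1)
    stop("phantom_spec: area_scale must be in (0, 1]")
  if (intensity_noise_sd < 0 || any(qmap_noise_sd < 0))
    stop("phantom_spec: noise SDs must be >= 0")
  if (cord_z[1] < 0 || cord_z[2] >= spec$dim[3] || cord_z[1] > cord_z[2])
    stop("phantom_spec: cord_z out of grid")
  class(spec) <- "phantom_spec"
  spec
}

TISSUE_CLASSES <- c("gm", "wm", "csf", "fat", "nonneural", "soft", "boneair")

phantom_affine <- function(spec) {
  A <- diag(c(spec$vox, 1))
  A[1, 4] <- -spec$vox[1] * (spec$dim[1] - 1) / 2
  A[2, 4] <- -spec$vox[2] * (spec$dim[2] - 1) / 2
  A[3, 4] <- 0
  A
}

# per-slice cord semi-axes at world z (continuous), incl taper and subject /
# group scaling; returns list(a, b, cx, cy)
cord_geometry <- function(spec, axis_scale, zw) {
  z0 <- spec$cord_z[1] * spec$vox[3]
  z1 <- spec$cord_z[2] * spec$vox[3]
  frac <- if (z1 > z0) (zw - z0) / (z1 - z0) else rep(0, length(zw))
  taper <- 1 - spec$cord_taper * pmin(pmax(1 - frac, 0), 1)  # 1 at top slice
  list(a = spec$cord_a_lr * axis_scale * taper,
       b = spec$cord_b_ap * axis_scale * taper,
       cx = spec$cord_bow * sin(pi * pmin(pmax(frac, 0), 1)),
       cy = rep(0, length(zw)))
}

# internal label codes: 0 none, 1 gm, 2 wm, 3 csf, 4 fat, 5 nonneural,
# 6 soft, 7 boneair, 8 cord gm, 9 cord wm
phantom_labels <- function(spec, axis_scale, X, Y, Z) {
  lab <- integer(length(X))
  cord_top <- (spec$cord_z[2] + 0.5) * spec$vox[3]
  bc <- c(0, 0, cord_top + spec$brain_radii[3] + 2)
  sh <- spec$brain_shells
  rho <- sqrt(((X - bc[1]) / spec$brain_radii[1])^2 +
              ((Y - bc[2]) / spec$brain_radii[2])^2 +
              ((Z - bc[3]) / spec$brain_radii[3])^2)
  lab[rho <= sh["soft"]] <- 6L
  lab[rho <= sh["fat"]] <- 4L
  lab[rho <= sh["boneair"]] <- 7L
  lab[rho <= sh["csf"]] <- 3L
  lab[rho <= sh["gm"]] <- 1L
  lab[rho <= sh["wm"]] <- 2L
  neck <- Z <= cord_top & lab == 0L
  if (any(neck)) {
    g <- cord_geometry(spec, axis_scale, Z[neck])
    dx <- X[neck] - g$cx
    dy <- Y[neck] - g$cy
    r2 <- sqrt((dx / g$a)^2 + (dy / g$b)^2)               # cord-normalised
    rcan <- sqrt((dx / (g$a + spec$canal_margin))^2 +
                 (dy / (g$b + spec$canal_margin))^2)
    rnn <- sqrt((dx / (g$a + spec$canal_margin + 3))^2 +
                (dy / (g$b + spec$canal_margin + 3))^2)
    rbone <- sqrt((dx / (g$a + spec$canal_margin + 6))^2 +
                  (dy / (g$b + spec$canal_margin + 6))^2)
    rr <- sqrt(dx^2 + dy^2)
    sub <- integer(sum(neck))
    sub[rr <= spec$neck_radius + spec$fat_thickness] <- 4L
    sub[rr <= spec$neck_radius] <- 6L
    sub[rbone <= 1] <- 7L
    sub[rnn <= 1] <- 5L
    sub[rcan <= 1] <- 3L
    sub[r2 <= 1] <- 9L
    sub[r2 <= spec$gm_core_frac] <- 8L
    lab[neck] <- sub
  }
  # region between cord top and brain: soft tissue within neck radius
  gap <- Z > cord_top & lab == 0L
  if (any(gap)) {
    rr <- sqrt(X[gap]^2 + Y[gap]^2)
    sub <- integer(sum(gap))
    sub[rr <= spec$neck_radius + spec$fat_thickness] <- 4L
    sub[rr <= spec$neck_radius] <- 6L
    gz <- Z[gap] > bc[3]   # above brain centre: no neck column
    sub[gz & rho[gap] > sh["soft"]] <- 0L
    lab[gap] <- sub
  }
  lab
}

#' Generate one phantom subject
#'
#' Builds the structural volume, ground-truth 7-class tissue probabilities
#' (soft partial-volume boundaries via sub-voxel supersampling), MT/R1/R2*
#' maps and the analytic ground-truth cord metrics for one subject.
#' Deterministic given `(spec, group, subject_seed)`. Patients have cord
#' semi-axes scaled by `sqrt(area_scale)` and cord/brain-ROI qmap effects
#' applied.
#'
#' @param spec a [phantom_spec()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed integer seed for this subject.
#' @return list with `structural` (`volume3d`), `truth` (a `tissue_set`),
#'   `qmaps` (list of `volume3d`: mt, r1, r2star), and `truth_metrics`
#'   (per-slice analytic a/b/SCA/APW/LRW, true cord qmap means, group,
#'   area factor).
#' @export
make_subject <- function(spec, group = c("control", "patient"),
                         subject_seed = 1L) {
  group <- match.arg(group)
  set.seed(as.integer(subject_seed))
  area_factor <- exp(rnorm(1, 0, spec$subject_area_cv))
  if (group == "patient") area_factor <- area_factor * spec$area_scale
  axis_scale <- sqrt(area_factor)

  g_top <- cord_geometry(spec, axis_scale, spec$cord_z[1] * spec$vox[3])
  half_x <- spec$vox[1] * (spec$dim[1] - 1) / 2
  half_y <- spec$vox[2] * (spec$dim[2] - 1) / 2
  if (spec$cord_a_lr * axis_scale + spec$canal_margin + 6 > half_x ||
      spec$cord_b_ap * axis_scale + spec$canal_margin + 6 > half_y)
    stop("make_subject: cord (with canal and bone) exceeds the grid")

  A <- phantom_affine(spec)
  nx <- spec$dim[1]; ny <- spec$dim[2]; nz <- spec$dim[3]
  xs <- A[1, 4] + spec$vox[1] * (seq_len(nx) - 1)
  ys <- A[2, 4] + spec$vox[2] * (seq_len(ny) - 1)
  zs <- A[3, 4] + spec$vox[3] * (seq_len(nz) - 1)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)

  ss <- spec$supersample
  offs <- if (ss <= 1) 0 else ((seq_len(ss) - (ss + 1) / 2) / ss)
  counts <- matrix(0L, nrow = nx * ny * nz, ncol = 9)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    lab <- phantom_labels(spec, axis_scale,
                          X + ox * spec$vox[1],
                          Y + oy * spec$vox[2],
                          Z + oz * spec$vox[3])
    pos <- lab > 0L
    idx <- which(pos) + (lab[pos] - 1L) * (nx * ny * nz)
    counts[idx] <- counts[idx] + 1L
  }
  probs <- counts / length(offs)^3

  # collapse internal labels to the 7 tissue classes; keep cord fraction
  p <- matrix(0, nrow = nx * ny * nz, ncol = 7,
              dimnames = list(NULL, TISSUE_CLASSES))
  p[, "gm"] <- probs[, 1] + probs[, 8]
  p[, "wm"] <- probs[, 2] + probs[, 9]
  p[, "csf"] <- probs[, 3]
  p[, "fat"] <- probs[, 4]
  p[, "nonneural"] <- probs[, 5]
  p[, "soft"] <- probs[, 6]
  p[, "boneair"] <- probs[, 7]
  cord_frac <- probs[, 8] + probs[, 9]

  vols <- lapply(TISSUE_CLASSES, function(cl)
    volume3d(array(p[, cl], dim = spec$dim), A, kind = "probability"))
  names(vols) <- TISSUE_CLASSES
  truth <- tissue_set(vols, gaussians_per_class = rep(1L, 7))

  structural <- array(as.vector(p %*% spec$intensity_means), dim = spec$dim)
  if (spec$intensity_noise_sd > 0)
    structural <- structural + rnorm(length(structural),
                                     0, spec$intensity_noise_sd)
  structural <- volume3d(structural, A, kind = "intensity")

  cord_scales <- c(mt = 1, r1 = 1, r2star = 1)
  if (group == "patient")
    cord_scales <- c(mt = spec$cord_mt_scale, r1 = spec$cord_r1_scale,
                     r2star = spec$cord_r2star_scale)
  roi <- sqrt((X - spec$brain_roi_center[1])^2 +
              (Y - spec$brain_roi_center[2])^2 +
              (Z - spec$brain_roi_center[3])^2) <= spec$brain_roi_radius
  brain_scales <- c(mt = 1, r1 = 1, r2star = 1)
  if (group == "patient")
    brain_scales <- c(mt = spec$brain_mt_scale, r1 = spec$brain_r1_scale,
                      r2star = 1)
  qkinds <- c(mt = "mt_pu", r1 = "r1", r2star = "r2star")
  qunits <- c(mt = "p.u.", r1 = "s^-1", r2star = "s^-1")
  qmaps <- list()
  for (q in c("mt", "r1", "r2star")) {
    mu <- spec$qmap_means[[q]]
    val <- as.vector(p %*% mu[TISSUE_CLASSES])
    # replace the cord-NT contribution with the cord-specific mean
    cord_mu <- mu[["cord"]] * cord_scales[[q]]
    val <- val + cord_frac * (cord_mu - as.vector(
      probs[, 8] * mu[["gm"]] + probs[, 9] * mu[["wm"]]) /
        pmax(cord_frac, 1e-12))
    val[roi] <- val[roi] * brain_scales[[q]]
    if (spec$qmap_noise_sd[[q]] > 0)
      val <- val + rnorm(length(val), 0, spec$qmap_noise_sd[[q]])
    qmaps[[q]] <- volume3d(array(val, dim = spec$dim), A,
                           kind = qkinds[[q]], units = qunits[[q]])
  }

  zidx <- spec$cord_z[1]:spec$cord_z[2]
  gsl <- cord_geometry(spec, axis_scale, zidx * spec$vox[3])
  truth_metrics <- list(
    group = group,
    area_factor = area_factor,
    slices = data.frame(z = zidx,
                        a_lr = gsl$a, b_ap = gsl$b,
                        sca = pi * gsl$a * gsl$b,
                        apw = 2 * gsl$b, lrw = 2 * gsl$a),
    mean_sca = mean(pi * gsl$a * gsl$b),
    mean_apw = mean(2 * gsl$b),
    mean_lrw = mean(2 * gsl$a),
    cord_mt = spec$qmap_means$mt[["cord"]] * cord_scales[["mt"]],
    cord_r1 = spec$qmap_means$r1[["cord"]] * cord_scales[["r1"]],
    cord_r2star = spec$qmap_means$r2star[["cord"]] * cord_scales[["r2star"]])

  list(structural = structural, truth = truth, qmaps = qmaps,
       truth_metrics = truth_metrics)
}

#' Generate a phantom cohort with covariates and a ground-truth manifest
#'
#' Per-subject seeds are `spec$seed + index`; covariates (age, gender,
#' scanner) are drawn from the configurable distributions in the spec and
#' recorded. The manifest stores the full analytic ground truth and is
#' byte-identical across reruns with the same spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `subjects` (list of [make_subject()] outputs),
#'   `covariates` (a `covariate_table`), and `manifest` (a list,
#'   serialisable to JSON).
#' @export
make_cohort <- function(spec) {
  if (spec$n_per_group < 2) stop("make_cohort: n_per_group must be >= 2")
  n <- 2L * spec$n_per_group
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  ids <- sprintf("sub-%03d", seq_len(n))
  set.seed(as.integer(spec$seed))
  age <- round(runif(n, spec$age_range[1], spec$age_range[2]), 1)
  gender <- c("f", "m")[1 + rbinom(n, 1, spec$gender_p)]
  scanner <- c("scannerA", "scannerB")[1 + rbinom(n, 1, spec$scanner_p)]
  covs <- as_covariate_table(data.frame(
    subject_id = ids, group = groups, age = age,
    gender = gender, scanner = scanner, stringsAsFactors = FALSE))
  subjects <- vector("list", n)
  manifest_subjects <- vector("list", n)
  for (i in seq_len(n)) {
    s <- make_subject(spec, groups[i], subject_seed = spec$seed + i)
    subjects[[i]] <- s
    manifest_subjects[[i]] <- list(
      subject_id = ids[i], group = groups[i], seed = spec$seed + i,
      area_factor = s$truth_metrics$area_factor,
      mean_sca = s$truth_metrics$mean_sca,
      mean_apw = s$truth_metrics$mean_apw,
      mean_lrw = s$truth_metrics$mean_lrw,
      cord_mt = s$truth_metrics$cord_mt,
      cord_r1 = s$truth_metrics$cord_r1,
      cord_r2star = s$truth_metrics$cord_r2star)
  }
  manifest <- list(spec = unclass(spec), subjects = manifest_subjects)
  list(subjects = subjects, covariates = covs, manifest = manifest)
}

#' Build tissue priors by averaging ground-truth tissue maps
#'
#' Voxel-wise average of the subjects' tissue probability maps,
#' renormalised to sum to 1 wherever any tissue is present. Stands in for
#' a population template of tissue priors.
#'
#' @param tissue_sets list of `tissue_set` objects on a common grid (or a
#'   cohort from [make_cohort()], whose truths are used).
#' @return a `tissue_set` of prior probability maps.
#' @export
make_priors <- function(tissue_sets) {
  if (!is.null(tissue_sets$subjects))
    tissue_sets <- lapply(tissue_sets$subjects, `[[`, "truth")
  if (length(tissue_sets) < 2)
    stop("make_priors: need at least 2 subjects")
  ref <- tissue_sets[[1]]
  for (ts in tissue_sets[-1])
    if (!same_grid(ts$maps[[1]], ref$maps[[1]]))
      stop("make_priors: tissue maps are not on a common grid")
  classes <- names(ref$maps)
  avg <- lapply(classes, function(cl) {
    Reduce(`+`, lapply(tissue_sets, function(ts) ts$maps[[cl]]$data)) /
      length(tissue_sets)
  })
  names(avg) <- classes
  total <- Reduce(`+`, avg)
  keep <- total > 1e-6
  avg <- lapply(avg, function(a) {
    a[keep] <- a[keep] / total[keep]
    a[!keep] <- 0
    a
  })
  vols <- lapply(avg, function(a)
    volume3d(a, ref$maps[[1]]$affine, kind = "probability"))
  tissue_set(vols, gaussians_per_class = ref$gaussians_per_class)
}

#' Analytic total intracranial volume of a phantom
#'
#' GM + WM + CSF volume from the analytic geometry: the brain ellipsoid out
#' to the CSF shell plus the cord-plus-canal ellipse integrated over the
#' cord slices. Oracle for [compute_tiv()].
#'
#' @param spec a [phantom_spec()].
#' @param axis_scale cord semi-axis scale factor (1 for an average control).
#' @return volume in mm^3.
#' @export
analytic_tiv <- function(spec, axis_scale = 1) {
  brain <- 4 / 3 * pi * prod(spec$brain_radii) * spec$brain_shells[["csf"]]^3
  zidx <- spec$cord_z[1]:spec$cord_z[2]
  g <- cord_geometry(spec, axis_scale, zidx * spec$vox[3])
  canal <- sum(pi * (g$a + spec$canal_margin) * (g$b + spec$canal_margin)) *
    spec$vox[3]
  unname(brain + canal)
}

#' Write a phantom cohort to disk
#'
#' Writes per-subject structural and qmap NIfTI volumes, ground-truth
#' tissue maps, a covariates CSV and a ground-truth manifest JSON under
#' `dir` — the on-disk layout consumed by the pipeline runners.
#'
#' @param cohort output of [make_cohort()].
#' @param dir output directory (created if missing).
#' @param write_truth also write ground-truth tissue maps (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$covariates$subject_id
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    write_volume(s$structural, file.path(dir, paste0(ids[i], "_t1w.nii.gz")))
    for (q in names(s$qmaps))
      write_volume(s$qmaps[[q]],
                   file.path(dir, paste0(ids[i], "_", q, ".nii.gz")))
    if (write_truth)
      for (cl in names(s$truth$maps))
        write_volume(s$truth$maps[[cl]],
                     file.path(dir, paste0(ids[i], "_truth_", cl, ".nii.gz")))
  }
  write.csv(as.data.frame(cohort$covariates),
            file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
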