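#' Run configuration for end-to-end VBM / VBQ analyses
#'
#' Serialisable configuration of a pipeline run. Unknown keys in a JSON
#' config file are rejected.
#'
#' @param input_dir cohort directory (as written by [write_cohort()] plus
#'   [write_priors()]).
#' @param output_dir where results are written (created if missing).
#' @param z_range inclusive 0-based cord slice range for cord ROI and
#'   native-space metrics.
#' @param fwhms smoothing plan in mm (single value for VBM; sweep for
#'   VBQ).
#' @param nt_threshold NT binarisation threshold (default 0.5).
#' @param roi_threshold group cord ROI mean-NT threshold (strict >,
#'   default 0.5).
#' @param vbq_support VBQ smoothing support threshold (default 0.05).
#' @param model `"group_diff"` or `"score_assoc"`.
#' @param score_name clinical score for `"score_assoc"`.
#' @param contrast contrast name (default `"control_gt_patient"`).
#' @param seed integer seed recorded in the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       z_range = c(0L, 23L), fwhms = 6,
                       nt_threshold = 0.5, roi_threshold = 0.5,
                       vbq_support = 0.05,
                       model = "group_diff", score_name = NULL,
                       contrast = "control_gt_patient", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#' @param path JSON file with keys matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(js), known)
  if (length(unknown) > 0)
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, js)
}

#' Write tissue priors to disk
#' @param priors a `tissue_set`.
#' @param dir output directory.
#' @param prefix filename prefix (default `"priors"`).
#' @return `dir`, invisibly.
#' @export
write_priors <- function(priors, dir, prefix = "priors") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(priors$maps))
    write_volume(priors$maps[[cl]],
                 file.path(dir, paste0(prefix, "_", cl, ".nii.gz")))
  invisible(dir)
}

#' Read tissue priors from disk
#' @param dir directory containing `<prefix>_<class>.nii.gz` files.
#' @param prefix filename prefix (default `"priors"`).
#' @param classes class names to read (default the 7 standard classes).
#' @return a `tissue_set`.
#' @export
read_priors <- function(dir, prefix = "priors", classes = TISSUE_CLASSES) {
  maps <- lapply(classes, function(cl)
    read_volume(file.path(dir, paste0(prefix, "_", cl, ".nii.gz"))))
  names(maps) <- classes
  tissue_set(maps)
}

pipeline_log <- function(stage, subject, t0) {
  message(sprintf("[%s] %s: %.2fs", stage, subject,
                  as.numeric(Sys.time()) - t0))
}

run_stage <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed for subject '", subject,
         "': ", conditionMessage(e), call. = FALSE))
}

#' End-to-end VBM run on a cohort
#'
#' For every subject: segment the structural volume with the cohort
#' priors, build the NT map and compute TIV; then smooth the NT maps
#' (subjects share one grid, so the template-space deformation is the
#' identity and Jacobian modulation is a no-op), fit the group GLM with
#' age/gender/scanner/TIV covariates, and report cord-ROI peaks with
#' RFT peak-level FWE correction. Outputs (t-map, peaks CSV, manifest
#' JSON) are written under `config$output_dir`.
#'
#' @param config a [run_config()]; `fwhms[1]` is the VBM smoothing FWHM.
#' @param verbose log stage timings (default FALSE).
#' @return list: `stat` (a `stat_map`), `peaks`, `roi`, `nt_maps`,
#'   `covariates` (with TIV), `manifest`.
#' @export
run_vbm <- function(config, verbose = FALSE) {
  t0 <- as.numeric(Sys.time())
  covs <- read_covariates(file.path(config$input_dir, "covariates.csv"))
  priors <- read_priors(config$input_dir)
  ids <- covs$subject_id
  nt_maps <- vector("list", length(ids))
  tiv <- numeric(length(ids))
  for (i in seq_along(ids)) {
    img <- run_stage("read", ids[i], read_volume(
      file.path(config$input_dir, paste0(ids[i], "_t1w.nii.gz"))))
    seg <- run_stage("segment", ids[i], segment(img, priors))
    nt_maps[[i]] <- run_stage("nt", ids[i], combine_nt(seg$posterior))
    tiv[i] <- run_stage("tiv", ids[i], compute_tiv(seg$posterior))
    if (verbose) pipeline_log("segment", ids[i], t0)
  }
  covs$tiv <- tiv
  smoothed <- lapply(nt_maps, function(m)
    if (config$fwhms[1] > 0) gaussian_smooth(m, config$fwhms[1]) else m)
  design <- build_design(covs, model = config$model,
                         score_name = config$score_name)
  stat <- glm_t_map(smoothed, design, contrast = config$contrast)
  roi <- group_cord_roi(nt_maps, z_range = config$z_range,
                        threshold = config$roi_threshold)
  peaks <- rft_peak_fwe(stat, roi, roi_name = "cord")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(stat$t, file.path(config$output_dir, "vbm_tmap.nii.gz"))
  write.csv(as.data.frame(peaks),
            file.path(config$output_dir, "vbm_peaks.csv"),
            row.names = FALSE)
  manifest <- list(analysis = "vbm", config = unclass(config),
                   version = as.character(packageVersion("neuraxis")),
                   n_subjects = length(ids), df = stat$df,
                   fwhm_est = stat$fwhm)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "vbm_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(stat = stat, peaks = peaks, roi = roi, nt_maps = nt_maps,
       covariates = covs, manifest = manifest)
}

#' End-to-end VBQ run with a smoothing scale-space sweep
#'
#' Segments each subject's MT map (aligning tissue probabilities with the
#' quantitative maps in native space), builds NT maps, applies
#' tissue-weighted (VBQ) smoothing to each quantitative map at every FWHM
#' of the plan, fits the group GLM per FWHM, and reports cord-ROI peaks
#' with RFT FWE correction per FWHM — the scale-space sweep used to study
#' how smoothing affects cord-level effects.
#'
#' @param config a [run_config()]; `fwhms` is the sweep (e.g. `0:6`).
#' @param qmap_names which quantitative maps to analyse (default mt, r1,
#'   r2star).
#' @param verbose log stage timings.
#' @return list: `peaks` (data.frame over qmap x fwhm), `stats` (nested
#'   list of `stat_map`s), `roi`, `nt_maps`, `covariates`, `smoothed`,
#'   `manifest`.
#' @export
run_vbq <- function(config, qmap_names = c("mt", "r1", "r2star"),
                    verbose = FALSE) {
  t0 <- as.numeric(Sys.time())
  covs <- read_covariates(file.path(config$input_dir, "covariates.csv"))
  priors <- read_priors(config$input_dir)
  ids <- covs$subject_id
  nt_maps <- vector("list", length(ids))
  qmaps <- lapply(qmap_names, function(q) vector("list", length(ids)))
  names(qmaps) <- qmap_names
  tiv <- numeric(length(ids))
  for (i in seq_along(ids)) {
    mt <- run_stage("read", ids[i], read_volume(
      file.path(config$input_dir, paste0(ids[i], "_mt.nii.gz"))))
    seg <- run_stage("segment-mt", ids[i], segment(mt, priors))
    nt_maps[[i]] <- run_stage("nt", ids[i], combine_nt(seg$posterior))
    tiv[i] <- compute_tiv(seg$posterior)
    qmaps$mt[[i]] <- mt
    for (q in setdiff(qmap_names, "mt"))
      qmaps[[q]][[i]] <- run_stage("read", ids[i], read_volume(
        file.path(config$input_dir, paste0(ids[i], "_", q, ".nii.gz"))))
    if (verbose) pipeline_log("segment-mt", ids[i], t0)
  }
  covs$tiv <- tiv
  design <- build_design(covs, model = config$model,
                         score_name = config$score_name)
  roi <- group_cord_roi(nt_maps, z_range = config$z_range,
                        threshold = config$roi_threshold)
  stats <- list(); peak_rows <- list(); smoothed <- list()
  for (q in qmap_names) {
    sweep <- scale_space_sweep(qmaps[[q]], nt_maps, fwhms = config$fwhms,
                               mode = "vbq",
                               support_threshold = config$vbq_support)
    smoothed[[q]] <- sweep
    stats[[q]] <- list()
    for (fn in names(sweep)) {
      stat <- glm_t_map(sweep[[fn]], design, contrast = config$contrast)
      stats[[q]][[fn]] <- stat
      pk <- tryCatch(rft_peak_fwe(stat, roi, roi_name = "cord"),
                     error = function(e) NULL)
      if (!is.null(pk) && nrow(pk) > 0) {
        top <- pk[1, ]
        peak_rows[[length(peak_rows) + 1]] <- data.frame(
          qmap = q, fwhm = attr(sweep[[fn]], "fwhm"), t = top$t,
          z = top$z, x_mm = top$x_mm, y_mm = top$y_mm, z_mm = top$z_mm,
          p_fwe = top$p_fwe)
      }
    }
  }
  peaks <- if (length(peak_rows) > 0) do.call(rbind, peak_rows)
           else data.frame()
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(peaks, file.path(config$output_dir, "vbq_peaks.csv"),
            row.names = FALSE)
  manifest <- list(analysis = "vbq", config = unclass(config),
                   version = as.character(packageVersion("neuraxis")),
                   n_subjects = length(ids))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "vbq_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(peaks = peaks, stats = stats, roi = roi, nt_maps = nt_maps,
       covariates = covs, smoothed = smoothed, manifest = manifest)
}

#' Method-agreement comparison of two processing runs
#'
#' Computes per-ROI subject-level mean values of each map kind under two
#' processing routes and their ICC(A,1), formatted as a table with one
#' row per ROI and one column per map kind.
#'
#' @param run_a,run_b results of [run_vbq()] on the same subjects (same
#'   order), e.g. two configurations differing in smoothing.
#' @param rois named list of `volume3d` ROI masks.
#' @param fwhm_key which smoothing level of each run to compare (default
#'   the last of each plan).
#' @return list: `icc` (ROIs x map-kinds matrix), `categories` (same
#'   shape, character), `tables` (the underlying n x 2 matrices).
#' @export
run_method_comparison <- function(run_a, run_b, rois, fwhm_key = NULL) {
  ids_a <- run_a$covariates$subject_id
  ids_b <- run_b$covariates$subject_id
  if (!identical(as.character(ids_a), as.character(ids_b)))
    stop("run_method_comparison: subject mismatch between runs")
  kinds <- intersect(names(run_a$smoothed), names(run_b$smoothed))
  icc <- matrix(NA_real_, length(rois), length(kinds),
                dimnames = list(names(rois), kinds))
  cats <- matrix(NA_character_, length(rois), length(kinds),
                 dimnames = list(names(rois), kinds))
  tables <- list()
  for (q in kinds) {
    ka <- if (is.null(fwhm_key)) tail(names(run_a$smoothed[[q]]), 1)
          else fwhm_key
    kb <- if (is.null(fwhm_key)) tail(names(run_b$smoothed[[q]]), 1)
          else fwhm_key
    stack_a <- run_a$smoothed[[q]][[ka]]
    stack_b <- run_b$smoothed[[q]][[kb]]
    to_vols <- function(stack) {
      aff <- attr(stack, "affine")
      lapply(seq_len(dim(stack)[4]), function(s)
        volume3d_allow_na(stack[, , , s], aff, "intensity", ""))
    }
    tabs <- roi_mean_table(list(a = to_vols(stack_a), b = to_vols(stack_b)),
                           rois)
    for (rn in names(rois)) {
      res <- icc_a1(tabs[[rn]])
      icc[rn, q] <- res$icc
      cats[rn, q] <- res$category
      tables[[paste(rn, q, sep = ".")]] <- tabs[[rn]]
    }
  }
  list(icc = icc, categories = cats, tables = tables)
}
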