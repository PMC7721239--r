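#' @importFrom stats rnorm runif rbinom dnorm pt qnorm quantile sd var lm coef
#' @importFrom stats uniroot setNames complete.cases predict update
#' @importFrom utils read.csv write.csv tail head packageVersion
NULL

VALID_KINDS <- c("intensity", "probability", "mt_pu", "r1", "r2star",
                 "tstat", "mask", "jacobian")

#' 3D volume with voxel-to-world affine
#'
#' The universal carrier for images, probability maps and statistic maps:
#' a 3D array plus a 4x4 voxel-to-world affine (mm, RAS+ world axes) and a
#' value-kind label. Voxel indices are 0-based in world-mapping formulas;
#' an "axial slice" is a fixed third (z) index.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm). Must be invertible.
#' @param kind one of `"intensity"`, `"probability"`, `"mt_pu"`, `"r1"`,
#'   `"r2star"`, `"tstat"`, `"mask"`, `"jacobian"`.
#' @param units free-text units (e.g. `"p.u."`, `"s^-1"`).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, affine, kind = "intensity", units = "") {
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    dim(data) <- dim(data)[1:3]
  if (length(dim(data)) != 3L)
    stop("volume3d: data must be a 3D array, got ",
         length(dim(data)), " dimensions")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("volume3d: affine must be 4x4")
  if (!all(is.finite(affine)) || abs(det(affine)) < 1e-12)
    stop("volume3d: affine must be finite and invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(!is.finite(vs)) || any(vs <= 0))
    stop("volume3d: voxel sizes must be finite and > 0")
  kind <- match.arg(kind, VALID_KINDS)
  if (kind == "probability") {
    rng <- range(data, na.rm = TRUE)
    if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
      stop("volume3d: probability values must lie in [0,1], range is [",
           rng[1], ", ", rng[2], "]")
    data[data < 0] <- 0
    data[data > 1] <- 1
  }
  if (kind == "mask" && !all(data %in% c(0, 1)))
    stop("volume3d: mask values must be in {0,1}")
  structure(list(data = data, affine = affine, kind = kind, units = units),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %dx%dx%d, kind=%s, voxel %s mm\n",
              d[1], d[2], d[3], x$kind,
              paste(signif(vox_sizes(x), 4), collapse = "x")))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

#' Voxel sizes (mm) of a volume
#' @param vol a `volume3d`.
#' @return numeric length-3 vector, column norms of the 3x3 affine block.
#' @export
vox_sizes <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Voxel volume in mm^3
#' @param vol a `volume3d`.
#' @return |det| of the 3x3 affine block.
#' @export
vox_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Map 0-based voxel indices to world coordinates (mm)
#' @param vol a `volume3d`.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(vol$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world coordinates (mm) to 0-based voxel indices
#' @param vol a `volume3d`.
#' @param xyz n x 3 matrix of world coordinates.
#' @return n x 3 matrix of (fractional) 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  ijk <- cbind(xyz, 1) %*% t(solve(vol$affine))
  ijk[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3D volume (trailing singleton dimensions are dropped), applying
#' any scl_slope/scl_inter data scaling. `kind` and `units` are taken from a
#' JSON sidecar (same basename, `.json`) when present, unless overridden.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind optional kind override; default uses sidecar, else
#'   `"intensity"`.
#' @param units optional units override.
#' @return A `volume3d`.
#' @export
read_volume <- function(path, kind = NULL, units = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4] > 1L)
      stop("read_volume: '", path, "' is 4D with ", d[4],
           " volumes; only 3D volumes are supported")
    dim(img) <- d[1:3]
  } else if (length(d) != 3L) {
    stop("read_volume: '", path, "' has ", length(d), " dimensions")
  }
  aff <- unname(unclass(RNifti::xform(img, useQuaternionFirst = FALSE)))
  attributes(aff) <- list(dim = c(4L, 4L))
  meta <- list(kind = "intensity", units = "")
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    js <- jsonlite::read_json(sc)
    if (!is.null(js$kind)) meta$kind <- js$kind
    if (!is.null(js$units)) meta$units <- js$units
  }
  if (!is.null(kind)) meta$kind <- kind
  if (!is.null(units)) meta$units <- units
  dat <- array(as.numeric(img), dim = dim(img))
  if (meta$kind == "probability") {  # float32 round-off guard
    dat[dat < 0] <- 0
    dat[dat > 1] <- 1
  }
  volume3d(dat, aff, kind = meta$kind, units = meta$units)
}

#' Write a volume as NIfTI-1 (with JSON sidecar)
#'
#' Masks are stored as uint8, everything else as float32. The affine is
#' written through the sform (code 2) so it round-trips exactly; kind and
#' units go to a `.json` sidecar with the same basename.
#'
#' @param vol a `volume3d`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory '", dirname(path), "' does not exist")
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  dtype <- if (vol$kind == "mask") "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  jsonlite::write_json(list(kind = vol$kind, units = vol$units),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Rotate a volume's content by 90 degrees in the axial (xy) plane
#'
#' Rearranges the data so the stored content is rotated by 90 degrees
#' about the in-plane centre of the grid while the affine is unchanged
#' (exact, no interpolation). Requires a square in-plane grid with equal
#' x/y voxel sizes. Mainly used for rotation-equivariance checks of cord
#' morphometry.
#'
#' @param vol a `volume3d`.
#' @return the rotated `volume3d`.
#' @export
rotate_volume_90 <- function(vol) {
  d <- dim(vol$data)
  vs <- vox_sizes(vol)
  if (d[1] != d[2] || abs(vs[1] - vs[2]) > 1e-9)
    stop("rotate_volume_90: requires a square in-plane grid")
  # value at new voxel (i,j,k) taken from old voxel (n-1-j, i, k):
  # an exact 90 degree rotation of the content about the slice centre
  newdat <- aperm(vol$data, c(2, 1, 3))[, d[1]:1, , drop = FALSE]
  volume3d(newdat, vol$affine, kind = vol$kind, units = vol$units)
}

#' Read a subject covariate table
#'
#' CSV with header; required columns `subject_id`, `group`, `age`, `gender`,
#' `scanner`. Optional: `tiv` and clinical scores (`lems`, `light_touch`,
#' `pinprick`, `scim`). Categorical levels are recorded in order of first
#' appearance.
#'
#' @param path CSV file path.
#' @return a validated `data.frame` of class `covariate_table`.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_covariate_table(df)
}

#' Validate a covariate data.frame
#' @param df data.frame with the columns described in [read_covariates()].
#' @return the validated `covariate_table`.
#' @export
as_covariate_table <- function(df) {
  required <- c("subject_id", "group", "age", "gender", "scanner")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("covariates: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(names(df)))
    stop("covariates: duplicated column names")
  if (anyDuplicated(df$subject_id))
    stop("covariates: duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (!all(df$group %in% c("patient", "control")))
    stop("covariates: group must be 'patient' or 'control'")
  if (!is.numeric(df$age) || any(!is.finite(df$age)) || any(df$age <= 0))
    stop("covariates: age must be positive and finite")
  for (col in c("gender", "scanner", "group"))
    df[[col]] <- factor(df[[col]], levels = unique(df[[col]]))
  class(df) <- c("covariate_table", "data.frame")
  df
}
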