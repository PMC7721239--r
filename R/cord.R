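axial_grid_check <- function(vol) {
  A <- vol$affine
  if (max(abs(A[3, 1:2])) > 1e-6 || max(abs(A[1:2, 3])) > 1e-6)
    stop("axial slicing requires the third voxel axis to be aligned with ",
         "the world z axis")
}

# largest 6-connected component of a logical 3D array (igraph backend)
largest_component <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(mask)
  coord <- arrayInd(idx, d)
  key <- (coord[, 3] - 1) * (d[1] * d[2]) + (coord[, 2] - 1) * d[1] + coord[, 1]
  pos <- integer(prod(d))
  pos[key] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    nb <- coord
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nbkey <- (nb[, 3] - 1) * (d[1] * d[2]) + (nb[, 2] - 1) * d[1] + nb[, 1]
    j <- ifelse(ok, pos[pmin(nbkey, prod(d))], 0L)
    keep <- ok & j > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(which(keep), j[keep]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)  # all isolated; keep the first voxel
    biggest <- 1L
    member <- comp == biggest
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    cs <- igraph::components(g)
    biggest <- which.max(cs$csize)
    member <- cs$membership[seq_along(idx)] == biggest
  }
  out <- array(FALSE, d)
  out[idx[member]] <- TRUE
  out
}

#' Binarise an NT probability map into a cord mask
#'
#' Threshold at `threshold` (inclusive: a voxel exactly at the threshold is
#' included), restricted to the slice range `z_range`, keeping the largest
#' 6-connected 3D component (removes speckles).
#'
#' @param nt a `volume3d` of kind `"probability"`.
#' @param threshold probability threshold, default 0.5.
#' @param z_range inclusive 0-based slice range `c(zmin, zmax)`; default
#'   spans the volume.
#' @return a `volume3d` mask (values in \{0,1\}).
#' @export
binarize_nt <- function(nt, threshold = 0.5, z_range = NULL) {
  stopifnot(is_volume3d(nt))
  if (nt$kind != "probability")
    stop("binarize_nt: nt must be of kind 'probability'")
  d <- dim(nt$data)
  if (is.null(z_range)) z_range <- c(0L, d[3] - 1L)
  m <- nt$data >= threshold
  keep_z <- rep(FALSE, d[3])
  keep_z[(z_range[1]:z_range[2]) + 1L] <- TRUE
  m[, , !keep_z] <- FALSE
  if (!any(m))
    stop("binarize_nt: empty mask after thresholding at ", threshold,
         " within z-range [", z_range[1], ", ", z_range[2], "]")
  m <- largest_component(m)
  volume3d(array(as.numeric(m), d), nt$affine, kind = "mask")
}

#' Sub-voxel iso-contour of one axial slice
#'
#' Extracts the closed `level` iso-contour of the probability slice by
#' bilinear interpolation (marching-squares style) and maps its vertices
#' through the affine to world mm. When several closed contours exist, the
#' one with the longest perimeter is returned (ties broken by larger
#' enclosed area). A slice with no closed contour is flagged invalid, not
#' an error.
#'
#' @param nt a `volume3d` probability map.
#' @param z 0-based axial slice index.
#' @param level iso-level, default 0.5.
#' @return list with `valid` (logical), `points` (n x 2 matrix of world
#'   x/y mm, closed: first row repeated last) and `z_world`.
#' @export
slice_contour <- function(nt, z, level = 0.5) {
  stopifnot(is_volume3d(nt))
  axial_grid_check(nt)
  d <- dim(nt$data)
  if (z < 0 || z > d[3] - 1) stop("slice_contour: slice ", z, " out of range")
  M <- nt$data[, , z + 1L]
  rng <- range(M)
  if (rng[1] >= level || rng[2] < level)
    return(list(valid = FALSE, points = NULL,
                z_world = unname(voxel_to_world(nt, c(0, 0, z))[3])))
  cl <- grDevices::contourLines(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                z = M, levels = level)
  if (length(cl) == 0)
    return(list(valid = FALSE, points = NULL,
                z_world = unname(voxel_to_world(nt, c(0, 0, z))[3])))
  closed <- vapply(cl, function(cc) {
    n <- length(cc$x)
    n >= 4 && abs(cc$x[1] - cc$x[n]) < 1e-9 && abs(cc$y[1] - cc$y[n]) < 1e-9
  }, logical(1))
  cl <- cl[closed]
  if (length(cl) == 0)
    return(list(valid = FALSE, points = NULL,
                z_world = unname(voxel_to_world(nt, c(0, 0, z))[3])))
  to_world <- function(cc) {
    w <- voxel_to_world(nt, cbind(cc$x, cc$y, z))
    w[, 1:2, drop = FALSE]
  }
  perim <- function(w) sum(sqrt(rowSums(diff(w)^2)))
  shoelace <- function(w) {
    n <- nrow(w)
    abs(sum(w[-n, 1] * w[-1, 2] - w[-1, 1] * w[-n, 2])) / 2
  }
  ws <- lapply(cl, to_world)
  ps <- vapply(ws, perim, numeric(1))
  best <- which(ps == max(ps))
  if (length(best) > 1)
    best <- best[which.max(vapply(ws[best], shoelace, numeric(1)))]
  list(valid = TRUE, points = ws[[best]],
       z_world = unname(voxel_to_world(nt, c(0, 0, z))[3]))
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct conic fit constrained to ellipses
#' (Halir-Flusser formulation of the Fitzgibbon method), followed by
#' conversion to centre / semi-axes / tilt. The residual is the RMS
#' gradient-normalised (Sampson) distance of the points to the fitted
#' conic, in mm.
#'
#' @param points n x 2 matrix of boundary points (world mm); n >= 5,
#'   non-collinear.
#' @return list of class `ellipse_fit`: `center` (x, y), `semi_a` >=
#'   `semi_b` (mm), `tilt` (radians, angle of the major axis to the world
#'   x axis, in (-pi/2, pi/2]), `residual` (RMS mm), `n_points`.
#' @export
fit_ellipse <- function(points) {
  points <- matrix(points, ncol = 2)
  points <- points[!duplicated(points[, 1] + 1i * points[, 2]), ,
                   drop = FALSE]
  n <- nrow(points)
  if (n < 5) stop("fit_ellipse: need at least 5 distinct points, got ", n)
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  x <- points[, 1] - mx; y <- points[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12)
    stop("fit_ellipse: degenerate point configuration (collinear?)")
  T <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12 & abs(Im(ev$values)) < 1e-8)
  if (length(ok) == 0)
    stop("fit_ellipse: no ellipse solution (degenerate conic)")
  a1 <- vecs[, ok[1]]
  coef <- c(a1, as.vector(T %*% a1))   # A B C D E F in centred frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ee <- eigen(Q, symmetric = TRUE)
  if (-Fc / ee$values[1] < 0) { ee$values <- -ee$values; Fc <- -Fc }
  semis <- sqrt(-Fc / ee$values)
  if (any(!is.finite(semis)) || any(semis <= 0))
    stop("fit_ellipse: degenerate conic (non-positive axes)")
  ord <- order(semis, decreasing = TRUE)
  semi_a <- semis[ord[1]]; semi_b <- semis[ord[2]]
  e1 <- ee$vectors[, ord[1]]
  tilt <- atan2(e1[2], e1[1])
  if (tilt <= -pi / 2) tilt <- tilt + pi
  if (tilt > pi / 2) tilt <- tilt - pi
  # Sampson residual on the original points
  qv <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
  gx <- 2 * A * x + B * y + D
  gy <- B * x + 2 * C * y + E
  resid <- sqrt(mean((qv / pmax(sqrt(gx^2 + gy^2), 1e-12))^2))
  structure(list(center = c(cx + mx, cy + my), semi_a = semi_a,
                 semi_b = semi_b, tilt = tilt, residual = resid,
                 n_points = n),
            class = "ellipse_fit")
}

#' Per-slice cord metrics from an ellipse fit
#'
#' `SCA = pi * a * b`. Widths are, by default, the full extents of the
#' fitted ellipse along the anatomical world axes (left-right = world x,
#' anterior-posterior = world y): the extent along a unit axis `u` is
#' `2 * sqrt((a * (e1 . u))^2 + (b * (e2 . u))^2)` with `e1`, `e2` the
#' ellipse principal directions. With `widths = "principal"` the principal
#' axis lengths themselves are reported (each assigned to the anatomical
#' axis its direction is closest to).
#'
#' @param fit an `ellipse_fit`.
#' @param z 0-based slice index.
#' @param widths `"extent"` (default) or `"principal"`.
#' @param max_residual validity threshold on the fit residual (mm).
#' @return one-row `data.frame`: z, sca, apw, lrw, residual, valid.
#' @export
slice_metrics <- function(fit, z, widths = c("extent", "principal"),
                          max_residual = 0.5) {
  widths <- match.arg(widths)
  a <- fit$semi_a; b <- fit$semi_b; t <- fit$tilt
  e1 <- c(cos(t), sin(t)); e2 <- c(-sin(t), cos(t))
  if (widths == "extent") {
    lrw <- 2 * sqrt((a * e1[1])^2 + (b * e2[1])^2)
    apw <- 2 * sqrt((a * e1[2])^2 + (b * e2[2])^2)
  } else {
    if (abs(e1[1]) >= abs(e1[2])) { lrw <- 2 * a; apw <- 2 * b }
    else { lrw <- 2 * b; apw <- 2 * a }
  }
  data.frame(z = z, sca = pi * a * b, apw = apw, lrw = lrw,
             residual = fit$residual,
             valid = fit$residual <= max_residual)
}

# per-slice contour + ellipse metrics over a z range; vectorised result
# assembly (called per subject in large simulations, so kept lean)
cord_slice_table <- function(nt, z_range, level = 0.5, max_residual = 0.5,
                             widths = "extent") {
  zs <- z_range[1]:z_range[2]
  nzr <- length(zs)
  sca <- apw <- lrw <- resid <- rep(NA_real_, nzr)
  valid <- rep(FALSE, nzr)
  for (i in seq_len(nzr)) {
    ct <- slice_contour(nt, zs[i], level = level)
    if (!ct$valid || nrow(ct$points) < 6) next
    fit <- tryCatch(fit_ellipse(ct$points[-nrow(ct$points), ]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    a <- fit$semi_a; b <- fit$semi_b; tl <- fit$tilt
    e1 <- c(cos(tl), sin(tl)); e2 <- c(-sin(tl), cos(tl))
    if (widths == "extent") {
      lrw[i] <- 2 * sqrt((a * e1[1])^2 + (b * e2[1])^2)
      apw[i] <- 2 * sqrt((a * e1[2])^2 + (b * e2[2])^2)
    } else if (abs(e1[1]) >= abs(e1[2])) {
      lrw[i] <- 2 * a; apw[i] <- 2 * b
    } else {
      lrw[i] <- 2 * b; apw[i] <- 2 * a
    }
    sca[i] <- pi * a * b
    resid[i] <- fit$residual
    valid[i] <- fit$residual <= max_residual
  }
  data.frame(z = zs, sca = sca, apw = apw, lrw = lrw, residual = resid,
             valid = valid)
}

#' Native-space cord summary for one subject
#'
#' Runs sub-voxel contouring and ellipse fitting on every axial slice in
#' `z_range`, aggregates SCA/APW/LRW over valid slices (fit residual <=
#' `max_residual` mm), and computes unweighted means of the quantitative
#' maps inside the thresholded NT cord mask. The per-slice table also
#' reports the voxel-count area (`mask_area`) for comparison with the
#' ellipse area.
#'
#' @param nt NT probability `volume3d` (native space).
#' @param qmaps optional named list of quantitative `volume3d`s (e.g. mt,
#'   r1, r2star) on the same grid.
#' @param z_range inclusive 0-based slice range covering the cord.
#' @param subject_id identifier carried into the summary.
#' @param threshold NT binarisation threshold (default 0.5).
#' @param max_residual slice validity threshold (mm RMS, default 0.5).
#' @param widths passed to [slice_metrics()].
#' @return list with `slices` (per-slice data.frame) and `summary`
#'   (subject-level list incl. mean SCA/APW/LRW, qmap means,
#'   `n_valid_slices`).
#' @export
cord_summary <- function(nt, qmaps = NULL, z_range, subject_id = "subject",
                         threshold = 0.5, max_residual = 0.5,
                         widths = "extent") {
  stopifnot(is_volume3d(nt))
  if (!is.null(qmaps))
    for (q in qmaps)
      if (!same_grid(q, nt)) stop("cord_summary: qmap grid mismatch")
  if (z_range[1] > z_range[2]) stop("cord_summary: empty z_range")
  mask <- binarize_nt(nt, threshold = threshold, z_range = z_range)
  pix_area <- abs(det(nt$affine[1:2, 1:2]))
  slices <- cord_slice_table(nt, z_range, level = threshold,
                             max_residual = max_residual, widths = widths)
  slices$mask_area <- vapply(z_range[1]:z_range[2], function(z)
    sum(mask$data[, , z + 1L]) * pix_area, numeric(1))
  ok <- slices$valid
  if (!any(ok))
    stop("cord_summary: no valid slices in z-range [", z_range[1], ", ",
         z_range[2], "]")
  qmeans <- list()
  if (!is.null(qmaps)) {
    inmask <- mask$data == 1
    qmeans <- lapply(qmaps, function(q) mean(q$data[inmask]))
  }
  list(slices = slices,
       summary = c(list(subject_id = subject_id,
                        z_min = z_range[1], z_max = z_range[2],
                        mean_sca = mean(slices$sca[ok]),
                        mean_apw = mean(slices$apw[ok]),
                        mean_lrw = mean(slices$lrw[ok]),
                        n_valid_slices = sum(ok)),
                   qmeans))
}

#' Group-level cord region of interest
#'
#' Voxels where the across-subject mean NT probability is strictly greater
#' than `threshold`, restricted to `z_range`. Used as the ROI for
#' peak-level FWE correction in the cord.
#'
#' @param nt_maps list of NT `volume3d`s in a common space (>= 2).
#' @param z_range inclusive 0-based slice range.
#' @param threshold mean-probability threshold (strict), default 0.5.
#' @return a `volume3d` mask.
#' @export
group_cord_roi <- function(nt_maps, z_range, threshold = 0.5) {
  if (length(nt_maps) < 2) stop("group_cord_roi: need >= 2 NT maps")
  ref <- nt_maps[[1]]
  for (m in nt_maps[-1])
    if (!same_grid(m, ref)) stop("group_cord_roi: grid mismatch")
  avg <- Reduce(`+`, lapply(nt_maps, function(m) m$data)) / length(nt_maps)
  m <- avg > threshold
  d <- dim(m)
  keep_z <- rep(FALSE, d[3])
  keep_z[(z_range[1]:z_range[2]) + 1L] <- TRUE
  m[, , !keep_z] <- FALSE
  if (!any(m))
    warning("group_cord_roi: empty ROI (disjoint cords?)")
  volume3d(array(as.numeric(m), d), ref$affine, kind = "mask")
}

#' Percent group difference
#'
#' `100 * (mean_control - mean_patient) / mean_control`, reported to two
#' decimals (round-half-even). Positive values mean the patient group is
#' reduced relative to controls.
#'
#' @param mean_control,mean_patient group means (control mean nonzero).
#' @return percent difference, rounded to 2 decimals.
#' @export
percent_group_difference <- function(mean_control, mean_patient) {
  if (any(mean_control == 0))
    stop("percent_group_difference: control mean must be nonzero")
  round(100 * (mean_control - mean_patient) / mean_control, 2)
}
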