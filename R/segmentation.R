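# Tumor segmentation surfaces: manual per-slice ROI statistics and the
# elliptical-VOI machinery feeding the EM clustering.

#' Construct an ellipsoidal VOI
#'
#' @param center_mm 3-vector, mm.
#' @param semi_axes_mm 3-vector of positive semi-axes, mm.
#' @return object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center_mm, semi_axes_mm) {
  if (any(semi_axes_mm <= 0)) {
    stop_validation("semi_axes_mm", "semi-axes must be strictly positive")
  }
  structure(list(center_mm = as.numeric(center_mm),
                 semi_axes_mm = as.numeric(semi_axes_mm)),
            class = "ellipsoid_voi")
}

#' Rasterize a planar ROI set onto a voxel grid
#'
#' A voxel is included iff its center lies inside the polygon of its slice
#' under the even-odd rule.
#'
#' @param roi a `planar_roi_set`: `slices` is a list of
#'   `list(z_index, vertices)` with vertices in mm.
#' @param grid_shape integer triple.
#' @param voxel_size_mm numeric triple.
#' @return 3D logical mask.
#' @export
rasterize_roi <- function(roi, grid_shape, voxel_size_mm) {
  mask <- array(FALSE, dim = grid_shape)
  xs <- axis_centers_mm(grid_shape[1], voxel_size_mm[1])
  ys <- axis_centers_mm(grid_shape[2], voxel_size_mm[2])
  pg <- expand.grid(x = xs, y = ys)
  for (sl in roi$slices) {
    z <- sl$z_index
    if (z < 1 || z > grid_shape[3]) {
      stop_validation("roi", sprintf("slice index %d outside grid", z))
    }
    mask[, , z] <- mask[, , z] |
      matrix(points_in_polygon(pg$x, pg$y, sl$vertices), nrow = grid_shape[1])
  }
  if (!any(mask)) stop_validation("roi", "rasterization produced an empty mask")
  mask
}

#' Voxel mask of an ellipsoidal VOI
#'
#' Voxel centers satisfying `sum(((x_i - c_i)/a_i)^2) <= 1`.
#'
#' @param voi an [ellipsoid_voi()].
#' @param grid_shape integer triple.
#' @param voxel_size_mm numeric triple.
#' @return 3D logical mask.
#' @export
voi_mask <- function(voi, grid_shape, voxel_size_mm) {
  pts <- grid_centers_mm(grid_shape, voxel_size_mm)
  q <- ((pts[, 1] - voi$center_mm[1]) / voi$semi_axes_mm[1])^2 +
    ((pts[, 2] - voi$center_mm[2]) / voi$semi_axes_mm[2])^2 +
    ((pts[, 3] - voi$center_mm[3]) / voi$semi_axes_mm[3])^2
  m <- array(q <= 1, dim = grid_shape)
  if (!any(m)) stop_validation("voi", "VOI does not intersect the grid")
  m
}

#' Manual-method mass statistics (per-plane averaging)
#'
#' The manual protocol outlines the mass on each axial plane and averages
#' over planes: per-slice mean and SD of the nCBV values inside that
#' slice's ROI, then the mass mean (and SD) as the unweighted average of
#' per-slice means (SDs). A slice with fewer than 2 voxels contributes an
#' SD of 0 and is counted in the `n_small_slices` QC field. The pooled-SD
#' alternative (sample SD over all ROI voxels) is available via
#' `sd_rule = "pooled"`.
#'
#' @param ncbv an `ncbv_map` (or plain 3D array).
#' @param roi 3D logical mask, or a `planar_roi_set` (rasterized first).
#' @param sd_rule `"plane_mean"` (default) or `"pooled"`.
#' @param provenance optional named list recorded on the result.
#' @return object of class `mass_statistics`.
#' @export
manual_mass_statistics <- function(ncbv, roi, sd_rule = c("plane_mean", "pooled"),
                                   provenance = list()) {
  sd_rule <- match.arg(sd_rule)
  vals3d <- if (inherits(ncbv, "ncbv_map")) ncbv$values else ncbv
  vs <- if (inherits(ncbv, "ncbv_map")) ncbv$voxel_size_mm else NULL
  if (inherits(roi, "planar_roi_set")) {
    if (is.null(vs)) stop_validation("roi", "polygon ROI needs an ncbv_map with grid metadata")
    roi <- rasterize_roi(roi, dim(vals3d), vs)
  }
  slice_n <- apply(roi, 3, sum)
  zz <- which(slice_n > 0)
  if (!length(zz)) stop_validation("roi", "empty ROI")
  means <- sds <- numeric(length(zz))
  n_small <- 0L
  for (k in seq_along(zz)) {
    v <- vals3d[, , zz[k]][roi[, , zz[k]]]
    means[k] <- mean(v)
    if (length(v) < 2) { sds[k] <- 0; n_small <- n_small + 1L } else sds[k] <- stats::sd(v)
  }
  all_vals <- vals3d[roi]
  structure(list(
    mean_ncbv = mean(means),
    sd_ncbv = if (sd_rule == "plane_mean") mean(sds) else sample_sd(all_vals),
    n_voxels = sum(slice_n),
    volume_ml = if (!is.null(vs)) sum(slice_n) * prod(vs) / 1000 else NA_real_,
    method = "manual",
    n_small_slices = n_small,
    provenance = provenance
  ), class = "mass_statistics")
}

#' Per-voxel feature vectors for clustering
#'
#' One row per in-mask voxel in lexicographic (column-major) voxel order:
#' `(structural intensity, nCBV)`, each z-scored within the mask. A
#' zero-variance feature is passed through unscaled and flagged.
#'
#' @param structural 3D structural image.
#' @param ncbv an `ncbv_map` or 3D array.
#' @param mask 3D logical mask.
#' @return matrix with attributes `voxel_index` (linear indices),
#'   `qc_constant_features` (character vector).
#' @export
build_feature_vectors <- function(structural, ncbv, mask) {
  vals3d <- if (inherits(ncbv, "ncbv_map")) ncbv$values else ncbv
  stopifnot(all(dim(structural) == dim(vals3d)),
            all(dim(mask) == dim(vals3d)))
  idx <- which(mask)
  feats <- cbind(structural = structural[idx], ncbv = vals3d[idx])
  qc <- character(0)
  for (j in seq_len(ncol(feats))) {
    s <- stats::sd(feats[, j])
    if (is.finite(s) && s > 0) {
      feats[, j] <- (feats[, j] - mean(feats[, j])) / s
    } else {
      qc <- c(qc, colnames(feats)[j])
    }
  }
  attr(feats, "voxel_index") <- idx
  attr(feats, "qc_constant_features") <- qc
  feats
}

#' Semiautomatic mass statistics over selected clusters
#'
#' Pooled mean and sample SD of the nCBV values of all voxels belonging to
#' the selected clusters within the segmented VOI, plus the cluster-based
#' volume (selected voxel count times voxel volume, in ml).
#'
#' @param model a `cluster_model` from [em_fit()].
#' @param selection integer vector of selected cluster ids.
#' @param ncbv_values per-voxel nCBV vector aligned with `model$labels`.
#' @param voxel_size_mm numeric triple.
#' @param provenance optional named list recorded on the result.
#' @return object of class `mass_statistics` with `method = "semiauto"`.
#' @export
semiauto_mass_statistics <- function(model, selection, ncbv_values,
                                     voxel_size_mm, provenance = list()) {
  if (!length(selection)) stop_validation("selection", "empty cluster selection")
  sel <- model$labels %in% selection
  if (!any(sel)) stop_validation("selection", "selected clusters contain no voxels")
  v <- ncbv_values[sel]
  structure(list(
    mean_ncbv = mean(v),
    sd_ncbv = sample_sd(v),
    n_voxels = sum(sel),
    volume_ml = sum(sel) * prod(voxel_size_mm) / 1000,
    method = "semiauto",
    provenance = provenance
  ), class = "mass_statistics")
}
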