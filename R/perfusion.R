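# Perfusion quantification: signal -> concentration, leakage correction,
# rCBV / nCBV maps under manual (contralateral NAWM ROI) and automatic
# normalization.

#' Construct a 4D dynamic series
#'
#' @param signal 4D nonnegative array (x, y, z, t).
#' @param tr_s repetition time, seconds.
#' @param te_s echo time, seconds.
#' @param voxel_size_mm numeric triple.
#' @param baseline_points number of pre-bolus frames.
#' @return object of class `dynamic_series`.
#' @export
dynamic_series <- function(signal, tr_s, te_s, voxel_size_mm, baseline_points) {
  if (length(dim(signal)) != 4) {
    stop_validation("signal", "must be a 4D array (x, y, z, t)")
  }
  if (te_s <= 0) stop_validation("te_s", "must be positive")
  if (baseline_points < 5) {
    stop_validation("baseline_points", "at least 5 baseline frames required")
  }
  if (dim(signal)[4] < baseline_points + 10) {
    stop_validation("signal", "time axis must have at least baseline_points + 10 frames")
  }
  structure(list(
    signal = signal, tr_s = tr_s, te_s = te_s,
    voxel_size_mm = voxel_size_mm,
    baseline_points = as.integer(baseline_points)
  ), class = "dynamic_series")
}

#' Convert dynamic signal to concentration-time curves
#'
#' Computes the transverse relaxation-rate change
#' `dR2*(t) = -log(S(t) / S0) / TE` per voxel, with `S0` the mean over the
#' baseline window (frames 2 .. `baseline_points`; the first frame is
#' excluded as unsaturated). Voxels with nonpositive baseline or any
#' nonpositive sample are flagged invalid (NA curves), never an error.
#'
#' @param series a [dynamic_series()].
#' @return object of class `concentration_series`: `delta_r2s` (4D array,
#'   1/s), `time_s`, `valid` (3D logical), and grid metadata.
#' @export
signal_to_concentration <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$signal)
  nt <- d[4]
  n_vox <- prod(d[1:3])
  sig <- matrix(series$signal, nrow = n_vox, ncol = nt)
  bwin <- 2:series$baseline_points
  s0 <- rowMeans(sig[, bwin, drop = FALSE])
  valid <- s0 > 0 & matrixStats_all_positive(sig)
  dr2 <- matrix(NA_real_, n_vox, nt)
  if (any(valid)) {
    dr2[valid, ] <- -log(sig[valid, , drop = FALSE] / s0[valid]) / series$te_s
  }
  structure(list(
    delta_r2s = array(dr2, dim = d),
    time_s = (seq_len(nt) - 1) * series$tr_s,
    valid = array(valid, dim = d[1:3]),
    voxel_size_mm = series$voxel_size_mm,
    baseline_points = series$baseline_points
  ), class = "concentration_series")
}

# rowwise all(x > 0) without apply()'s overhead
matrixStats_all_positive <- function(m) {
  rowSums(m <= 0) == 0
}

#' Average concentration curve of nonleaky reference parenchyma
#'
#' Mean `dR2*(t)` over valid normal-appearing white matter and gray matter
#' voxels — the nonenhancing reference curve required by the two-parameter
#' leakage correction.
#'
#' @param conc a `concentration_series`.
#' @param labels a `tissue_label_map` on the same grid.
#' @param min_voxels minimum reference-voxel count (default 100).
#' @return numeric vector of length `n_timepoints`.
#' @export
reference_tissue_curve <- function(conc, labels, min_voxels = 100L) {
  stopifnot(inherits(conc, "concentration_series"))
  lab <- labels$labels
  sel <- (lab == TISSUE_LABELS[["nawm"]] | lab == TISSUE_LABELS[["gray_matter"]]) &
    conc$valid
  if (sum(sel) < min_voxels) {
    stop_validation("labels", sprintf(
      "only %d valid reference parenchyma voxels; need at least %d",
      sum(sel), min_voxels))
  }
  d <- dim(conc$delta_r2s)
  m <- matrix(conc$delta_r2s, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(m[as.vector(sel), , drop = FALSE])
}

#' Two-parameter contrast-leakage correction of a concentration curve
#'
#' Linear least-squares fit of the leaky voxel curve against a nonleaky
#' reference curve: `trace(t) ~ k1 * ref(t) - k2 * integral_0^t ref`, the
#' two-parameter model of Boxerman-type leakage correction. The corrected
#' curve adds the estimated leakage term back:
#' `corrected(t) = trace(t) + k2 * integral_0^t ref`.
#'
#' @param trace voxel concentration curve (1/s).
#' @param ref reference curve from [reference_tissue_curve()].
#' @param time_s time vector, seconds.
#' @return object of class `leakage_fit` with `k1`, `k2` (1/s) and
#'   `corrected` trace.
#' @export
leakage_correct <- function(trace, ref, time_s) {
  if (trapz_time(ref, time_s) <= 0 || all(ref == 0)) {
    stop_validation("ref", "degenerate reference curve (nonpositive first-pass area)")
  }
  cum_ref <- cumtrapz_time(ref, time_s)
  X <- cbind(k1 = ref, k2 = -cum_ref)
  beta <- solve(crossprod(X), crossprod(X, trace))
  k1 <- beta[1]; k2 <- beta[2]
  structure(list(
    k1 = unname(k1), k2 = unname(k2),
    corrected = as.numeric(trace + k2 * cum_ref),
    residual_rss = sum((trace - X %*% beta)^2)
  ), class = "leakage_fit")
}

# Vectorized leakage correction over a time x voxel matrix. The regressors
# are shared, so one 2x2 normal-equation solve serves every voxel.
leakage_correct_matrix <- function(conc_mat, ref, time_s) {
  cum_ref <- cumtrapz_time(ref, time_s)
  X <- cbind(ref, -cum_ref)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, conc_mat))   # 2 x n_vox
  list(k1 = beta[1, ], k2 = beta[2, ], cum_ref = cum_ref)
}

#' Compute a relative CBV map from a concentration series
#'
#' Per-voxel rCBV as the time-integral of the concentration curve, under one
#' of three estimators: `raw` (trapezoidal integral of the measured curve),
#' `gamma_fit` (analytic area of a per-voxel gamma-variate first-pass fit,
#' suppressing recirculation and leakage), or `leakage_corrected`
#' (trapezoidal integral after two-parameter leakage correction against the
#' reference-parenchyma curve; requires `labels`). Negative integrals are
#' clipped to zero and counted in the `n_clipped` QC attribute; invalid
#' voxels map to 0.
#'
#' @param conc a `concentration_series`.
#' @param mode one of `"raw"`, `"gamma_fit"`, `"leakage_corrected"`.
#' @param labels `tissue_label_map`, required for `leakage_corrected`.
#' @return object of class `cbv_map`: `values` (3D array), `mode`, QC counts.
#' @export
compute_cbv_map <- function(conc,
                            mode = c("raw", "gamma_fit", "leakage_corrected"),
                            labels = NULL) {
  stopifnot(inherits(conc, "concentration_series"))
  mode <- match.arg(mode)
  d <- dim(conc$delta_r2s)
  n_vox <- prod(d[1:3])
  # delta_r2s is (x,y,z,t); reshape to time x voxel
  m <- t(matrix(conc$delta_r2s, nrow = n_vox, ncol = d[4]))
  valid <- as.vector(conc$valid)
  t_s <- conc$time_s

  vals <- numeric(n_vox)
  n_fit_failed <- 0L
  if (mode == "raw") {
    vals[valid] <- trapz_time(m[, valid, drop = FALSE], t_s)
  } else if (mode == "leakage_corrected") {
    if (is.null(labels)) {
      stop_validation("labels", "leakage_corrected mode requires a tissue label map")
    }
    ref <- reference_tissue_curve(conc, labels)
    fit <- leakage_correct_matrix(m[, valid, drop = FALSE], ref, t_s)
    raw_int <- trapz_time(m[, valid, drop = FALSE], t_s)
    vals[valid] <- raw_int + fit$k2 * trapz_time(fit$cum_ref, t_s)
  } else {
    gm <- gamma_fit_map(m, valid, t_s, conc$baseline_points)
    vals <- gm$area
    n_fit_failed <- gm$n_failed
  }
  n_clipped <- sum(vals < 0)
  vals[vals < 0] <- 0
  structure(list(
    values = array(vals, dim = d[1:3]),
    mode = mode,
    voxel_size_mm = conc$voxel_size_mm,
    n_clipped = n_clipped,
    n_fit_failed = n_fit_failed
  ), class = "cbv_map")
}

#' Normalize a CBV map by a contralateral white-matter ROI (manual scheme)
#'
#' Divides the map by the mean rCBV inside the supplied normal-appearing
#' white-matter ROI. Enforces the manual-protocol constraints: ROI area of
#' at least 40 mm^2 on each slice it occupies, and no gray-matter voxels
#' inside the ROI.
#'
#' @param cbv a `cbv_map`.
#' @param nawm_roi 3D logical mask of the reference ROI.
#' @param labels `tissue_label_map` used to check the gray-matter exclusion.
#' @return object of class `ncbv_map` with `values`, `method_tag =
#'   "manual_norm"` and the `reference_value` used.
#' @export
normalize_manual <- function(cbv, nawm_roi, labels) {
  stopifnot(inherits(cbv, "cbv_map"))
  vs <- cbv$voxel_size_mm
  slice_counts <- apply(nawm_roi, 3, sum)
  occupied <- which(slice_counts > 0)
  if (length(occupied) == 0) stop_validation("nawm_roi", "empty ROI")
  area_mm2 <- min(slice_counts[occupied]) * vs[1] * vs[2]
  if (area_mm2 < 40) {
    stop_validation("nawm_roi", sprintf(
      "ROI area %.1f mm^2 is below the 40 mm^2 minimum", area_mm2))
  }
  if (any(labels$labels[nawm_roi] == TISSUE_LABELS[["gray_matter"]])) {
    stop_validation("nawm_roi", "gray matter voxels inside the reference ROI")
  }
  ref <- mean(cbv$values[nawm_roi])
  if (!is.finite(ref) || ref <= 0) {
    stop_validation("nawm_roi", "nonpositive reference mean rCBV")
  }
  structure(list(
    values = cbv$values / ref,
    method_tag = "manual_norm",
    reference_value = ref,
    voxel_size_mm = vs
  ), class = "ncbv_map")
}

#' Normalize a CBV map by mean rCBV outside the tumor (automatic scheme)
#'
#' The automatic normalization used by the semiautomatic pipeline: the map
#' is divided by the mean rCBV over brain voxels outside the tumor mask.
#'
#' @param cbv a `cbv_map`.
#' @param tumor_mask 3D logical mask of the tumor (e.g. the VOI).
#' @param brain_mask 3D logical mask of brain voxels (background excluded).
#' @return object of class `ncbv_map` with `method_tag = "auto_norm"`.
#' @export
normalize_auto <- function(cbv, tumor_mask, brain_mask) {
  stopifnot(inherits(cbv, "cbv_map"))
  if (!any(tumor_mask)) stop_validation("tumor_mask", "empty tumor mask")
  comp <- brain_mask & !tumor_mask
  if (!any(comp)) {
    stop_validation("brain_mask", "no brain voxels outside the tumor mask")
  }
  ref <- mean(cbv$values[comp])
  if (!is.finite(ref) || ref <= 0) {
    stop_validation("brain_mask", "nonpositive reference mean rCBV")
  }
  structure(list(
    values = cbv$values / ref,
    method_tag = "auto_norm",
    reference_value = ref,
    voxel_size_mm = cbv$voxel_size_mm
  ), class = "ncbv_map")
}

# Brain mask from a structural image: brain tissue is far brighter than the
# air background in the phantom's intensity model.
brain_mask_from_structural <- function(structural, threshold = 40) {
  structural > threshold
}
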