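# Phantom and observer specifications: the study conditions for the
# synthetic DSC cohort are fixed here.

#' Tissue label codes used by the digital phantom
#'
#' Integer codes of the labeled compartments. Every phantom voxel carries
#' exactly one label.
#'
#' @format named integer vector.
#' @export
TISSUE_LABELS <- c(
  background   = 0L,
  nawm         = 1L,
  gray_matter  = 2L,
  tumor_solid  = 3L,
  necrosis_cyst = 4L,
  edema        = 5L,
  macrovessel  = 6L
)

tissue_names <- function() names(TISSUE_LABELS)

# Default per-tissue kinetic parameters. `true_cbv` is in units of the
# normal-appearing white matter blood volume (NAWM = 1); the gamma-variate
# bolus shape (t0, alpha, beta) is shared across tissues with amplitude
# proportional to true_cbv, the standard digital-phantom simplification.
# Only solid tumor leaks contrast (k2_true > 0).
default_tissue_table <- function() {
  data.frame(
    tissue      = c("background", "nawm", "gray_matter", "tumor_solid",
                    "necrosis_cyst", "edema", "macrovessel"),
    true_cbv    = c(0, 1.0, 2.0, 4.5, 0.3, 0.8, 12.0),
    t0_s        = rep(15, 7),
    alpha       = rep(3, 7),
    beta_s      = rep(1.5, 7),
    recirc_frac = c(0, rep(0.25, 6)),
    k2_true     = c(0, 0, 0, 0.01, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic DSC perfusion study
#'
#' Bundles acquisition geometry, timing, noise level, per-tissue kinetic
#' parameters and tumor geometry for one phantom "patient". Defaults follow
#' a typical 3T gradient-echo EPI DSC protocol: TR 1.5 s, TE 30 ms, 60
#' dynamic frames, voxel 1.875 x 1.875 x 5 mm.
#'
#' @param grid_shape integer triple, voxels per axis (x, y, z).
#' @param voxel_size_mm numeric triple, mm.
#' @param tr_s repetition time, seconds.
#' @param te_s echo time, seconds.
#' @param n_timepoints number of dynamic frames.
#' @param baseline_points number of pre-bolus frames used for the baseline
#'   signal estimate (frame 1 is always excluded as saturation).
#' @param snr baseline signal-to-noise ratio; `Inf` for a noiseless phantom.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param tissue_table data.frame of per-tissue kinetics, see
#'   [default_tissue_table()] columns.
#' @param area_scale first-pass area (in 1/s * s) of a unit-CBV tissue;
#'   converts the dimensionless `true_cbv` into concentration-curve area.
#' @param tumor_center_frac tumor center as a fraction of the field of view.
#' @param tumor_radius_mm solid-tumor sphere radius, mm.
#' @param necrosis_radius_frac necrotic-core radius as a fraction of the
#'   tumor radius; 0 for a solid mass without necrosis.
#' @param edema_margin_mm thickness of the perilesional edema shell, mm.
#' @param vessel logical, include an intralesional macrovessel.
#' @param cbv_heterogeneity SD of the smooth multiplicative spatial
#'   heterogeneity field applied to all brain-tissue CBV values.
#' @param structural_noise_sd additive Gaussian noise SD on the structural
#'   images (arbitrary intensity units).
#' @param leakage_t1_dominant logical; `TRUE` (default) makes extravasation
#'   reduce the apparent concentration (T1-dominant leakage), `FALSE` makes
#'   it add (T2*-dominant).
#' @param recirc_delay_s delay of the recirculation bolus after first-pass
#'   arrival, seconds.
#' @param rng_seed integer seed; the phantom is a pure function of the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 12L),
                         voxel_size_mm = c(1.875, 1.875, 5),
                         tr_s = 1.5,
                         te_s = 0.030,
                         n_timepoints = 60L,
                         baseline_points = 8L,
                         snr = 50,
                         noise_model = c("gaussian", "rician"),
                         tissue_table = default_tissue_table(),
                         area_scale = 10,
                         tumor_center_frac = c(0.70, 0.50, 0.50),
                         tumor_radius_mm = 14,
                         necrosis_radius_frac = 0.45,
                         edema_margin_mm = 6,
                         vessel = TRUE,
                         cbv_heterogeneity = 0.12,
                         structural_noise_sd = 4,
                         leakage_t1_dominant = TRUE,
                         recirc_delay_s = 8,
                         rng_seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    tr_s = tr_s, te_s = te_s,
    n_timepoints = as.integer(n_timepoints),
    baseline_points = as.integer(baseline_points),
    snr = snr,
    noise_model = match.arg(noise_model),
    tissue_table = tissue_table,
    area_scale = area_scale,
    tumor_center_frac = tumor_center_frac,
    tumor_radius_mm = tumor_radius_mm,
    necrosis_radius_frac = necrosis_radius_frac,
    edema_margin_mm = edema_margin_mm,
    vessel = isTRUE(vessel),
    cbv_heterogeneity = cbv_heterogeneity,
    structural_noise_sd = structural_noise_sd,
    leakage_t1_dominant = isTRUE(leakage_t1_dominant),
    recirc_delay_s = recirc_delay_s,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the structural invariants of a [phantom_spec()]; signals a
#' validation error naming the offending field otherwise.
#'
#' @param spec a `phantom_spec`.
#' @return the spec, invisibly.
#' @export
validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8)) {
    stop_validation("grid_shape", "must be a triple of at least 8 voxels per axis")
  }
  if (length(spec$voxel_size_mm) != 3 || any(spec$voxel_size_mm <= 0)) {
    stop_validation("voxel_size_mm", "must be three positive lengths in mm")
  }
  if (spec$te_s <= 0) stop_validation("te_s", "echo time must be positive")
  if (spec$tr_s <= 0) stop_validation("tr_s", "repetition time must be positive")
  if (spec$baseline_points < 5) {
    stop_validation("baseline_points", "at least 5 pre-bolus frames are required")
  }
  if (spec$n_timepoints < spec$baseline_points + 10) {
    stop_validation("n_timepoints",
                    "must be at least baseline_points + 10 frames")
  }
  if (!(spec$snr > 0)) stop_validation("snr", "must be positive (Inf = noiseless)")
  tt <- spec$tissue_table
  need <- c("tissue", "true_cbv", "t0_s", "alpha", "beta_s", "recirc_frac",
            "k2_true")
  if (!all(need %in% names(tt))) {
    stop_validation("tissue_table", paste("missing columns:",
                                          paste(setdiff(need, names(tt)), collapse = ", ")))
  }
  if (!setequal(tt$tissue, tissue_names())) {
    stop_validation("tissue_table", "must contain exactly the 7 tissue labels")
  }
  if (any(tt$alpha <= 0) || any(tt$beta_s <= 0)) {
    stop_validation("tissue_table", "alpha and beta_s must be strictly positive")
  }
  if (any(tt$t0_s < 0) || any(tt$k2_true < 0) || any(tt$recirc_frac < 0)) {
    stop_validation("tissue_table", "t0_s, k2_true and recirc_frac must be nonnegative")
  }
  cbv <- stats::setNames(tt$true_cbv, tt$tissue)
  if (!(cbv["tumor_solid"] > cbv["nawm"])) {
    stop_validation("tissue_table",
                    "tumor_solid must be hyperperfused relative to nawm (true_cbv)")
  }
  # bolus must arrive after the baseline window
  t_base_end <- (spec$baseline_points - 1) * spec$tr_s
  if (any(tt$t0_s[tt$true_cbv > 0] <= t_base_end)) {
    stop_validation("tissue_table",
                    "bolus arrival t0_s must fall after the baseline window")
  }
  if (spec$necrosis_radius_frac < 0 || spec$necrosis_radius_frac >= 1) {
    stop_validation("necrosis_radius_frac", "must be in [0, 1)")
  }
  if (spec$tumor_radius_mm <= 0) {
    stop_validation("tumor_radius_mm", "must be positive")
  }
  invisible(spec)
}

#' Specification of a simulated observer
#'
#' Models the delineation habits of one reader: smooth radial jitter of the
#' outlined mass margin, a systematic tight/loose boundary bias, occasional
#' wrong inclusion of excluded tissue (necrosis, vessels, edema), jitter in
#' the placement of the contralateral white-matter reference ROI, and a
#' larger margin uncertainty on T2WI where edema blurs the mass boundary.
#'
#' @param observer_id 1 or 2.
#' @param boundary_jitter_mm SD of the smooth radial boundary perturbation.
#' @param boundary_bias_mm systematic radial offset (positive = generous
#'   outlines, negative = tight outlines); a stable per-reader habit.
#' @param inclusion_error_rate probability that an excluded-tissue voxel
#'   inside the outline is wrongly retained.
#' @param nawm_roi_placement_jitter_mm SD of the reference-ROI placement.
#' @param t2_jitter_factor multiplier on `boundary_jitter_mm` when
#'   delineating on T2WI.
#' @param rng_seed integer seed for this observer/session.
#' @return object of class `observer_spec`.
#' @export
observer_spec <- function(observer_id = 1L,
                          boundary_jitter_mm = 1.0,
                          boundary_bias_mm = 0,
                          inclusion_error_rate = 0.05,
                          nawm_roi_placement_jitter_mm = 4,
                          t2_jitter_factor = 1.5,
                          rng_seed = 1L) {
  if (!observer_id %in% c(1L, 2L)) {
    stop_validation("observer_id", "must be 1 or 2")
  }
  if (boundary_jitter_mm < 0) {
    stop_validation("boundary_jitter_mm", "must be nonnegative")
  }
  if (inclusion_error_rate < 0 || inclusion_error_rate > 1) {
    stop_validation("inclusion_error_rate", "must be a probability in [0, 1]")
  }
  if (nawm_roi_placement_jitter_mm < 0) {
    stop_validation("nawm_roi_placement_jitter_mm", "must be nonnegative")
  }
  structure(list(
    observer_id = as.integer(observer_id),
    boundary_jitter_mm = boundary_jitter_mm,
    boundary_bias_mm = boundary_bias_mm,
    inclusion_error_rate = inclusion_error_rate,
    nawm_roi_placement_jitter_mm = nawm_roi_placement_jitter_mm,
    t2_jitter_factor = t2_jitter_factor,
    rng_seed = as.integer(rng_seed)
  ), class = "observer_spec")
}
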