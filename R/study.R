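# The reproducibility experiment: 2 observers x 2 sessions x
# {manual, semiautomatic} x {CE-T1WI, T2WI} = 16 records per mass
# (8 measurement occasions per observer), executed on a synthetic cohort,
# plus the report tables.

STRUCTURAL_TAGS <- c(ce_t1wi = "CE_T1WI", t2wi = "T2WI")

#' Default study configuration
#'
#' The packaged study conditions: a cohort of phantom masses whose tumor
#' blood volume, size and necrosis vary across masses the way a
#' glioblastoma cohort's do, two observers with 1 mm boundary jitter,
#' opposite systematic outline habits (generous vs tight by 0.75 mm), 4 mm
#' reference-ROI placement jitter, and the pipeline defaults
#' (leakage-corrected CBV, 7 clusters, absolute-agreement ICC, RMS CV
#' aggregation).
#'
#' @param n_masses number of phantom masses in the cohort.
#' @param master_seed integer master seed; every stage seed derives from it.
#' @param grid_shape,snr phantom geometry and noise level.
#' @param boundary_jitter_mm,inclusion_error_rate,nawm_jitter_mm,
#'   observer_bias_mm observer-variability magnitudes; `observer_bias_mm`
#'   is applied as +bias for observer 1 and -bias for observer 2.
#' @param cbv_heterogeneity,structural_noise_sd phantom realism settings
#'   passed through to [phantom_spec()].
#' @param cbv_mode CBV estimator for the maps.
#' @param k cluster count for the semiautomatic segmentation.
#' @param icc_variant,cv_agg statistics variants.
#' @return object of class `study_config`.
#' @export
default_study_config <- function(n_masses = 20L,
                                 master_seed = 1234L,
                                 grid_shape = c(48L, 48L, 12L),
                                 snr = 50,
                                 boundary_jitter_mm = 1.0,
                                 inclusion_error_rate = 0.05,
                                 nawm_jitter_mm = 4,
                                 observer_bias_mm = 0.75,
                                 cbv_heterogeneity = 0.12,
                                 structural_noise_sd = 4,
                                 cbv_mode = "leakage_corrected",
                                 k = 7L,
                                 icc_variant = "agreement",
                                 cv_agg = "rms") {
  structure(list(
    n_masses = as.integer(n_masses),
    master_seed = as.integer(master_seed),
    grid_shape = as.integer(grid_shape),
    snr = snr,
    cbv_heterogeneity = cbv_heterogeneity,
    structural_noise_sd = structural_noise_sd,
    boundary_jitter_mm = boundary_jitter_mm,
    inclusion_error_rate = inclusion_error_rate,
    nawm_jitter_mm = nawm_jitter_mm,
    observer_bias_mm = observer_bias_mm,
    cbv_mode = cbv_mode,
    k = as.integer(k),
    icc_variant = icc_variant,
    cv_agg = cv_agg
  ), class = "study_config")
}

#' Phantom specification for one cohort mass
#'
#' Derives the per-mass [phantom_spec()] from the study config: tumor
#' blood volume is log-normal around 4.5 times white matter (clamped to
#' [1.5, 15]), radius uniform in 10-18 mm, a necrotic core is present in
#' 89% of masses (fraction 0.30-0.55 of the radius), an intralesional
#' macrovessel in 70%, and laterality alternates. Deterministic given the
#' master seed and mass id.
#'
#' @param config a [default_study_config()].
#' @param mass_id integer mass index.
#' @return a `phantom_spec`.
#' @export
cohort_phantom_spec <- function(config, mass_id) {
  seed <- derive_seed(config$master_seed, "mass", mass_id)
  with_seed(seed, {
    tumor_cbv <- min(max(exp(stats::rnorm(1, log(4.5), 0.5)), 1.5), 15)
    radius <- stats::runif(1, 10, 18)
    necro <- if (stats::runif(1) < 0.89) stats::runif(1, 0.30, 0.55) else 0
    vessel <- stats::runif(1) < 0.70
    side <- if (mass_id %% 2 == 0) 0.30 else 0.70
    cy <- stats::runif(1, 0.42, 0.58)
    tt <- default_tissue_table()
    tt$true_cbv[tt$tissue == "tumor_solid"] <- tumor_cbv
    phantom_spec(
      grid_shape = config$grid_shape,
      snr = config$snr,
      cbv_heterogeneity = config$cbv_heterogeneity %||% 0.12,
      structural_noise_sd = config$structural_noise_sd %||% 4,
      tissue_table = tt,
      tumor_center_frac = c(side, cy, 0.5),
      tumor_radius_mm = radius,
      necrosis_radius_frac = necro,
      vessel = vessel,
      rng_seed = derive_seed(seed, "phantom")
    )
  })
}

# observer spec for one design cell (observer x session), with the
# systematic per-observer boundary habit from the config
cell_observer_spec <- function(config, mass_id, observer, session) {
  observer_spec(
    observer_id = observer,
    boundary_jitter_mm = config$boundary_jitter_mm,
    boundary_bias_mm = if (observer == 1) config$observer_bias_mm
                       else -config$observer_bias_mm,
    inclusion_error_rate = config$inclusion_error_rate,
    nawm_roi_placement_jitter_mm = config$nawm_jitter_mm,
    rng_seed = derive_seed(config$master_seed, "mass", mass_id,
                           "obs", observer, "ses", session)
  )
}

# tumor dimensions (cm) of a mask for the ellipsoid volume formula
mask_dimensions_cm <- function(mask, vs) {
  idx <- which(mask, arr.ind = TRUE)
  vapply(1:3, function(a) {
    (max(idx[, a]) - min(idx[, a]) + 1) * vs[a] / 10
  }, numeric(1))
}

#' Run every design-cell measurement for one mass
#'
#' Executes manual and semiautomatic nCBV measurement for both observers,
#' both sessions and both structural images on one phantom study, exactly
#' as the study design prescribes. Session differences are realized by
#' per-session observer seeds.
#'
#' @param study a `phantom_study`.
#' @param config a `study_config`.
#' @param mass_id integer mass index.
#' @return data.frame of 16 measurement records (8 per observer).
#' @export
measure_mass <- function(study, config, mass_id) {
  conc <- signal_to_concentration(study$dynamic)
  cbv <- compute_cbv_map(conc, mode = config$cbv_mode,
                         labels = study$truth_labels)
  brain <- brain_mask_from_structural(study$ce_t1wi)
  vs <- study$spec$voxel_size_mm
  gs <- study$spec$grid_shape

  rows <- list()
  for (observer in 1:2) for (session in 1:2) {
    ospec <- cell_observer_spec(config, mass_id, observer, session)
    for (str in c("ce_t1wi", "t2wi")) {
      oseed <- derive_seed(ospec$rng_seed, str)
      del <- simulate_observer_rois(
        study,
        observer_spec(observer_id = ospec$observer_id,
                      boundary_jitter_mm = ospec$boundary_jitter_mm,
                      boundary_bias_mm = ospec$boundary_bias_mm,
                      inclusion_error_rate = ospec$inclusion_error_rate,
                      nawm_roi_placement_jitter_mm = ospec$nawm_roi_placement_jitter_mm,
                      t2_jitter_factor = ospec$t2_jitter_factor,
                      rng_seed = oseed),
        structural = str)

      # manual method: NAWM-ROI normalization, per-plane averaging,
      # ellipsoid volume from the delineated extents
      ncbv_man <- normalize_manual(cbv, del$nawm_roi, study$truth_labels)
      stat_m <- manual_mass_statistics(ncbv_man, del$manual_mask)
      dims <- mask_dimensions_cm(del$manual_mask, vs)
      vol_m <- ellipsoid_volume(dims[2], dims[3], dims[1])

      # semiautomatic method: VOI + EM clustering, automatic normalization
      vm <- voi_mask(del$voi, gs, vs)
      ncbv_auto <- normalize_auto(cbv, vm, brain)
      feats <- build_feature_vectors(study[[str]], ncbv_auto, vm)
      idx <- attr(feats, "voxel_index")
      model <- em_fit(feats, k = config$k,
                      seed = derive_seed(oseed, "em"))
      sel <- select_clusters(model, ncbv_auto$values[idx], study[[str]][idx])
      stat_s <- semiauto_mass_statistics(model, sel, ncbv_auto$values[idx], vs)

      rows[[length(rows) + 1]] <- data.frame(
        mass_id = mass_id, observer = observer, session = session,
        method = c("manual", "semiauto"),
        structural = STRUCTURAL_TAGS[[str]],
        mean_ncbv = c(stat_m$mean_ncbv, stat_s$mean_ncbv),
        sd_ncbv = c(stat_m$sd_ncbv, stat_s$sd_ncbv),
        n_voxels = c(stat_m$n_voxels, stat_s$n_voxels),
        volume_ml = c(vol_m, stat_s$volume_ml),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full reproducibility study on a phantom cohort
#'
#' Generates (or accepts) a cohort of phantom masses, performs the 8
#' measurement occasions per observer on each mass, and computes the agreement tables: intraobserver
#' (per observer, method and structural image), interobserver (per session,
#' method and structural image), interobserver volume agreement, and the
#' cohort nCBV summary. Fully deterministic given the config's master seed.
#'
#' @param config a [default_study_config()].
#' @param cohort optional list of pre-generated `phantom_study` objects;
#'   generated from the config when NULL.
#' @param progress print per-mass progress to stderr.
#' @return list: `measurements` (the measurement table),
#'   `intraobserver`, `interobserver`, `volume_interobserver`,
#'   `ncbv_summary` (data.frames), `config`.
#' @export
run_reproducibility_study <- function(config = default_study_config(),
                                      cohort = NULL, progress = FALSE) {
  n <- if (is.null(cohort)) config$n_masses else length(cohort)
  if (n < 3) stop_validation("n_masses", "need at least 3 masses")
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    study <- if (is.null(cohort)) {
      generate_phantom(cohort_phantom_spec(config, i))
    } else cohort[[i]]
    meas[[i]] <- measure_mass(study, config, i)
    if (progress) message(sprintf("mass %d/%d done", i, n))
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL
  c(list(measurements = measurements, config = config),
    build_report_tables(measurements, icc_variant = config$icc_variant,
                        cv_agg = config$cv_agg))
}

# check the 8-cell design is complete for every mass; error listing missing
# (mass, cell) pairs otherwise
check_design_complete <- function(meas) {
  cells <- expand.grid(observer = 1:2, session = 1:2,
                       method = c("manual", "semiauto"),
                       structural = unname(STRUCTURAL_TAGS),
                       stringsAsFactors = FALSE)
  missing <- character(0)
  for (m in unique(meas$mass_id)) {
    sub <- meas[meas$mass_id == m, ]
    for (r in seq_len(nrow(cells))) {
      hit <- sub$observer == cells$observer[r] &
        sub$session == cells$session[r] &
        sub$method == cells$method[r] &
        sub$structural == cells$structural[r]
      if (sum(hit) != 1) {
        missing <- c(missing, sprintf(
          "mass %s: observer %d session %d %s %s", m, cells$observer[r],
          cells$session[r], cells$method[r], cells$structural[r]))
      }
    }
  }
  if (length(missing)) {
    stop_validation("measurements", paste0(
      "incomplete design cells:\n  ", paste(missing, collapse = "\n  ")))
  }
  invisible(TRUE)
}

pair_values <- function(meas, value, split_by, split_vals, method, structural) {
  sub <- meas[meas$method == method & meas$structural == structural, ]
  a <- sub[sub[[split_by]] == split_vals[1], ]
  b <- sub[sub[[split_by]] == split_vals[2], ]
  a <- a[order(a$mass_id), ]; b <- b[order(b$mass_id), ]
  list(m1 = a[[value]], m2 = b[[value]])
}

agreement_row <- function(ag) {
  data.frame(icc = ag$icc, icc_lo = ag$icc_ci95[1], icc_hi = ag$icc_ci95[2],
             icc_category = ag$icc_category, cv_percent = ag$cv_percent,
             bias = ag$bias, loa_low = ag$loa_low, loa_high = ag$loa_high,
             paired_t_p = ag$paired_t_p, n_pairs = ag$n_pairs,
             stringsAsFactors = FALSE)
}

#' Build the agreement report tables from a measurement table
#'
#' @param meas measurement data.frame (columns `mass_id`, `observer`,
#'   `session`, `method`, `structural`, `mean_ncbv`, `sd_ncbv`,
#'   `n_voxels`, `volume_ml`).
#' @param icc_variant,cv_agg statistics variants.
#' @return list of data.frames: `intraobserver`, `interobserver`,
#'   `volume_interobserver`, `ncbv_summary`.
#' @export
build_report_tables <- function(meas, icc_variant = "agreement",
                                cv_agg = "rms") {
  need <- c("mass_id", "observer", "session", "method", "structural",
            "mean_ncbv", "sd_ncbv", "n_voxels", "volume_ml")
  miss <- setdiff(need, names(meas))
  if (length(miss)) {
    stop_validation(miss[1], "missing measurement-table column")
  }
  check_design_complete(meas)
  methods <- c("manual", "semiauto")
  structs <- unname(STRUCTURAL_TAGS)

  intra <- list()
  for (obs in 1:2) for (m in methods) for (s in structs) {
    sub <- meas[meas$observer == obs, ]
    pv <- pair_values(sub, "mean_ncbv", "session", c(1, 2), m, s)
    ag <- agreement_summary(pv$m1, pv$m2, icc_variant, cv_agg)
    intra[[length(intra) + 1]] <- cbind(
      data.frame(observer = obs, method = m, structural = s),
      agreement_row(ag))
  }

  inter <- vol_inter <- list()
  for (ses in 1:2) for (m in methods) for (s in structs) {
    sub <- meas[meas$session == ses, ]
    pv <- pair_values(sub, "mean_ncbv", "observer", c(1, 2), m, s)
    ag <- agreement_summary(pv$m1, pv$m2, icc_variant, cv_agg)
    inter[[length(inter) + 1]] <- cbind(
      data.frame(session = ses, method = m, structural = s),
      agreement_row(ag))
    pvv <- pair_values(sub, "volume_ml", "observer", c(1, 2), m, s)
    agv <- agreement_summary(pvv$m1, pvv$m2, icc_variant, cv_agg)
    vol_inter[[length(vol_inter) + 1]] <- cbind(
      data.frame(session = ses, method = m, structural = s),
      agreement_row(agv))
  }

  summ <- list()
  for (m in methods) for (s in structs) for (obs in 1:2) for (ses in 1:2) {
    sub <- meas[meas$method == m & meas$structural == s &
                  meas$observer == obs & meas$session == ses, ]
    summ[[length(summ) + 1]] <- data.frame(
      method = m, structural = s, observer = obs, session = ses,
      mean_ncbv = mean(sub$mean_ncbv), sd_ncbv = sample_sd(sub$mean_ncbv),
      mean_volume_ml = mean(sub$volume_ml), n_masses = nrow(sub),
      stringsAsFactors = FALSE)
  }

  list(intraobserver = do.call(rbind, intra),
       interobserver = do.call(rbind, inter),
       volume_interobserver = do.call(rbind, vol_inter),
       ncbv_summary = do.call(rbind, summ))
}
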