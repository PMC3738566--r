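# 4D digital DSC phantom: labeled tissue compartments, gamma-variate bolus
# dynamics with recirculation and tumor contrast leakage, structural images.

#' Gamma-variate bolus curve
#'
#' `k * (t - t0)^alpha * exp(-(t - t0) / beta)` for `t > t0`, zero before
#' arrival. The canonical first-pass bolus shape.
#'
#' @param t time vector, seconds.
#' @param k amplitude.
#' @param t0 bolus arrival time, seconds.
#' @param alpha shape parameter (> 0).
#' @param beta scale parameter, seconds (> 0).
#' @return numeric vector of curve values.
#' @export
gamma_variate <- function(t, k, t0, alpha, beta) {
  out <- numeric(length(t))
  idx <- t > t0
  dt <- t[idx] - t0
  out[idx] <- k * dt^alpha * exp(-dt / beta)
  out
}

# Analytic area under a gamma-variate with amplitude k:
# integral over (t0, Inf) = k * beta^(alpha+1) * Gamma(alpha+1).
gamma_variate_area <- function(k, alpha, beta) {
  k * beta^(alpha + 1) * gamma(alpha + 1)
}

# Amplitude giving a requested first-pass area.
gamma_variate_amplitude <- function(area, alpha, beta) {
  area / (beta^(alpha + 1) * gamma(alpha + 1))
}

# Build the tissue label map for a spec: ellipsoidal brain with a gray
# matter shell, a spherical tumor with optional necrotic core and
# intralesional vessel, surrounded by an edema shell.
make_label_map <- function(spec) {
  gs <- spec$grid_shape
  vs <- spec$voxel_size_mm
  fov <- gs * vs
  pts <- grid_centers_mm(gs, vs)
  brain_c <- fov / 2
  brain_ax <- fov / 2 - c(4, 4, 3)

  dn2 <- ((pts[, 1] - brain_c[1]) / brain_ax[1])^2 +
    ((pts[, 2] - brain_c[2]) / brain_ax[2])^2 +
    ((pts[, 3] - brain_c[3]) / brain_ax[3])^2
  labels <- rep(TISSUE_LABELS[["background"]], nrow(pts))
  brain <- dn2 <= 1
  labels[brain] <- TISSUE_LABELS[["gray_matter"]]
  labels[dn2 <= 0.78^2] <- TISSUE_LABELS[["nawm"]]

  tc <- spec$tumor_center_frac * fov
  dt2 <- sqrt((pts[, 1] - tc[1])^2 + (pts[, 2] - tc[2])^2 +
                (pts[, 3] - tc[3])^2)
  r <- spec$tumor_radius_mm
  edema <- brain & dt2 <= r + spec$edema_margin_mm
  labels[edema] <- TISSUE_LABELS[["edema"]]
  labels[dt2 <= r] <- TISSUE_LABELS[["tumor_solid"]]
  rn <- spec$necrosis_radius_frac * r
  if (rn > 0) labels[dt2 <= rn] <- TISSUE_LABELS[["necrosis_cyst"]]

  if (spec$vessel) {
    # thin cylinder through the solid rim, along z, offset from the core
    voff <- rn + 0.55 * (r - rn)
    vx <- tc[1] + voff
    dv <- sqrt((pts[, 1] - vx)^2 + (pts[, 2] - tc[2])^2)
    labels[dv <= 2.0 & dt2 <= r & labels == TISSUE_LABELS[["tumor_solid"]]] <-
      TISSUE_LABELS[["macrovessel"]]
  }

  structure(list(
    labels = array(labels, dim = gs),
    voxel_size_mm = vs
  ), class = "tissue_label_map")
}

# Smooth multiplicative heterogeneity field with approximately unit mean and
# the requested SD: a sum of random-phase low-frequency cosines.
heterogeneity_field <- function(spec) {
  gs <- spec$grid_shape
  if (spec$cbv_heterogeneity <= 0) return(array(1, dim = gs))
  pts <- grid_centers_mm(gs, spec$voxel_size_mm)
  fov <- gs * spec$voxel_size_mm
  n_waves <- 4L
  f <- numeric(nrow(pts))
  for (w in seq_len(n_waves)) {
    freq <- stats::runif(3, 0.5, 1.6) / fov     # 0.5-1.6 cycles across FOV
    phase <- stats::runif(3, 0, 2 * pi)
    f <- f + cos(2 * pi * pts[, 1] * freq[1] + phase[1]) *
      cos(2 * pi * pts[, 2] * freq[2] + phase[2]) *
      cos(2 * pi * pts[, 3] * freq[3] + phase[3])
  }
  f <- (f - mean(f)) / stats::sd(f)
  field <- 1 + spec$cbv_heterogeneity * pmax(pmin(f, 3), -3)
  array(pmax(field, 0.05), dim = gs)
}

# Structural image intensity tables. CE-T1WI separates the compartments
# (enhancing solid tumor bright, necrosis dark); on T2WI fluid-rich necrosis
# and edema are both bright and close to tumor signal, the classic
# overlapping-contrast situation.
structural_intensity <- function(which = c("ce_t1wi", "t2wi")) {
  which <- match.arg(which)
  if (which == "ce_t1wi") {
    c(background = 10, nawm = 100, gray_matter = 110, tumor_solid = 220,
      necrosis_cyst = 60, edema = 90, macrovessel = 200)
  } else {
    c(background = 10, nawm = 100, gray_matter = 115, tumor_solid = 170,
      necrosis_cyst = 195, edema = 185, macrovessel = 40)
  }
}

render_structural <- function(labels, which, noise_sd) {
  ints <- structural_intensity(which)
  img <- array(ints[tissue_names()][labels + 1L], dim = dim(labels))
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(labels))
  }
  img
}

#' Generate a synthetic DSC perfusion study
#'
#' Builds a complete 4D phantom from a [phantom_spec()]: tissue label map,
#' ground-truth CBV and leakage-rate maps, dynamic signal
#' `S(t) = S0 * exp(-TE * dR2*(t)) + noise` where the true concentration
#' curve is a per-tissue gamma-variate first pass plus a delayed, dispersed
#' recirculation bolus, minus (T1-dominant, the default) or plus
#' (T2*-dominant) a leakage term `k2 * integral of the first pass` in leaky
#' tumor voxels; and CE-T1WI / T2WI structural images. The result is a pure
#' function of the spec: same spec (same seed) gives a bit-identical study.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_study` with elements `dynamic` (a
#'   `dynamic_series`), `ce_t1wi`, `t2wi`, `truth_labels`, `truth_cbv`,
#'   `truth_k2`, and the generating `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$rng_seed, {
    gs <- spec$grid_shape
    nt <- spec$n_timepoints
    time_s <- (seq_len(nt) - 1) * spec$tr_s
    lab_map <- make_label_map(spec)
    labels <- lab_map$labels
    het <- heterogeneity_field(spec)

    tt <- spec$tissue_table
    tt <- tt[match(tissue_names(), tt$tissue), ]

    truth_cbv <- array(tt$true_cbv[labels + 1L], dim = gs) * het
    truth_k2 <- array(tt$k2_true[labels + 1L], dim = gs)

    # per-tissue unit-CBV curves (first pass, recirculation, leakage basis)
    n_vox <- prod(gs)
    dr2 <- matrix(0, nrow = nt, ncol = n_vox)
    lab_vec <- as.vector(labels)
    cbv_vec <- as.vector(truth_cbv)
    k2_vec <- as.vector(truth_k2)
    leak_sign <- if (spec$leakage_t1_dominant) -1 else 1
    for (i in seq_len(nrow(tt))) {
      sel <- lab_vec == TISSUE_LABELS[[tt$tissue[i]]]
      if (!any(sel) || tt$true_cbv[i] <= 0) next
      k_fp <- gamma_variate_amplitude(spec$area_scale, tt$alpha[i], tt$beta_s[i])
      fp <- gamma_variate(time_s, k_fp, tt$t0_s[i], tt$alpha[i], tt$beta_s[i])
      rc_beta <- 2 * tt$beta_s[i]
      k_rc <- gamma_variate_amplitude(tt$recirc_frac[i] * spec$area_scale,
                                      tt$alpha[i], rc_beta)
      rc <- gamma_variate(time_s, k_rc, tt$t0_s[i] + spec$recirc_delay_s,
                          tt$alpha[i], rc_beta)
      base <- fp + rc
      dr2[, sel] <- outer(base, cbv_vec[sel])
      leaky <- sel & k2_vec > 0
      if (any(leaky)) {
        cum_fp <- cumtrapz_time(fp, time_s)
        dr2[, leaky] <- dr2[, leaky] +
          leak_sign * outer(cum_fp, k2_vec[leaky] * cbv_vec[leaky])
      }
    }

    s0 <- ifelse(lab_vec == TISSUE_LABELS[["background"]], 2, 100)
    signal <- exp(-spec$te_s * dr2)
    signal <- sweep(signal, 2, s0, `*`)
    if (is.finite(spec$snr)) {
      sd_noise <- 100 / spec$snr
      noise <- matrix(stats::rnorm(length(signal), 0, sd_noise),
                      nrow = nt)
      if (spec$noise_model == "rician") {
        noise2 <- matrix(stats::rnorm(length(signal), 0, sd_noise), nrow = nt)
        signal <- sqrt((signal + noise)^2 + noise2^2)
      } else {
        signal <- signal + noise
      }
    }

    dynamic <- dynamic_series(
      signal = array(t(signal), dim = c(gs, nt)),
      tr_s = spec$tr_s, te_s = spec$te_s,
      voxel_size_mm = spec$voxel_size_mm,
      baseline_points = spec$baseline_points
    )

    ce <- render_structural(labels, "ce_t1wi", spec$structural_noise_sd)
    t2 <- render_structural(labels, "t2wi", spec$structural_noise_sd)

    structure(list(
      dynamic = dynamic,
      ce_t1wi = ce,
      t2wi = t2,
      truth_labels = lab_map,
      truth_cbv = truth_cbv,
      truth_k2 = truth_k2,
      spec = spec
    ), class = "phantom_study")
  })
}

#' Per-tissue mean of a 3D map
#'
#' Convenience accessor used in recovery checks: the mean of `map` over each
#' labeled tissue compartment.
#'
#' @param map 3D numeric array.
#' @param label_map a `tissue_label_map`.
#' @return named numeric vector, one entry per tissue present.
#' @export
tissue_means <- function(map, label_map) {
  labs <- label_map$labels
  out <- vapply(tissue_names(), function(tn) {
    sel <- labs == TISSUE_LABELS[[tn]]
    if (!any(sel)) return(NA_real_)
    mean(map[sel], na.rm = TRUE)
  }, numeric(1))
  out[!is.na(out)]
}
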