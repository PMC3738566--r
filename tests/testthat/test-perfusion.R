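# Concentration conversion, reference curve, leakage correction, CBV maps
# and both normalization schemes.

test_that("constant signal converts to zero concentration; single-frame drop inverts exactly", {
  gs <- c(4L, 4L, 2L)
  nt <- 20L
  sig <- array(100, dim = c(gs, nt))
  ds <- dynamic_series(sig, 1.5, 0.03, c(1.875, 1.875, 5), 5L)
  conc <- signal_to_concentration(ds)
  expect_equal(max(abs(conc$delta_r2s)), 0)
  # one frame drops by exp(-TE * x)
  x <- 4.2
  sig[1, 1, 1, 12] <- 100 * exp(-0.03 * x)
  conc2 <- signal_to_concentration(
    dynamic_series(sig, 1.5, 0.03, c(1.875, 1.875, 5), 5L))
  expect_equal(conc2$delta_r2s[1, 1, 1, 12], x, tolerance = 1e-12)
})

test_that("all-zero voxels are flagged invalid, not an exception", {
  gs <- c(3L, 3L, 1L)
  sig <- array(100, dim = c(gs, 20L))
  sig[2, 2, 1, ] <- 0
  conc <- signal_to_concentration(
    dynamic_series(sig, 1.5, 0.03, c(1.875, 1.875, 5), 5L))
  expect_false(conc$valid[2, 2, 1])
  expect_true(all(is.na(conc$delta_r2s[2, 2, 1, ])))
  expect_true(conc$valid[1, 1, 1])
})

test_that("concentration noise matches analytic first-order propagation", {
  # S = S0 exp(-TE x) + noise => sd(dR2*) ~ sd_noise / (TE * S)
  set.seed(31)
  nt <- 60L; n_rep <- 4000L
  s0 <- 100; te <- 0.03; sd_n <- 1            # SNR 100
  x_true <- 3
  clean <- s0 * exp(-te * x_true)
  sig <- array(s0, dim = c(n_rep, 1, 1, nt))
  sig[, 1, 1, 30] <- clean
  sig <- sig + array(rnorm(length(sig), 0, sd_n), dim = dim(sig))
  conc <- signal_to_concentration(dynamic_series(sig, 1.5, te, c(1, 1, 1), 8L))
  err <- conc$delta_r2s[, 1, 1, 30] - x_true
  prop_sd <- sd_n / (te * clean)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 3 * prop_sd)
  expect_gt(sqrt(mean(err^2, na.rm = TRUE)), prop_sd / 3)
})

test_that("reference curve averages nonleaky parenchyma exactly", {
  gs <- c(8L, 8L, 2L)
  nt <- 20L
  labs <- array(TISSUE_LABELS[["nawm"]], dim = gs)
  labs[, 1:4, ] <- TISSUE_LABELS[["gray_matter"]]
  lm <- structure(list(labels = labs, voxel_size_mm = c(1, 1, 1)),
                  class = "tissue_label_map")
  trace_a <- sin(seq_len(nt)) + 2
  trace_b <- cos(seq_len(nt)) + 2
  dr2 <- array(0, dim = c(gs, nt))
  for (t in seq_len(nt)) {
    dr2[, 1:4, , t] <- trace_a[t]
    dr2[, 5:8, , t] <- trace_b[t]
  }
  conc <- structure(list(delta_r2s = dr2, time_s = (1:nt - 1) * 1.5,
                         valid = array(TRUE, dim = gs),
                         voxel_size_mm = c(1, 1, 1), baseline_points = 8L),
                    class = "concentration_series")
  expect_equal(reference_tissue_curve(conc, lm), (trace_a + trace_b) / 2)
  # brute-force masked mean on a phantom
  st <- generate_phantom(noisy_spec())
  pc <- signal_to_concentration(st$dynamic)
  ref <- reference_tissue_curve(pc, st$truth_labels)
  sel <- (st$truth_labels$labels %in%
            TISSUE_LABELS[c("nawm", "gray_matter")]) & pc$valid
  brute <- sapply(seq_along(pc$time_s), function(t) {
    mean(pc$delta_r2s[, , , t][sel])
  })
  expect_equal(ref, brute, tolerance = 1e-12)
})

test_that("too few reference voxels is an error", {
  gs <- c(4L, 4L, 1L)
  labs <- array(TISSUE_LABELS[["tumor_solid"]], dim = gs)
  lm <- structure(list(labels = labs, voxel_size_mm = c(1, 1, 1)),
                  class = "tissue_label_map")
  conc <- structure(list(delta_r2s = array(1, dim = c(gs, 20L)),
                         time_s = (1:20 - 1) * 1.5,
                         valid = array(TRUE, dim = gs),
                         voxel_size_mm = c(1, 1, 1), baseline_points = 8L),
                    class = "concentration_series")
  expect_error(reference_tissue_curve(conc, lm), "reference",
               class = "dscrepro_validation_error")
})

test_that("leakage fit recovers constructed (k1, k2) against the normal-equation oracle", {
  cv <- make_gamma_curve()
  ref <- cv$y
  cum <- cumtrapz_oracle(ref, cv$t)
  trace <- 2 * ref - 0.01 * cum
  fit <- leakage_correct(trace, ref, cv$t)
  expect_equal(fit$k1, 2.0, tolerance = 1e-6)
  expect_equal(fit$k2, 0.01, tolerance = 1e-6)
  # oracle: solve the 2x2 normal equations explicitly
  a11 <- sum(ref * ref); a12 <- sum(ref * -cum)
  a22 <- sum(cum * cum); b1 <- sum(ref * trace); b2 <- sum(-cum * trace)
  det <- a11 * a22 - a12 * a12
  k1_o <- (a22 * b1 - a12 * b2) / det
  k2_o <- (a11 * b2 - a12 * b1) / det
  expect_equal(fit$k1, k1_o, tolerance = 1e-10)
  expect_equal(fit$k2, k2_o, tolerance = 1e-10)
  # identity case
  fit0 <- leakage_correct(ref, ref, cv$t)
  expect_equal(fit0$k1, 1, tolerance = 1e-10)
  expect_equal(fit0$k2, 0, tolerance = 1e-10)
  expect_equal(fit0$corrected, ref, tolerance = 1e-9)
})

test_that("degenerate reference curve is rejected", {
  t <- (0:19) * 1.5
  expect_error(leakage_correct(rnorm(20), rep(0, 20), t), "ref",
               class = "dscrepro_validation_error")
})

test_that("correction moves a leaky tumor voxel's CBV toward truth", {
  tt <- dscrepro:::default_tissue_table()
  tt$k2_true[tt$tissue == "tumor_solid"] <- 0.02
  st <- generate_phantom(quiet_spec(tissue_table = tt))
  conc <- signal_to_concentration(st$dynamic)
  ref <- reference_tissue_curve(conc, st$truth_labels)
  tum <- which(st$truth_labels$labels == TISSUE_LABELS[["tumor_solid"]],
               arr.ind = TRUE)
  v <- tum[1, ]
  trace <- conc$delta_r2s[v[1], v[2], v[3], ]
  fit <- leakage_correct(trace, ref, conc$time_s)
  raw_cbv <- trapz_oracle(trace, conc$time_s)
  cor_cbv <- trapz_oracle(fit$corrected, conc$time_s)
  # truth: area_scale * true_cbv at that voxel, plus recirculation fraction
  truth <- st$truth_cbv[v[1], v[2], v[3]] * st$spec$area_scale * 1.25
  expect_lt(abs(cor_cbv - truth), abs(raw_cbv - truth))
  expect_gt(fit$k2, 0)
})

test_that("CBV maps equal a straight-loop oracle on a small instance", {
  set.seed(5)
  gs <- c(8L, 8L, 2L)
  nt <- 20L
  dr2 <- array(abs(rnorm(prod(gs) * nt)), dim = c(gs, nt))
  t_s <- (1:nt - 1) * 1.5
  conc <- structure(list(delta_r2s = dr2, time_s = t_s,
                         valid = array(TRUE, dim = gs),
                         voxel_size_mm = c(1, 1, 1), baseline_points = 8L),
                    class = "concentration_series")
  cbv <- compute_cbv_map(conc, "raw")
  oracle <- array(0, dim = gs)
  for (i in 1:gs[1]) for (j in 1:gs[2]) for (k in 1:gs[3]) {
    oracle[i, j, k] <- trapz_oracle(dr2[i, j, k, ], t_s)
  }
  expect_equal(cbv$values, oracle, tolerance = 1e-12)
})

test_that("zero concentration gives a zero CBV map; recirculation inflates raw vs gamma fit", {
  gs <- c(6L, 6L, 1L)
  conc0 <- structure(list(delta_r2s = array(0, dim = c(gs, 20L)),
                          time_s = (1:20 - 1) * 1.5,
                          valid = array(TRUE, dim = gs),
                          voxel_size_mm = c(1, 1, 1), baseline_points = 8L),
                     class = "concentration_series")
  expect_true(all(compute_cbv_map(conc0, "raw")$values == 0))

  st <- generate_phantom(quiet_spec())
  conc <- signal_to_concentration(st$dynamic)
  raw <- compute_cbv_map(conc, "raw")
  gam <- compute_cbv_map(conc, "gamma_fit")
  parench <- st$truth_labels$labels %in% TISSUE_LABELS[c("nawm", "gray_matter")]
  expect_true(all(raw$values[parench] > gam$values[parench]))
  # first-pass ratio survives the gamma fit
  nawm <- st$truth_labels$labels == TISSUE_LABELS[["nawm"]]
  gm <- st$truth_labels$labels == TISSUE_LABELS[["gray_matter"]]
  expect_equal(mean(gam$values[gm]) / mean(gam$values[nawm]), 2,
               tolerance = 0.02)
})

test_that("leakage_corrected mode requires labels", {
  st <- generate_phantom(quiet_spec())
  conc <- signal_to_concentration(st$dynamic)
  expect_error(compute_cbv_map(conc, "leakage_corrected"), "labels",
               class = "dscrepro_validation_error")
})

test_that("manual normalization enforces the ROI protocol", {
  gs <- c(16L, 16L, 2L)
  vs <- c(1.875, 1.875, 5)
  vals <- array(2, dim = gs)
  cbv <- structure(list(values = vals, mode = "raw", voxel_size_mm = vs,
                        n_clipped = 0L, n_fit_failed = 0L), class = "cbv_map")
  labs <- array(TISSUE_LABELS[["nawm"]], dim = gs)
  lm <- structure(list(labels = labs, voxel_size_mm = vs),
                  class = "tissue_label_map")
  roi <- array(FALSE, dim = gs); roi[1:4, 1:3, 1] <- TRUE   # 12 vox = 42.2 mm^2
  ncbv <- normalize_manual(cbv, roi, lm)
  expect_true(all(ncbv$values == 1))
  expect_equal(ncbv$reference_value, 2)
  # 11 voxels = 38.7 mm^2 < 40
  roi39 <- array(FALSE, dim = gs); roi39[1:11, 1, 1] <- TRUE
  expect_error(normalize_manual(cbv, roi39, lm), "40 mm",
               class = "dscrepro_validation_error")
  # gray matter contamination
  labs2 <- labs; labs2[2, 2, 1] <- TISSUE_LABELS[["gray_matter"]]
  lm2 <- structure(list(labels = labs2, voxel_size_mm = vs),
                   class = "tissue_label_map")
  expect_error(normalize_manual(cbv, roi, lm2), "gray",
               class = "dscrepro_validation_error")
  # 4x tumor contrast
  vals4 <- vals; vals4[10:12, 10:12, 2] <- 8
  cbv4 <- structure(list(values = vals4, mode = "raw", voxel_size_mm = vs,
                         n_clipped = 0L, n_fit_failed = 0L), class = "cbv_map")
  n4 <- normalize_manual(cbv4, roi, lm)
  expect_equal(unique(as.vector(n4$values[10:12, 10:12, 2])), 4)
})

test_that("automatic normalization divides by the outside-tumor brain mean", {
  gs <- c(10L, 10L, 1L)
  vals <- array(2, dim = gs)
  mask <- array(FALSE, dim = gs); mask[4:6, 4:6, 1] <- TRUE
  vals[mask] <- 8
  brain <- array(TRUE, dim = gs)
  cbv <- structure(list(values = vals, mode = "raw",
                        voxel_size_mm = c(1, 1, 1),
                        n_clipped = 0L, n_fit_failed = 0L), class = "cbv_map")
  ncbv <- normalize_auto(cbv, mask, brain)
  expect_equal(unique(as.vector(ncbv$values[mask])), 4)
  expect_equal(ncbv$reference_value, mean(vals[brain & !mask]))
  expect_error(normalize_auto(cbv, brain, brain), "brain",
               class = "dscrepro_validation_error")
})

test_that("both normalizations are invariant to a global CBV rescaling", {
  st <- generate_phantom(noisy_spec())
  conc <- signal_to_concentration(st$dynamic)
  cbv <- compute_cbv_map(conc, "raw")
  del <- simulate_observer_rois(st, observer_spec(rng_seed = 3L), "ce_t1wi")
  brain <- st$truth_labels$labels != TISSUE_LABELS[["background"]]
  vm <- voi_mask(del$voi, dim(cbv$values), st$spec$voxel_size_mm)
  scaled <- cbv; scaled$values <- cbv$values * 7.3
  a1 <- normalize_manual(cbv, del$nawm_roi, st$truth_labels)
  a2 <- normalize_manual(scaled, del$nawm_roi, st$truth_labels)
  expect_equal(a1$values, a2$values, tolerance = 1e-12)
  b1 <- normalize_auto(cbv, vm, brain)
  b2 <- normalize_auto(scaled, vm, brain)
  expect_equal(b1$values, b2$values, tolerance = 1e-12)
})
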