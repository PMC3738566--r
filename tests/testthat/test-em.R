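# EM Gaussian mixture and the cluster-selection surrogate.

test_that("cluster count outside 3..7 is rejected unless overridden", {
  X <- matrix(rnorm(400), ncol = 2)
  expect_error(em_fit(X, k = 8L), "cluster count",
               class = "dscrepro_validation_error")
  expect_error(em_fit(X, k = 2L), "cluster count",
               class = "dscrepro_validation_error")
  expect_s3_class(em_fit(X, k = 2L, allow_any_k = TRUE), "cluster_model")
})

test_that("well-separated blobs are recovered with ARI >= 0.99", {
  set.seed(21)
  n <- 150
  X <- rbind(cbind(rnorm(n, -4, 0.5), rnorm(n, 0, 0.5)),
             cbind(rnorm(n, 4, 0.5), rnorm(n, 0, 0.5)))
  truth <- rep(1:2, each = n)
  model <- em_fit(X, k = 2L, seed = 5L, allow_any_k = TRUE)
  ari <- adjusted_rand_index(model$labels, truth)
  expect_gte(ari, 0.99)
  # cross-check the helper ARI against mclust's implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(model$labels, truth),
                 tolerance = 1e-12)
  }
})

test_that("log-likelihood trace is non-decreasing on every fit", {
  set.seed(33)
  for (seed in 1:4) {
    X <- cbind(rnorm(120, rep(c(0, 3, 6), 40)), rnorm(120))
    model <- em_fit(X, k = 3L, seed = seed)
    expect_true(all(diff(model$log_likelihood_trace) >= -1e-8))
  }
})

test_that("EM is deterministic given features, k and seed", {
  set.seed(14)
  X <- matrix(rnorm(600), ncol = 2)
  a <- em_fit(X, k = 4L, seed = 77L)
  b <- em_fit(X, k = 4L, seed = 77L)
  expect_identical(a$labels, b$labels)
  expect_identical(a$log_likelihood_trace, b$log_likelihood_trace)
})

test_that("labels partition the data and weights form a simplex", {
  set.seed(6)
  X <- matrix(rnorm(800), ncol = 2)
  model <- em_fit(X, k = 5L, seed = 3L)
  expect_equal(length(model$labels), nrow(X))
  expect_true(all(model$labels %in% 1:5))
  expect_equal(sum(model$weights), 1, tolerance = 1e-9)
  for (s in model$covariances) {
    expect_equal(s, t(s), tolerance = 1e-10)
    expect_true(all(eigen(s, only.values = TRUE)$values > 0))
  }
})

test_that("degenerate (constant) features survive through regularization", {
  X <- cbind(rep(1, 60), rnorm(60))
  model <- em_fit(X, k = 3L, seed = 1L)
  expect_s3_class(model, "cluster_model")
  expect_true(all(is.finite(model$log_likelihood_trace)))
})

test_that("selection excludes the jointly-darkest low-perfusion cluster", {
  labels <- rep(1:3, times = c(30, 40, 50))
  model <- structure(list(k = 3L, labels = labels), class = "cluster_model")
  ncbv <- c(rnorm(30, 0.2, 0.01), rnorm(40, 4, 0.01), rnorm(50, 4.5, 0.01))
  struct <- c(rnorm(30, 60, 1), rnorm(40, 220, 1), rnorm(50, 210, 1))
  sel <- select_clusters(model, ncbv, struct)
  expect_false(1L %in% sel)
  expect_true(all(c(2L, 3L) %in% sel))
  expect_equal(attr(sel, "excluded_necrosis"), 1L)
})

test_that("extreme high-nCBV cluster is excluded as a vessel surrogate", {
  labels <- rep(1:3, times = c(100, 100, 12))
  model <- structure(list(k = 3L, labels = labels), class = "cluster_model")
  ncbv <- c(rnorm(100, 1, 0.01), rnorm(100, 4, 0.01), rnorm(12, 12, 0.01))
  struct <- c(rnorm(100, 100, 1), rnorm(100, 220, 1), rnorm(12, 200, 1))
  sel <- select_clusters(model, ncbv, struct)
  expect_false(3L %in% sel)
  expect_true(3L %in% attr(sel, "excluded_vessel"))
})

test_that("identical cluster means trigger the median-retention fallback", {
  labels <- rep(1:2, each = 30)
  model <- structure(list(k = 2L, labels = labels), class = "cluster_model")
  ncbv <- rep(2, 60); struct <- rep(100, 60)
  sel <- select_clusters(model, ncbv, struct)
  expect_length(sel, 1)
  expect_true(attr(sel, "qc_fallback"))
})

test_that("phantom necrosis is excluded from the semiautomatic selection", {
  st <- generate_phantom(
    phantom_spec(grid_shape = c(40L, 40L, 10L), n_timepoints = 40L,
                 snr = 50, tumor_radius_mm = 13,
                 necrosis_radius_frac = 0.5, rng_seed = 12L))
  conc <- signal_to_concentration(st$dynamic)
  cbv <- compute_cbv_map(conc, "leakage_corrected", st$truth_labels)
  del <- simulate_observer_rois(st, observer_spec(rng_seed = 4L), "ce_t1wi")
  vm <- voi_mask(del$voi, dim(cbv$values), st$spec$voxel_size_mm)
  brain <- st$truth_labels$labels != TISSUE_LABELS[["background"]]
  ncbv <- normalize_auto(cbv, vm, brain)
  f <- build_feature_vectors(st$ce_t1wi, ncbv, vm)
  idx <- attr(f, "voxel_index")
  model <- em_fit(f, k = 7L, seed = 2L)
  sel <- select_clusters(model, ncbv$values[idx], st$ce_t1wi[idx])
  selected_vox <- idx[model$labels %in% sel]
  necro_idx <- which(st$truth_labels$labels == TISSUE_LABELS[["necrosis_cyst"]])
  necro_in_voi <- intersect(necro_idx, idx)
  frac_excluded <- 1 - length(intersect(necro_in_voi, selected_vox)) /
    length(necro_in_voi)
  expect_gte(frac_excluded, 0.9)
  # partition property: selected + unselected = VOI
  expect_equal(length(model$labels), sum(vm))
  expect_equal(sum(model$labels %in% sel) + sum(!(model$labels %in% sel)),
               sum(vm))
})

test_that("semiautomatic exclusion raises the mean when necrosis sits inside the manual outline", {
  # observer wrongly includes all excluded tissue; same (manual)
  # normalization for both methods isolates the segmentation effect
  st <- generate_phantom(quiet_spec(necrosis_radius_frac = 0.5))
  conc <- signal_to_concentration(st$dynamic)
  cbv <- compute_cbv_map(conc, "leakage_corrected", st$truth_labels)
  del <- simulate_observer_rois(
    st, observer_spec(boundary_jitter_mm = 0, inclusion_error_rate = 1,
                      nawm_roi_placement_jitter_mm = 0), "ce_t1wi")
  ncbv <- normalize_manual(cbv, del$nawm_roi, st$truth_labels)
  man <- manual_mass_statistics(ncbv, del$manual_mask)
  vm <- voi_mask(del$voi, dim(cbv$values), st$spec$voxel_size_mm)
  f <- build_feature_vectors(st$ce_t1wi, ncbv, vm)
  idx <- attr(f, "voxel_index")
  model <- em_fit(f, k = 7L, seed = 6L)
  sel <- select_clusters(model, ncbv$values[idx], st$ce_t1wi[idx])
  semi <- semiauto_mass_statistics(model, sel, ncbv$values[idx],
                                   st$spec$voxel_size_mm)
  expect_gte(semi$mean_ncbv, man$mean_ncbv)
})
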