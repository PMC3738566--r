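# ROI rasterization, VOI masks, manual and semiautomatic statistics.

test_that("axis-aligned rectangle rasterizes to its enclosed voxel centers", {
  gs <- c(10L, 10L, 2L)
  vs <- c(1, 1, 1)
  # rectangle spanning 4 x 3 voxel centers on slice 1
  poly <- rbind(c(1.9, 2.9), c(6.1, 2.9), c(6.1, 6.1), c(1.9, 6.1))
  roi <- structure(list(slices = list(list(z_index = 1L, vertices = poly)),
                        structural_tag = "CE_T1WI"), class = "planar_roi_set")
  mask <- rasterize_roi(roi, gs, vs)
  expect_equal(sum(mask), 12)
  expect_true(all(which(mask, arr.ind = TRUE)[, 3] == 1))
})

test_that("triangle rasterization matches a brute-force even-odd oracle", {
  gs <- c(12L, 12L, 1L)
  vs <- c(1, 1, 1)
  tri <- rbind(c(1.2, 1.3), c(10.7, 2.1), c(5.5, 10.9))
  roi <- structure(list(slices = list(list(z_index = 1L, vertices = tri)),
                        structural_tag = "T2WI"), class = "planar_roi_set")
  mask <- rasterize_roi(roi, gs, vs)
  # oracle: per-voxel ray casting written independently
  oracle <- array(FALSE, dim = gs)
  for (i in 1:gs[1]) for (j in 1:gs[2]) {
    px <- i - 0.5; py <- j - 0.5
    crossings <- 0
    for (e in 1:3) {
      p1 <- tri[e, ]; p2 <- tri[if (e == 3) 1 else e + 1, ]
      if ((p1[2] > py) != (p2[2] > py)) {
        x_int <- p1[1] + (py - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
        if (px < x_int) crossings <- crossings + 1
      }
    }
    oracle[i, j, 1] <- crossings %% 2 == 1
  }
  expect_identical(mask, oracle)
})

test_that("polygon threading between voxel centers gives an empty-mask error", {
  gs <- c(10L, 10L, 1L)
  poly <- rbind(c(3.1, 3.1), c(3.4, 3.1), c(3.4, 3.4), c(3.1, 3.4))
  roi <- structure(list(slices = list(list(z_index = 1L, vertices = poly)),
                        structural_tag = "CE_T1WI"), class = "planar_roi_set")
  expect_error(rasterize_roi(roi, gs, c(1, 1, 1)), "empty",
               class = "dscrepro_validation_error")
})

test_that("manual statistics average per plane, not per voxel", {
  gs <- c(6L, 6L, 3L)
  vals <- array(0, dim = gs)
  mask <- array(FALSE, dim = gs)
  vals[1:4, 1, 1] <- 2; mask[1:4, 1, 1] <- TRUE    # slice 1: 4 voxels, mean 2
  vals[1, 1:2, 2] <- 4; mask[1, 1:2, 2] <- TRUE    # slice 2: 2 voxels, mean 4
  st <- manual_mass_statistics(vals, mask)
  expect_equal(st$mean_ncbv, 3.0)                  # unweighted plane average
  expect_equal(st$n_voxels, 6)

  # constant map: mean c, SD 0 on any ROI
  stc <- manual_mass_statistics(array(5.5, dim = gs), mask)
  expect_equal(stc$mean_ncbv, 5.5)
  expect_equal(stc$sd_ncbv, 0)

  # single-slice ROI equals brute-force moments
  set.seed(8)
  vals2 <- array(rnorm(prod(gs), 3), dim = gs)
  m1 <- array(FALSE, dim = gs); m1[2:5, 2:4, 2] <- TRUE
  st1 <- manual_mass_statistics(vals2, m1)
  expect_equal(st1$mean_ncbv, mean(vals2[m1]))
  expect_equal(st1$sd_ncbv, sd(vals2[m1]))
})

test_that("a slice with one voxel contributes SD 0 and a QC flag", {
  gs <- c(4L, 4L, 2L)
  vals <- array(rnorm(prod(gs)), dim = gs)
  mask <- array(FALSE, dim = gs)
  mask[1:3, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE
  st <- manual_mass_statistics(vals, mask)
  expect_equal(st$n_small_slices, 1L)
  expect_equal(st$sd_ncbv, mean(c(sd(vals[1:3, 1, 1]), 0)))
})

test_that("sphere VOI of radius 1.5 voxels contains exactly 19 voxel centers", {
  voi <- ellipsoid_voi(c(5.5, 5.5, 5.5), c(1.5, 1.5, 1.5))
  mask <- voi_mask(voi, c(11L, 11L, 11L), c(1, 1, 1))
  expect_equal(sum(mask), 19)   # brute-force enumeration of the inequality
  # near-infinite semi-axes cover the whole grid
  all_m <- voi_mask(ellipsoid_voi(c(5, 5, 5), c(1e6, 1e6, 1e6)),
                    c(11L, 11L, 11L), c(1, 1, 1))
  expect_true(all(all_m))
  expect_error(voi_mask(ellipsoid_voi(c(-50, -50, -50), c(1, 1, 1)),
                        c(11L, 11L, 11L), c(1, 1, 1)),
               "intersect", class = "dscrepro_validation_error")
  expect_error(ellipsoid_voi(c(0, 0, 0), c(1, 0, 1)),
               "semi", class = "dscrepro_validation_error")
})

test_that("feature vectors are z-scored in lexicographic voxel order", {
  gs <- c(4L, 4L, 2L)
  set.seed(2)
  struct <- array(rnorm(prod(gs), 100, 10), dim = gs)
  ncbv <- array(rnorm(prod(gs), 3, 1), dim = gs)
  mask <- array(FALSE, dim = gs)
  mask[c(2, 7, 12, 20, 29)] <- TRUE
  f <- build_feature_vectors(struct, ncbv, mask)
  expect_equal(dim(f), c(5L, 2L))
  expect_equal(attr(f, "voxel_index"), which(mask))   # column-major order
  expect_equal(colMeans(f), c(structural = 0, ncbv = 0), tolerance = 1e-12)
  expect_equal(apply(f, 2, sd), c(structural = 1, ncbv = 1), tolerance = 1e-12)
  # constant structural image: flagged, passed through unscaled
  fc <- build_feature_vectors(array(7, dim = gs), ncbv, mask)
  expect_equal(attr(fc, "qc_constant_features"), "structural")
  expect_true(all(fc[, 1] == 7))
  expect_equal(sd(fc[, 2]), 1, tolerance = 1e-12)
})

test_that("semiautomatic statistics pool selected-cluster voxels", {
  model <- structure(list(k = 3L, labels = c(1L, 1L, 2L, 3L)),
                     class = "cluster_model")
  vals <- c(2, 4, 10, 20)
  st <- semiauto_mass_statistics(model, 1L, vals, c(1.875, 1.875, 5))
  expect_equal(st$mean_ncbv, 3)
  expect_equal(st$sd_ncbv, sqrt(2))
  expect_equal(st$n_voxels, 2)
  # selecting every cluster equals brute force over all voxels
  st_all <- semiauto_mass_statistics(model, 1:3, vals, c(1.875, 1.875, 5))
  expect_equal(st_all$mean_ncbv, mean(vals))
  expect_equal(st_all$sd_ncbv, sd(vals))
  expect_error(semiauto_mass_statistics(model, integer(0), vals, c(1, 1, 1)),
               "selection", class = "dscrepro_validation_error")
})

test_that("cluster volume follows the voxel size", {
  model <- structure(list(k = 3L, labels = rep(1L, 100)),
                     class = "cluster_model")
  st <- semiauto_mass_statistics(model, 1L, rnorm(100, 5),
                                 c(1.875, 1.875, 5))
  expect_equal(st$volume_ml, 1.7578, tolerance = 1e-4)
})
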