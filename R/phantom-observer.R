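# Simulated observers: per-slice manual outlines with smooth radial jitter,
# contralateral NAWM reference ROI, and the bounding elliptical VOI.

# Trace the boundary loops of a 2D logical mask as polygons along voxel
# edges (mm coordinates). Rasterizing a traced loop with the even-odd rule
# recovers the enclosed voxel set exactly, which anchors the zero-jitter
# identity between the simulated outline and the true mask.
trace_mask_loops <- function(mask2d, vs_xy) {
  nx <- nrow(mask2d); ny <- ncol(mask2d)
  idx <- which(mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  key <- function(p) paste0(p[1], "_", p[2])   # corner lattice coordinates (2x)
  # segments between corner points; corners indexed on a doubled lattice so
  # they stay exact integers
  segs <- list(); n_seg <- 0
  inm <- function(i, j) i >= 1 && i <= nx && j >= 1 && j <= ny && mask2d[i, j]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    # corners of voxel (i,j) on doubled lattice: (2i-2,2j-2) .. (2i,2j)
    if (!inm(i - 1, j)) { n_seg <- n_seg + 1
      segs[[n_seg]] <- rbind(c(2 * i - 2, 2 * j - 2), c(2 * i - 2, 2 * j)) }
    if (!inm(i + 1, j)) { n_seg <- n_seg + 1
      segs[[n_seg]] <- rbind(c(2 * i, 2 * j - 2), c(2 * i, 2 * j)) }
    if (!inm(i, j - 1)) { n_seg <- n_seg + 1
      segs[[n_seg]] <- rbind(c(2 * i - 2, 2 * j - 2), c(2 * i, 2 * j - 2)) }
    if (!inm(i, j + 1)) { n_seg <- n_seg + 1
      segs[[n_seg]] <- rbind(c(2 * i - 2, 2 * j), c(2 * i, 2 * j)) }
  }
  # chain segments into closed loops
  ends <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_len(n_seg)) {
    for (e in 1:2) {
      k <- key(segs[[s]][e, ])
      ends[[k]] <- c(if (!is.null(ends[[k]])) ends[[k]], s)
    }
  }
  used <- logical(n_seg)
  loops <- list()
  for (s0 in seq_len(n_seg)) {
    if (used[s0]) next
    loop <- list(segs[[s0]][1, ], segs[[s0]][2, ])
    used[s0] <- TRUE
    repeat {
      cur <- loop[[length(loop)]]
      cand <- ends[[key(cur)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      s <- min(cand)                      # deterministic choice at junctions
      used[s] <- TRUE
      p1 <- segs[[s]][1, ]; p2 <- segs[[s]][2, ]
      nxt <- if (all(p1 == cur)) p2 else p1
      if (all(nxt == loop[[1]])) break
      loop[[length(loop) + 1]] <- nxt
    }
    loops[[length(loops) + 1]] <- do.call(rbind, loop)
  }
  # doubled-lattice corners -> mm (corner c corresponds to c/2 voxel widths)
  lapply(loops, function(L) cbind(L[, 1] / 2 * vs_xy[1], L[, 2] / 2 * vs_xy[2]))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  0.5 * abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y))
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Smooth angular displacement field: constant + 3 Fourier harmonics with
# total pointwise SD equal to `sd_mm`.
smooth_radial_noise <- function(sd_mm) {
  if (sd_mm <= 0) {
    return(function(theta) numeric(length(theta)))
  }
  s <- sd_mm / 2
  c0 <- stats::rnorm(1, 0, s)
  ch <- stats::rnorm(3, 0, s)
  sh <- stats::rnorm(3, 0, s)
  function(theta) {
    out <- rep(c0, length(theta))
    for (h in 1:3) out <- out + ch[h] * cos(h * theta) + sh[h] * sin(h * theta)
    out
  }
}

# Displace polygon vertices radially about the polygon centroid.
displace_polygon <- function(poly, noise_fun, bias_mm) {
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  dx <- poly[, 1] - cx; dy <- poly[, 2] - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  r2 <- pmax(r + noise_fun(theta) + bias_mm, 0.1)
  cbind(cx + r2 * cos(theta), cy + r2 * sin(theta))
}

#' Simulate one observer's delineation of a phantom mass
#'
#' Emulates a reader outlining the mass margin on each axial slice of a
#' structural image, placing a contralateral normal-appearing white-matter
#' reference ROI, and adjusting a bounding elliptical VOI. The outline is
#' the true mass boundary perturbed by a smooth radial jitter field (SD
#' `boundary_jitter_mm`, inflated by `t2_jitter_factor` on T2WI where edema
#' blurs the margin) plus the observer's systematic bias; tissue the manual
#' protocol excludes (necrosis/cyst, macrovessels, edema) is removed from
#' the outline, each voxel wrongly retained with `inclusion_error_rate`.
#' The NAWM ROI is a 4 x 4-voxel square (> 40 mm^2 at the default voxel
#' size) placed at the mirrored tumor position with Gaussian placement
#' jitter, then snapped to the nearest all-NAWM position; by construction it
#' never contains gray matter. The VOI is the smallest axis-aligned
#' ellipsoid covering the jittered mass.
#'
#' @param study a `phantom_study`.
#' @param obs an [observer_spec()].
#' @param structural `"ce_t1wi"` or `"t2wi"`.
#' @return object of class `observer_delineation`: `roi` (a
#'   `planar_roi_set` of jittered polygons in mm), `manual_mask`,
#'   `outline_mask`, `nawm_roi` (3D logical masks), and `voi` (an
#'   `ellipsoid_voi`).
#' @export
simulate_observer_rois <- function(study, obs,
                                   structural = c("ce_t1wi", "t2wi")) {
  structural <- match.arg(structural)
  stopifnot(inherits(study, "phantom_study"), inherits(obs, "observer_spec"))
  labels <- study$truth_labels$labels
  vs <- study$truth_labels$voxel_size_mm
  gs <- dim(labels)
  mass <- labels == TISSUE_LABELS[["tumor_solid"]] |
    labels == TISSUE_LABELS[["necrosis_cyst"]] |
    labels == TISSUE_LABELS[["macrovessel"]]
  if (!any(mass)) stop_validation("study", "phantom contains no tumor_solid voxels")

  jit <- obs$boundary_jitter_mm *
    if (structural == "t2wi") obs$t2_jitter_factor else 1

  with_seed(obs$rng_seed, {
    xs <- axis_centers_mm(gs[1], vs[1])
    ys <- axis_centers_mm(gs[2], vs[2])
    outline <- array(FALSE, dim = gs)
    polys <- list()
    for (z in seq_len(gs[3])) {
      sl <- mass[, , z]
      if (!any(sl)) next
      loops <- trace_mask_loops(sl, vs[1:2])
      outer_loop <- loops[[which.max(vapply(loops, polygon_area, numeric(1)))]]
      poly <- displace_polygon(outer_loop, smooth_radial_noise(jit),
                               obs$boundary_bias_mm)
      polys[[length(polys) + 1]] <- list(z_index = z, vertices = poly)
      pg <- expand.grid(x = xs, y = ys)
      outline[, , z] <- matrix(points_in_polygon(pg$x, pg$y, poly),
                               nrow = gs[1])
    }

    excluded <- labels == TISSUE_LABELS[["necrosis_cyst"]] |
      labels == TISSUE_LABELS[["macrovessel"]] |
      labels == TISSUE_LABELS[["edema"]]
    manual <- outline & !(labels == TISSUE_LABELS[["background"]])
    excl_in <- which(manual & excluded)
    if (length(excl_in)) {
      keep <- stats::runif(length(excl_in)) < obs$inclusion_error_rate
      manual[excl_in[!keep]] <- FALSE
    }

    nawm <- place_nawm_roi(labels, vs, mass, obs$nawm_roi_placement_jitter_mm)
    voi <- bounding_ellipsoid_voi(outline, vs)

    structure(list(
      roi = structure(list(slices = polys, structural_tag = toupper(structural)),
                      class = "planar_roi_set"),
      manual_mask = manual,
      outline_mask = outline,
      nawm_roi = nawm,
      voi = voi,
      structural = structural,
      observer_id = obs$observer_id
    ), class = "observer_delineation")
  })
}

# Place a 4x4-voxel all-NAWM square ROI in the hemisphere contralateral to
# the mass, nearest to the (jittered) mirrored tumor position.
place_nawm_roi <- function(labels, vs, mass, placement_jitter_mm, half = 2L) {
  gs <- dim(labels)
  idx <- which(mass, arr.ind = TRUE)
  ctr <- colMeans(idx)
  mid_x <- (gs[1] + 1) / 2
  target <- c(2 * mid_x - ctr[1], ctr[2]) +
    stats::rnorm(2, 0, placement_jitter_mm) / vs[1:2]
  z_order <- order(abs(seq_len(gs[3]) - ctr[3]))
  contralateral <- if (ctr[1] > mid_x) {
    function(i) i < mid_x
  } else {
    function(i) i > mid_x
  }
  for (z in z_order) {
    nawm_sl <- labels[, , z] == TISSUE_LABELS[["nawm"]]
    cand <- which(nawm_sl, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[contralateral(cand[, 1]), , drop = FALSE]
    cand <- cand[cand[, 1] > half & cand[, 1] <= gs[1] - half &
                   cand[, 2] > half & cand[, 2] <= gs[2] - half, , drop = FALSE]
    if (!nrow(cand)) next
    d2 <- (cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2
    for (r in order(d2)) {
      i <- cand[r, 1]; j <- cand[r, 2]
      block <- nawm_sl[(i - half + 1):(i + half), (j - half + 1):(j + half)]
      if (all(block)) {
        roi <- array(FALSE, dim = gs)
        roi[(i - half + 1):(i + half), (j - half + 1):(j + half), z] <- TRUE
        return(roi)
      }
    }
  }
  stop_validation("nawm_roi",
                  "no contralateral NAWM region of at least 40 mm^2 on any slice")
}

# Smallest axis-aligned ellipsoid (by uniform inflation of the half-extent
# box) covering every voxel center of the mask.
bounding_ellipsoid_voi <- function(mask, vs) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop_validation("mask", "empty mask for VOI construction")
  pts <- cbind((idx[, 1] - 0.5) * vs[1],
               (idx[, 2] - 0.5) * vs[2],
               (idx[, 3] - 0.5) * vs[3])
  ctr <- (apply(pts, 2, min) + apply(pts, 2, max)) / 2
  a0 <- pmax((apply(pts, 2, max) - apply(pts, 2, min)) / 2 + vs / 2, vs / 2)
  s <- sqrt(max(colSums((t(pts) - ctr)^2 / a0^2)))
  ellipsoid_voi(ctr, a0 * max(s, 1e-6) + 1e-9)
}

#' Dice overlap of two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
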