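# Rigid coregistration by mutual-information maximization: joint-histogram
# MI, trilinear/nearest resampling, and a deterministic two-stage search.

#' Mutual information between two images
#'
#' `MI = H(A) + H(B) - H(A, B)` in bits, from an equal-width joint
#' histogram over voxels finite in both images. A constant image carries no
#' information: MI is 0 with attribute `degenerate = TRUE`.
#'
#' @param image_a,image_b numeric arrays of identical shape (NA = invalid).
#' @param n_bins histogram bins per axis (>= 8).
#' @return scalar MI in bits.
#' @export
mutual_information <- function(image_a, image_b, n_bins = 32L) {
  if (n_bins < 8) stop_validation("n_bins", "need at least 8 histogram bins")
  stopifnot(all(dim(image_a) == dim(image_b)))
  a <- as.vector(image_a); b <- as.vector(image_b)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop_validation("image_a", "no voxels valid in both images")
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    return(structure(0, degenerate = TRUE))
  }
  ia <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * n_bins) + 1L, n_bins)
  ib <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * n_bins) + 1L, n_bins)
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins) / length(a)
  pj <- joint[joint > 0]
  jm <- matrix(joint, n_bins, n_bins)
  pa <- rowSums(jm); pa <- pa[pa > 0]
  pb <- colSums(jm); pb <- pb[pb > 0]
  h <- function(p) -sum(p * log2(p))
  max(h(pa) + h(pb) - h(pj), 0)
}

#' Construct a rigid transform
#'
#' A pure rotation (intrinsic x-y-z Euler angles, degrees) about the volume
#' center followed by a translation in mm, mapping moving-space points to
#' fixed-space points.
#'
#' @param translation_mm 3-vector, mm.
#' @param rotation_deg 3 Euler angles, degrees.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0)) {
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 convention = "xyz-intrinsic"),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Resample a volume under a rigid transform
#'
#' Resamples the moving volume onto the fixed grid: each fixed voxel center
#' is pulled back through the inverse transform and interpolated in the
#' moving volume (`linear` for intensity maps, `nearest` for masks/labels).
#' Voxels mapping outside the moving field of view become NA.
#'
#' @param volume 3D numeric array.
#' @param transform a [rigid_transform()].
#' @param voxel_size_mm numeric triple.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return resampled 3D array.
#' @export
apply_transform <- function(volume, transform, voxel_size_mm,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  gs <- dim(volume)
  ctr <- gs * voxel_size_mm / 2
  pts <- grid_centers_mm(gs, voxel_size_mm)
  R <- rotation_matrix(transform$rotation_deg)
  # inverse map: fixed point -> moving point
  src <- t(t(R) %*% (t(pts) - ctr - transform$translation_mm) + ctr)
  # continuous voxel index (1-based center convention)
  ix <- src[, 1] / voxel_size_mm[1] + 0.5
  iy <- src[, 2] / voxel_size_mm[2] + 0.5
  iz <- src[, 3] / voxel_size_mm[3] + 0.5
  out <- rep(NA_real_, nrow(pts))
  if (interpolation == "nearest") {
    ri <- round(ix); rj <- round(iy); rk <- round(iz)
    ok <- ri >= 1 & ri <= gs[1] & rj >= 1 & rj <= gs[2] & rk >= 1 & rk <= gs[3]
    out[ok] <- volume[cbind(ri[ok], rj[ok], rk[ok])]
  } else {
    f1 <- floor(ix); f2 <- floor(iy); f3 <- floor(iz)
    ok <- f1 >= 1 & f1 + 1 <= gs[1] & f2 >= 1 & f2 + 1 <= gs[2] &
      f3 >= 1 & f3 + 1 <= gs[3]
    wx <- (ix - f1)[ok]; wy <- (iy - f2)[ok]; wz <- (iz - f3)[ok]
    g1 <- f1[ok]; g2 <- f2[ok]; g3 <- f3[ok]
    acc <- numeric(sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) wx else 1 - wx) *
        (if (dy == 1) wy else 1 - wy) *
        (if (dz == 1) wz else 1 - wz)
      acc <- acc + w * volume[cbind(g1 + dx, g2 + dy, g3 + dz)]
    }
    out[ok] <- acc
  }
  array(out, dim = gs)
}

#' Rigid registration by mutual-information maximization
#'
#' Deterministic two-stage search for the rigid transform aligning `moving`
#' to `fixed`: an integer-voxel translation grid (rotations at zero), then
#' cyclic per-parameter grid descent over rotations and sub-voxel
#' translations, then a Nelder-Mead polish of all six parameters.
#'
#' @param moving,fixed 3D numeric arrays on the same grid.
#' @param voxel_size_mm numeric triple.
#' @param search list of search-range settings: `max_translation_vox`
#'   (default 5), `max_rotation_deg` (10), `rotation_step_deg` (2),
#'   `translation_step_vox` (0.25), `n_bins` (32).
#' @return a [rigid_transform()] with attribute `mi` (achieved mutual
#'   information, bits).
#' @export
register_rigid <- function(moving, fixed, voxel_size_mm,
                           search = list()) {
  s <- utils::modifyList(list(max_translation_vox = 5, max_rotation_deg = 10,
                              rotation_step_deg = 2, translation_step_vox = 0.25,
                              n_bins = 32L), search)
  if (length(unique(as.vector(fixed))) < 2 ||
      length(unique(as.vector(moving))) < 2) {
    stop_validation("fixed", "degenerate (constant) image cannot be registered")
  }
  mi_of <- function(par) {
    tr <- rigid_transform(par[1:3], par[4:6])
    res <- apply_transform(moving, tr, voxel_size_mm, "linear")
    as.numeric(mutual_information(res, fixed, s$n_bins))
  }

  # stage 1: integer translation grid
  steps <- -s$max_translation_vox:s$max_translation_vox
  best <- c(0, 0, 0, 0, 0, 0); best_mi <- mi_of(best)
  for (tx in steps * voxel_size_mm[1]) for (ty in steps * voxel_size_mm[2]) {
    for (tz in (-2:2) * voxel_size_mm[3]) {
      m <- mi_of(c(tx, ty, tz, 0, 0, 0))
      if (m > best_mi) { best_mi <- m; best <- c(tx, ty, tz, 0, 0, 0) }
    }
  }

  # stage 2: cyclic per-parameter refinement
  rot_grid <- seq(-s$max_rotation_deg, s$max_rotation_deg,
                  by = s$rotation_step_deg)
  fine_tr <- seq(-1, 1, by = s$translation_step_vox)
  for (sweep in 1:2) {
    for (p in 4:6) {
      cand <- best[p] + rot_grid
      cand <- cand[abs(cand) <= s$max_rotation_deg + 1e-9]
      for (v in cand) {
        trial <- best; trial[p] <- v
        m <- mi_of(trial)
        if (m > best_mi) { best_mi <- m; best <- trial }
      }
    }
    for (p in 1:3) {
      for (v in best[p] + fine_tr * voxel_size_mm[p]) {
        trial <- best; trial[p] <- v
        m <- mi_of(trial)
        if (m > best_mi) { best_mi <- m; best <- trial }
      }
    }
    rot_grid <- seq(-2, 2, by = 0.5)
  }

  # stage 3: simplex polish
  opt <- stats::optim(best, function(p) -mi_of(p), method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8,
                                     parscale = c(voxel_size_mm, 1, 1, 1)))
  if (-opt$value > best_mi) { best <- opt$par; best_mi <- -opt$value }
  out <- rigid_transform(best[1:3], best[4:6])
  attr(out, "mi") <- best_mi
  out
}
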