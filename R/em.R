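# Full-covariance Gaussian-mixture EM with hard maximum-posterior labels —
# the engine of the semiautomatic segmentation.

# log N(x; mu, Sigma) for all rows of X, via Cholesky.
log_mvnorm <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  centered <- sweep(X, 2, mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)   # solves t(ch) %*% z = t(centered)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# Seeded farthest-point ("k-means++-style") initial centers: the first
# center is drawn uniformly, each next center is the point farthest from
# the chosen set. Deterministic given the seed.
farthest_point_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  d2 <- colSums((t(X) - centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    nxt <- which.max(d2)
    centers[j, ] <- X[nxt, ]
    d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
  }
  centers
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Standard EM for a `k`-component full-covariance Gaussian mixture over
#' per-voxel feature vectors, the clustering model of the semiautomatic
#' segmentation. Initialization is seeded farthest-point center picking
#' followed by a hard nearest-center assignment; covariances are
#' regularized by `epsilon * I` so degenerate features never abort a fit.
#' Iteration stops when the relative log-likelihood change drops below
#' `tol` or after `max_iter` iterations; the per-iteration log-likelihood
#' trace is recorded and is non-decreasing. Voxels receive hard labels by
#' maximum posterior, so the clusters partition the VOI.
#'
#' @param features numeric matrix (rows = voxels) from
#'   [build_feature_vectors()].
#' @param k number of clusters; the segmentation tool offers 3 to 7 and the
#'   study default is 7. Values outside 3..7 are a validation error unless
#'   `allow_any_k = TRUE` (testing override).
#' @param seed integer seed for the initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param allow_any_k override the 3..7 constraint (tests only).
#' @param reg_eps covariance regularization scale (fraction of the mean
#'   feature variance added to the diagonal).
#' @return object of class `cluster_model`: `k`, `weights`, `means`,
#'   `covariances`, `labels`, `log_likelihood_trace`, `converged`, `seed`.
#' @export
em_fit <- function(features, k = 7L, seed = 1L, tol = 1e-6, max_iter = 200L,
                   allow_any_k = FALSE, reg_eps = 1e-6) {
  if (!allow_any_k && !(k %in% 3:7)) {
    stop_validation("k", "cluster count must be between 3 and 7")
  }
  X <- as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (n < 10 * k) {
    stop_validation("features", sprintf(
      "need at least %d rows for k = %d clusters (got %d)", 10 * k, k, n))
  }
  ridge <- reg_eps * mean(apply(X, 2, stats::var)) + 1e-12

  with_seed(seed, {
    centers <- farthest_point_centers(X, k)
    # hard init assignment -> initial parameters
    d2 <- vapply(seq_len(k), function(j) colSums((t(X) - centers[j, ])^2),
                 numeric(n))
    assign0 <- max.col(-d2, ties.method = "first")
    w <- numeric(k); mu <- matrix(0, k, d)
    sig <- vector("list", k)
    glob_cov <- stats::cov(X) + diag(ridge, d)
    for (j in seq_len(k)) {
      rows <- assign0 == j
      w[j] <- max(sum(rows), 1) / n
      mu[j, ] <- if (any(rows)) colMeans(X[rows, , drop = FALSE]) else centers[j, ]
      sig[[j]] <- if (sum(rows) > d) {
        stats::cov(X[rows, , drop = FALSE]) + diag(ridge, d)
      } else glob_cov
    }
    w <- w / sum(w)

    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    resp <- NULL
    for (iter in seq_len(max_iter)) {
      # E step
      logdens <- vapply(seq_len(k),
                        function(j) log(w[j]) + log_mvnorm(X, mu[j, ], sig[[j]]),
                        numeric(n))
      mx <- apply(logdens, 1, max)
      lse <- mx + log(rowSums(exp(logdens - mx)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      resp <- exp(logdens - lse)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      # M step
      nk <- colSums(resp)
      nk <- pmax(nk, 1e-10)
      w <- nk / n
      for (j in seq_len(k)) {
        mu[j, ] <- colSums(X * resp[, j]) / nk[j]
        centered <- sweep(X, 2, mu[j, ])
        sig[[j]] <- crossprod(centered * sqrt(resp[, j])) / nk[j] + diag(ridge, d)
      }
    }
    labels <- max.col(resp, ties.method = "first")
    structure(list(
      k = as.integer(k), weights = w, means = mu, covariances = sig,
      labels = labels, log_likelihood_trace = ll_trace,
      converged = converged, seed = as.integer(seed)
    ), class = "cluster_model")
  })
}

#' Rule-based cluster selection (visual-inspection surrogate)
#'
#' Deterministic stand-in for the reader's visual selection of clusters,
#' which aims to exclude intralesional cystic/necrotic tissue and
#' macrovessels, while keeping the clusters that look like perfused tumor:
#' the cluster that has both the lowest mean structural intensity and the
#' lowest mean nCBV is excluded (necrosis/cyst surrogate); any cluster
#' whose mean nCBV exceeds `vessel_factor` times the next-highest cluster
#' mean is excluded (macrovessel surrogate); and of the remaining clusters
#' only those whose mean nCBV reaches `retain_frac` of the highest
#' remaining cluster mean are kept (the perfused-core surrogate — normal
#' parenchyma and edema swept into the VOI are not tumor and a reader
#' would not select them). At least one cluster is always retained; if the
#' rules would exclude everything, the cluster with the median mean nCBV
#' is kept and a QC flag is set.
#'
#' @param model a `cluster_model`.
#' @param ncbv_values,structural_values per-voxel raw values aligned with
#'   `model$labels`.
#' @param rules list with elements `vessel_factor` (default 2) and
#'   `retain_frac` (default 0.5).
#' @return integer vector of selected cluster ids with attributes
#'   `excluded_necrosis`, `excluded_vessel`, `qc_fallback`.
#' @export
select_clusters <- function(model, ncbv_values, structural_values,
                            rules = list(vessel_factor = 2, retain_frac = 0.5)) {
  k <- model$k
  mean_ncbv <- vapply(seq_len(k), function(j) {
    v <- ncbv_values[model$labels == j]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  mean_struct <- vapply(seq_len(k), function(j) {
    v <- structural_values[model$labels == j]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  present <- which(!is.na(mean_ncbv))

  # indistinguishable clusters: no rule can single anything out; keep the
  # median-mean cluster and flag it
  if (length(present) > 1 &&
      diff(range(mean_ncbv[present])) < 1e-12 &&
      diff(range(mean_struct[present])) < 1e-12) {
    med <- present[order(mean_ncbv[present])][ceiling(length(present) / 2)]
    return(structure(med, excluded_necrosis = integer(0),
                     excluded_vessel = integer(0), qc_fallback = TRUE))
  }

  excl_necro <- integer(0)
  lo_n <- present[which.min(mean_ncbv[present])]
  lo_s <- present[which.min(mean_struct[present])]
  if (length(present) > 1 && lo_n == lo_s) excl_necro <- lo_n

  # vessel threshold: vessel_factor times the next-highest (second-largest)
  # cluster mean; clusters above it are macrovessel surrogates
  vf <- rules$vessel_factor %||% 2
  excl_vessel <- integer(0)
  if (length(present) > 1) {
    ord <- present[order(mean_ncbv[present], decreasing = TRUE)]
    thr <- vf * mean_ncbv[ord[2]]
    if (mean_ncbv[ord[2]] > 0) {
      excl_vessel <- present[mean_ncbv[present] > thr]
    }
  }

  sel <- setdiff(present, union(excl_necro, excl_vessel))
  # perfused-core retention, anchored on substantial clusters: a cluster
  # holding under min_frac of the VOI is a focal structure (vessel), not a
  # tissue class, and cannot define the tumor reference level
  rf <- rules$retain_frac %||% 0.5
  mf <- rules$min_frac %||% 0.05
  if (length(sel) > 1 && rf > 0) {
    frac <- vapply(sel, function(j) mean(model$labels == j), numeric(1))
    anchor <- sel[frac >= mf]
    ref_top <- if (length(anchor)) max(mean_ncbv[anchor]) else max(mean_ncbv[sel])
    if (ref_top > 0) sel <- sel[mean_ncbv[sel] >= rf * ref_top]
  }
  qc_fallback <- FALSE
  if (!length(sel)) {
    med <- present[order(mean_ncbv[present])][ceiling(length(present) / 2)]
    sel <- med
    qc_fallback <- TRUE
  }
  structure(sort(sel),
            excluded_necrosis = excl_necro,
            excluded_vessel = excl_vessel,
            qc_fallback = qc_fallback)
}
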