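# Shared fixtures: small, fast phantom specs and independent oracles.

# compact noiseless phantom: 36x36x8 grid, 40 frames
quiet_spec <- function(..., seed = 7L) {
  phantom_spec(
    grid_shape = c(36L, 36L, 8L),
    n_timepoints = 40L,
    snr = Inf,
    cbv_heterogeneity = 0,
    structural_noise_sd = 0,
    tumor_radius_mm = 11,
    rng_seed = seed,
    ...
  )
}

# small noisy phantom
noisy_spec <- function(snr = 50, seed = 7L, ...) {
  phantom_spec(
    grid_shape = c(36L, 36L, 8L),
    n_timepoints = 40L,
    snr = snr,
    cbv_heterogeneity = 0,
    structural_noise_sd = 0,
    tumor_radius_mm = 11,
    rng_seed = seed,
    ...
  )
}

# compact study config for end-to-end tests
small_config <- function(n_masses = 3L, master_seed = 99L, ...) {
  default_study_config(
    n_masses = n_masses, master_seed = master_seed,
    grid_shape = c(40L, 40L, 10L), ...
  )
}

# adjusted Rand index, computed from the pair-counting contingency table —
# independent of any clustering package
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# single-component check by flood fill (6-connectivity)
is_connected_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  d <- dim(mask)
  seen <- array(FALSE, dim = d)
  queue <- matrix(idx[1, ], ncol = 3)
  seen[idx[1, , drop = FALSE]] <- TRUE
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (k in 1:6) {
      q <- p + nbr[k, ]
      if (all(q >= 1) && all(q <= d) && mask[q[1], q[2], q[3]] &&
          !seen[q[1], q[2], q[3]]) {
        seen[q[1], q[2], q[3]] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  sum(seen) == sum(mask)
}

# gamma-variate test curve on a DSC-like time grid
make_gamma_curve <- function(k = 2, t0 = 10, alpha = 3, beta = 2,
                             n = 60, tr = 1.5) {
  t <- (seq_len(n) - 1) * tr
  list(t = t, y = gamma_variate(t, k, t0, alpha, beta))
}

# independent straight-loop trapezoid integrators (oracles)
trapz_oracle <- function(y, t) {
  s <- 0
  for (i in 2:length(t)) s <- s + (y[i] + y[i - 1]) * (t[i] - t[i - 1]) / 2
  s
}

cumtrapz_oracle <- function(y, t) {
  out <- numeric(length(t))
  for (i in 2:length(t)) {
    out[i] <- out[i - 1] + (y[i] + y[i - 1]) * (t[i] - t[i - 1]) / 2
  }
  out
}
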