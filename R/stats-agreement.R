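# Agreement statistics for repeated nCBV measurements: ICC (two-way random,
# absolute agreement, single measures) with F-based 95% CI and categories,
# coefficient of variation, Bland-Altman limits of agreement, paired t-test,
# and Kolmogorov-Smirnov normality.

#' Categorize an ICC value
#'
#' Thresholds: below 0.40 poor; 0.40-0.59 fair; 0.60-0.74 good; above 0.74
#' excellent.
#'
#' @param value ICC value.
#' @return one of `"poor"`, `"fair"`, `"good"`, `"excellent"` (NA for a
#'   degenerate ICC).
#' @export
icc_category <- function(value) {
  if (!is.finite(value)) return(NA_character_)
  if (value < 0.40) "poor"
  else if (value < 0.60) "fair"
  else if (value <= 0.74) "good"
  else "excellent"
}

#' Intraclass correlation coefficient for paired measurements
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (the
#' standard test-retest form) from the two-way ANOVA mean squares of an
#' n-subject by k-rater table, with the F-distribution 95% confidence
#' interval. The consistency variant is available via `variant`.
#'
#' @param m1,m2 paired measurements (one value per mass).
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @param conf confidence level (default 0.95).
#' @return list: `icc`, `ci95` (length-2), `category`, `ms` (mean squares),
#'   `n`, `degenerate`.
#' @export
icc_pairs <- function(m1, m2, variant = c("agreement", "consistency"),
                      conf = 0.95) {
  variant <- match.arg(variant)
  stopifnot(length(m1) == length(m2))
  if (length(m1) < 3) stop_validation("m1", "need at least 3 pairs for an ICC")
  if (anyNA(m1) || anyNA(m2)) stop_validation("m1", "ICC requires finite values")
  X <- cbind(m1, m2)
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  rowm <- rowMeans(X); colm <- colMeans(X)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((X - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  if (msr <= 0 && mse <= 0 && msc <= 0) {
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                category = NA_character_,
                ms = c(msr = msr, msc = msc, mse = mse), n = n,
                degenerate = TRUE, variant = variant))
  }

  if (variant == "agreement") {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    icc <- if (denom > 0) (msr - mse) / denom else NA_real_
  } else {
    denom <- msr + (k - 1) * mse
    icc <- if (denom > 0) (msr - mse) / denom else NA_real_
  }

  ci <- c(NA_real_, NA_real_)
  alpha <- 1 - conf
  if (is.finite(icc)) {
    if (variant == "agreement") {
      r <- min(icc, 1 - 1e-12)
      a <- (k * r) / (n * (1 - r))
      b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      if (is.finite(v) && v > 0) {
        FL <- stats::qf(1 - alpha / 2, n - 1, v)
        FU <- stats::qf(1 - alpha / 2, v, n - 1)
        lb <- n * (msr - FL * mse) /
          (FL * (k * msc + (k * n - k - n) * mse) + n * msr)
        ub <- n * (FU * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * FU * msr)
        ci <- c(lb, ub)
      } else {
        ci <- c(icc, icc)
      }
    } else {
      Fobs <- msr / mse
      if (is.finite(Fobs) && Fobs > 0) {
        FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
        FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
        ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
      } else {
        ci <- c(icc, icc)
      }
    }
  }
  list(icc = icc, ci95 = ci, category = icc_category(icc),
       ms = c(msr = msr, msc = msc, mse = mse), n = n,
       degenerate = !is.finite(icc), variant = variant)
}

#' Coefficient of variation for paired measurements
#'
#' Per mass, `CV_i = 100 * SD(m1_i, m2_i) / mean(m1_i, m2_i)` with the
#' sample (n-1) SD of the pair; the cohort value aggregates per-mass CVs by
#' root-mean-square (default) or plain mean. Masses with nonpositive pair
#' mean are excluded and counted in `n_excluded`.
#'
#' @param m1,m2 paired measurements.
#' @param agg `"rms"` (default) or `"mean"`.
#' @return list: `cv_percent`, `per_mass`, `n_excluded`.
#' @export
cv_percent <- function(m1, m2, agg = c("rms", "mean")) {
  agg <- match.arg(agg)
  stopifnot(length(m1) == length(m2))
  pair_mean <- (m1 + m2) / 2
  pair_sd <- abs(m1 - m2) / sqrt(2)      # sample SD of a pair
  ok <- pair_mean > 0
  cv_i <- 100 * pair_sd[ok] / pair_mean[ok]
  cv <- if (!length(cv_i)) NA_real_
  else if (agg == "rms") sqrt(mean(cv_i^2)) else mean(cv_i)
  list(cv_percent = cv, per_mass = cv_i, n_excluded = sum(!ok))
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences `d = m1 - m2`; bias = mean(d); 95% limits of agreement =
#' bias +/- 1.96 SD(d).
#'
#' @param m1,m2 paired measurements (>= 3 pairs).
#' @return list: `bias`, `loa_low`, `loa_high`, `sd_diff`, `points`
#'   (data.frame of per-mass mean and difference).
#' @export
bland_altman <- function(m1, m2) {
  stopifnot(length(m1) == length(m2))
  if (length(m1) < 3) stop_validation("m1", "need at least 3 pairs")
  d <- m1 - m2
  bias <- mean(d)
  s <- sample_sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s,
       points = data.frame(mean = (m1 + m2) / 2, diff = d))
}

#' Paired t-test on measurement pairs
#'
#' Two-tailed paired t-test on the differences, with a significance flag at
#' the 0.05 level. Zero-variance differences with zero mean give `t = 0,
#' p = 1`; zero variance with nonzero mean is reported degenerate.
#'
#' @param m1,m2 paired measurements (>= 2 pairs).
#' @return list: `t`, `p`, `significant`, `degenerate`.
#' @export
paired_ttest <- function(m1, m2) {
  stopifnot(length(m1) == length(m2))
  if (length(m1) < 2) stop_validation("m1", "need at least 2 pairs")
  d <- m1 - m2
  if (sample_sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, significant = FALSE, degenerate = FALSE))
    }
    return(list(t = Inf, p = NA_real_, significant = NA, degenerate = TRUE))
  }
  tt <- stats::t.test(m1, m2, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05, degenerate = FALSE)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the values against a normal distribution with
#' the sample mean and SD.
#'
#' @param values numeric vector (n >= 5, non-constant).
#' @return list: `statistic`, `p`.
#' @export
ks_normality <- function(values) {
  if (length(values) < 5) stop_validation("values", "need at least 5 values")
  if (sample_sd(values) == 0) {
    stop_validation("values", "constant sample has no distribution to test")
  }
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Ellipsoid tumor-volume formula
#'
#' `volume = 0.5 * anteroposterior * superoinferior * transverse`; with
#' dimensions in cm the result is in ml.
#'
#' @param ap_cm,si_cm,tr_cm largest tumor dimensions.
#' @return volume (ml when inputs are cm).
#' @export
ellipsoid_volume <- function(ap_cm, si_cm, tr_cm) {
  if (any(c(ap_cm, si_cm, tr_cm) < 0)) {
    stop_validation("dimensions", "tumor dimensions must be nonnegative")
  }
  0.5 * ap_cm * si_cm * tr_cm
}

#' Full agreement summary for one comparison cell
#'
#' Bundles ICC (value, CI, category), CV, Bland-Altman and paired t-test
#' for one set of measurement pairs.
#'
#' @param m1,m2 paired measurements.
#' @param icc_variant passed to [icc_pairs()].
#' @param cv_agg passed to [cv_percent()].
#' @return object of class `agreement_result`.
#' @export
agreement_summary <- function(m1, m2, icc_variant = "agreement",
                              cv_agg = "rms") {
  icc <- icc_pairs(m1, m2, variant = icc_variant)
  cv <- cv_percent(m1, m2, agg = cv_agg)
  ba <- bland_altman(m1, m2)
  tt <- paired_ttest(m1, m2)
  structure(list(
    icc = icc$icc, icc_ci95 = icc$ci95, icc_category = icc$category,
    cv_percent = cv$cv_percent, bias = ba$bias,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    n_pairs = length(m1), paired_t_p = tt$p,
    ba_points = ba$points, degenerate_icc = icc$degenerate
  ), class = "agreement_result")
}
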