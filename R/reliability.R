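#' Per-subject percent bias between test and retest
#'
#' b = 100 * (test - retest) / ((test + retest) / 2): the signed difference
#' as a percentage of the subject's own mean. Subjects whose test + retest
#' is zero are flagged and excluded from the summary.
#'
#' @param test,retest Paired numeric vectors for the same subjects.
#' @return List with `bias` (signed per-subject percent values),
#'   `mean_abs_bias`, and `excluded` (indices with zero mean).
#' @export
compute_bias <- function(test, retest) {
  if (length(test) != length(retest)) stop("test and retest must be paired")
  ok <- !is.na(test) & !is.na(retest)
  denom <- (test + retest) / 2
  zero <- ok & denom == 0
  b <- rep(NA_real_, length(test))
  use <- ok & !zero
  b[use] <- 100 * (test[use] - retest[use]) / denom[use]
  list(bias = b,
       mean_abs_bias = mean(abs(b[use])),
       excluded = which(zero))
}

#' Bland-Altman limits of agreement
#'
#' Mean test-retest difference with limits of agreement at
#' mean +/- 1.96 * SD of the differences.
#'
#' @param test,retest Paired numeric vectors (at least 3 complete pairs).
#' @return Named numeric vector `c(mean_diff, loa_low, loa_high)`.
#' @export
bland_altman <- function(test, retest) {
  ok <- !is.na(test) & !is.na(retest)
  if (sum(ok) < 3) stop("Bland-Altman needs at least 3 complete pairs")
  d <- test[ok] - retest[ok]
  m <- mean(d)
  s <- stats::sd(d)
  c(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' One-way intraclass correlation ICC(1,1)
#'
#' One-way random-effects ANOVA estimator of the population quantity
#' ICC = sigma2_BS / (sigma2_BS + sigma2_WS): subjects are random, sessions
#' are exchangeable repeats. The estimate is (MSB - MSW)/(MSB + (k-1)*MSW),
#' the p-value comes from F = MSB/MSW on (n-1, n(k-1)) df, and the standard
#' error follows the SE = ICC/Z rule with Z the standard-normal quantile
#' matching the (two-sided) p-value; the SE is undefined (NA) when the
#' estimate is not positive or p = 1.
#'
#' @param sessions Numeric matrix, subjects in rows, k >= 2 sessions in
#'   columns, no missing cells.
#' @return List with `icc`, `p`, `se`, `msb`, `msw`, `sigma2_bs`,
#'   `sigma2_ws`, `n`, `k`.
#' @export
compute_icc <- function(sessions) {
  sessions <- as.matrix(sessions)
  sessions <- sessions[stats::complete.cases(sessions), , drop = FALSE]
  n <- nrow(sessions); k <- ncol(sessions)
  if (k < 2) stop("need at least 2 sessions")
  if (n < 3) stop("need at least 3 subjects")
  grand <- mean(sessions)
  if (stats::var(as.vector(sessions)) < .Machine$double.eps)
    stop("degenerate trait: zero total variance")
  row_m <- rowMeans(sessions)
  ssb <- k * sum((row_m - grand)^2)
  ssw <- sum((sessions - row_m)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f <- msb / msw
  p <- stats::pf(f, n - 1, n * (k - 1), lower.tail = FALSE)
  z <- -stats::qnorm(p / 2)  # tail-stable Phi^-1(1 - p/2)
  se <- if (icc > 0 && is.finite(z) && z > 0) icc / z else NA_real_
  list(icc = icc, p = p, se = se, msb = msb, msw = msw,
       sigma2_bs = max((msb - msw) / k, 0), sigma2_ws = msw, n = n, k = k)
}

#' Classify an ICC estimate into reliability bands
#'
#' Below 0.4: "poor"; from 0.4 up to (but excluding) 0.75: "fair_to_good";
#' 0.75 and above: "excellent".
#'
#' @param icc Finite ICC value.
#' @return One of `"poor"`, `"fair_to_good"`, `"excellent"`.
#' @export
classify_icc <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc < 0.4) "poor" else if (icc < 0.75) "fair_to_good" else "excellent"
}

#' Inverse-variance meta-analysis of ICC across cohorts
#'
#' Combines per-cohort ICC estimates with weights se^-2 where
#' se = ICC / Z(p). Entries with non-positive ICC or p = 1 carry no usable
#' weight and are excluded with a warning. The combined value is reported
#' only when the trait was estimable in at least 3/4 of the available
#' cohorts (ceiling(0.75 * n_cohorts)); otherwise the result is NA.
#'
#' @param per_cohort Data frame (or list of lists) with columns/fields
#'   `icc` and `p`, one row per cohort where the trait was measured.
#' @param n_cohorts_available Total number of cohorts in the study (defaults
#'   to the number of entries supplied).
#' @return List with `icc` (NA when the 3/4 rule fails), `se`,
#'   `n_cohorts_used`, `n_cohorts_available`.
#' @export
meta_icc <- function(per_cohort, n_cohorts_available = NULL) {
  if (is.data.frame(per_cohort)) {
    icc <- per_cohort$icc; p <- per_cohort$p
  } else {
    icc <- vapply(per_cohort, function(e) e$icc, 0)
    p <- vapply(per_cohort, function(e) e$p, 0)
  }
  n_avail <- n_cohorts_available %||% length(icc)
  z <- -stats::qnorm(p / 2)  # tail-stable Phi^-1(1 - p/2)
  valid <- is.finite(icc) & icc > 0 & is.finite(z) & z > 0 & p < 1
  if (any(!valid))
    warning(sum(!valid), " cohort ICC entries excluded (icc <= 0 or p = 1)")
  need <- ceiling(0.75 * n_avail)
  if (sum(valid) < need)
    return(list(icc = NA_real_, se = NA_real_, n_cohorts_used = sum(valid),
                n_cohorts_available = n_avail))
  se <- icc[valid] / z[valid]
  w <- se^-2
  list(icc = sum(w * icc[valid]) / sum(w),
       se = sum(w)^-0.5,
       n_cohorts_used = sum(valid),
       n_cohorts_available = n_avail)
}

#' Reliability summary for one trait in one cohort
#'
#' Convenience wrapper combining [compute_icc], [compute_bias] (sessions 1
#' vs 2) and [bland_altman] into one record.
#'
#' @param sessions Numeric matrix, subjects x sessions.
#' @return List of class `reliability_summary`.
#' @export
reliability_summary <- function(sessions) {
  sessions <- as.matrix(sessions)
  icc <- compute_icc(sessions)
  bias <- compute_bias(sessions[, 1], sessions[, 2])
  ba <- bland_altman(sessions[, 1], sessions[, 2])
  structure(list(
    n_subjects = icc$n, icc = icc$icc, p_icc = icc$p, se_icc = icc$se,
    band = classify_icc(icc$icc),
    sigma2_bs = icc$sigma2_bs, sigma2_ws = icc$sigma2_ws,
    bias_values = bias$bias, mean_abs_bias = bias$mean_abs_bias,
    ba_mean_diff = unname(ba["mean_diff"]),
    ba_loa_low = unname(ba["loa_low"]),
    ba_loa_high = unname(ba["loa_high"])
  ), class = "reliability_summary")
}
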