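# Power and sample-size analysis for two-sample t-tests (noncentral t) and
# Pearson correlations (Fisher z approximation, bias-corrected mean).

#' Power of a two-sample t-test (noncentral t)
#'
#' `df = n1 + n2 - 2`, noncentrality `d * sqrt(n1 n2 / (n1 + n2))`; power is
#' the probability that |T'| exceeds the two-tailed critical value (or T'
#' exceeds the one-tailed one).
#'
#' @param d standardized effect size (Cohen's d, >= 0)
#' @param n1,n2 group sizes (>= 2)
#' @param alpha type-I error rate (default 0.05)
#' @param tails 2 (default) or 1
#' @return power in (0, 1)
#' @export
ttest_power <- function(d, n1, n2, alpha = 0.05, tails = 2) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1,
            tails %in% c(1, 2))
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Smallest total sample size reaching a target t-test power
#'
#' Scans total N upward (given the allocation ratio) until
#' [ttest_power()] reaches the target.
#'
#' @param d effect size (> 0)
#' @param power target power (default 0.8)
#' @param alpha type-I error rate
#' @param tails 1 or 2
#' @param ratio allocation ratio n1:n2 (default 1; e.g. 4/7 for a 4:7 split)
#' @param n_max search cap
#' @return list: `n_total`, `n1`, `n2`, `power` achieved
#' @export
ttest_sample_size <- function(d, power = 0.8, alpha = 0.05, tails = 2,
                              ratio = 1, n_max = 10000) {
  stopifnot(d > 0, power > 0, power < 1)
  w <- ratio / (1 + ratio)
  for (N in 4:n_max) {
    n1 <- max(2, round(N * w)); n2 <- N - n1
    if (n2 < 2) next
    pw <- ttest_power(d, n1, n2, alpha, tails)
    if (pw >= power)
      return(list(n_total = N, n1 = n1, n2 = n2, power = pw))
  }
  stop("ttest_sample_size: target power not reached by N = ", n_max)
}

#' Power of a Pearson correlation test (Fisher z)
#'
#' Fisher z approximation with the standard mean bias correction
#' `z_r = atanh(r) + r / (2 (n - 1))`:
#' `power = Phi(z_r sqrt(n-3) - z_{1-alpha/2}) + Phi(-z_r sqrt(n-3) -
#' z_{1-alpha/2})` (two-tailed).
#'
#' @param r true correlation, |r| in (0, 1)
#' @param n sample size (>= 4)
#' @param alpha type-I error rate
#' @param tails 1 or 2
#' @return power in (0, 1)
#' @export
pearson_power <- function(r, n, alpha = 0.05, tails = 2) {
  stopifnot(abs(r) > 0, abs(r) < 1, n >= 4, alpha > 0, alpha < 1,
            tails %in% c(1, 2))
  zr <- atanh(r) + r / (2 * (n - 1))
  za <- if (tails == 2) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  pw <- stats::pnorm(abs(zr) * sqrt(n - 3) - za)
  if (tails == 2) pw <- pw + stats::pnorm(-abs(zr) * sqrt(n - 3) - za)
  pw
}

#' Smallest sample size reaching a target Pearson-correlation power
#'
#' Inverts the Fisher-z formula for a starting value, then steps to the
#' smallest n whose [pearson_power()] reaches the target.
#'
#' @param r true correlation, |r| in (0, 1)
#' @param power target power (default 0.8)
#' @param alpha type-I error rate
#' @param tails 1 or 2
#' @return sample size n (integer >= 4)
#' @export
pearson_sample_size <- function(r, power = 0.8, alpha = 0.05, tails = 2) {
  stopifnot(abs(r) > 0, abs(r) < 1, power > 0, power < 1)
  za <- if (tails == 2) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  n <- max(4, floor(((za + zb) / atanh(abs(r)))^2 + 3) - 2)
  while (pearson_power(r, n, alpha, tails) < power) n <- n + 1
  while (n > 4 && pearson_power(r, n - 1, alpha, tails) >= power) n <- n - 1
  as.integer(n)
}

#' Power curve table for two-sample t-tests
#'
#' Total sample size against effect size for several target power levels
#' (the small-cohort design space of an NHP study).
#'
#' @param d_grid effect sizes
#' @param power_levels target powers
#' @param alpha type-I error rate
#' @param ratio allocation ratio n1:n2
#' @return data.frame: `d`, `power_target`, `n_total`, `power_achieved`
#' @export
ttest_power_curve <- function(d_grid = seq(0.5, 8, by = 0.25),
                              power_levels = c(0.8, 0.9, 0.95),
                              alpha = 0.05, ratio = 1) {
  rows <- list()
  for (pw in power_levels) for (d in d_grid) {
    ss <- ttest_sample_size(d, pw, alpha, ratio = ratio)
    rows[[length(rows) + 1]] <- data.frame(
      d = d, power_target = pw, n_total = ss$n_total,
      power_achieved = ss$power)
  }
  do.call(rbind, rows)
}

#' Power curve table for Pearson correlations
#'
#' @param r_grid correlation magnitudes
#' @param power_levels target powers
#' @param alpha type-I error rate
#' @return data.frame: `r`, `power_target`, `n`
#' @export
pearson_power_curve <- function(r_grid = seq(0.2, 0.9, by = 0.05),
                                power_levels = c(0.8, 0.9, 0.95),
                                alpha = 0.05) {
  rows <- list()
  for (pw in power_levels) for (r in r_grid) {
    rows[[length(rows) + 1]] <- data.frame(
      r = r, power_target = pw, n = pearson_sample_size(r, pw, alpha))
  }
  do.call(rbind, rows)
}
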