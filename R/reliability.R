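# Reproducibility statistics for paired repeat PSD readings: ICC(2,1)
# (two-way random effects, absolute agreement, single measurement) and
# Bland-Altman limits of agreement.

#' ICC(2,1) from paired readings
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation from the two-way ANOVA mean squares
#' (McGraw & Wong A,1 form):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the F test `MSR/MSE` on (n-1, (n-1)(k-1)) df and the standard
#' Satterthwaite-based confidence interval.
#'
#' @param pairs data.frame with `reading_1`, `reading_2` (and optionally
#'   `patient_id`, `cluster`).
#' @param ci_level Confidence level (default 0.95).
#' @return List: `icc`, `ci_lower`, `ci_upper`, `f_stat`, `p_value`, `n`,
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way <- function(pairs, ci_level = 0.95) {
  Y <- as.matrix(pairs[, c("reading_1", "reading_2")])
  n <- nrow(Y); k <- ncol(Y)
  if (n < 5) stopf("ICC needs >= 5 pairs, got %d", n)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps && msr <= .Machine$double.eps)
    stopf("zero between-subject variance; ICC undefined")
  icc <- (msr - mse) / denom
  f_stat <- msr / mse
  p <- pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 1 - ci_level
  if (mse <= .Machine$double.eps) {
    lo <- up <- icc  # degenerate: perfect agreement
  } else {
    r <- icc
    a <- k * r / (n * (1 - r)); b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    up <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  list(icc = icc, ci_lower = lo, ci_upper = up, f_stat = f_stat,
       p_value = p, n = n, msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement
#'
#' Bias = mean of `reading_1 - reading_2`; limits of agreement =
#' bias +/- 1.96 sd of the differences (n-1 sd). Per-pair (mean,
#' difference) coordinates are returned for plotting.
#'
#' @param pairs data.frame with `reading_1`, `reading_2`.
#' @return List: `bias`, `loa_lower`, `loa_upper`, `sd_diff`, `n`,
#'   `coordinates` (data.frame mean/difference).
#' @export
bland_altman <- function(pairs) {
  d <- pairs$reading_1 - pairs$reading_2
  if (length(d) < 2) stopf("Bland-Altman needs >= 2 pairs")
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s, n = length(d),
       coordinates = data.frame(mean = (pairs$reading_1 + pairs$reading_2) / 2,
                                difference = d))
}

#' Per-cluster reliability report
#'
#' Runs [icc_two_way()] and [bland_altman()] within each cluster of a
#' paired-readings table.
#'
#' @param pairs data.frame with `cluster`, `reading_1`, `reading_2`.
#' @return Named list of per-cluster reports (icc fields + Bland-Altman
#'   fields).
#' @export
reliability_by_cluster <- function(pairs) {
  out <- lapply(split(pairs, pairs$cluster), function(p) {
    c(icc_two_way(p), bland_altman(p)[c("bias", "loa_lower", "loa_upper", "sd_diff")])
  })
  out
}
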