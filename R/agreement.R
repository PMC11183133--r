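# Method-comparison statistics: Bland-Altman limits of agreement, error
# metrics, ICC(2,1) with F-based confidence bounds, Pearson correlation,
# test-retest reliability.

#' Bland-Altman analysis of paired measurements
#'
#' Bias is the mean of the differences (test minus reference); the 95%
#' limits of agreement are `bias +/- 1.96 * SD` of the differences. The bias
#' CI uses the t distribution; the LoA CIs use the standard Bland-Altman
#' variance `(1/n + 1.96^2 / (2*(n-1))) * SD^2`.
#'
#' @param test,ref paired numeric vectors (test and reference device).
#' @param conf confidence level for the CIs.
#' @return object of class `bland_altman`: list with `bias`, `loa_lower`,
#'   `loa_upper`, `sd_diff`, `bias_ci`, `loa_lower_ci`, `loa_upper_ci`, `n`.
#' @export
bland_altman <- function(test, ref, conf = 0.95) {
  ok <- complete.cases(test, ref)
  test <- test[ok]; ref <- ref[ok]
  n <- length(test)
  if (n < 3) stop("Bland-Altman requires at least 3 pairs")
  d <- test - ref
  bias <- mean(d)
  s <- sd(d)
  loa <- c(bias - 1.96 * s, bias + 1.96 * s)
  tcrit <- qt(1 - (1 - conf) / 2, n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  structure(list(
    bias = bias, loa_lower = loa[1], loa_upper = loa[2], sd_diff = s,
    bias_ci = bias + c(-1, 1) * tcrit * se_bias,
    loa_lower_ci = loa[1] + c(-1, 1) * tcrit * se_loa,
    loa_upper_ci = loa[2] + c(-1, 1) * tcrit * se_loa,
    n = n
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d)\n", x$n))
  cat(sprintf("  bias %.3f (%.3f, %.3f)\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LoA (%.3f, %.3f)\n", x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Error metrics between test and reference measurements
#'
#' @param test,ref paired numeric vectors.
#' @return list: `bias` (mean difference), `mad` (mean absolute difference),
#'   `mpe` (mean percent error, `100 * mean((test - ref)/ref)`), `n`,
#'   `n_mpe` (pairs contributing to MPE; pairs with a zero reference are
#'   excluded with a warning).
#' @export
error_metrics <- function(test, ref) {
  ok <- complete.cases(test, ref)
  test <- test[ok]; ref <- ref[ok]
  n <- length(test)
  if (n < 1) stop("error metrics require at least 1 pair")
  d <- test - ref
  nz <- ref != 0
  if (any(!nz)) warning("pairs with zero reference excluded from MPE")
  list(bias = mean(d), mad = mean(abs(d)),
       mpe = if (any(nz)) 100 * mean(d[nz] / ref[nz]) else NA_real_,
       n = n, n_mpe = sum(nz))
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares of the complete subjects x
#' raters matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with 95% bounds from the F-based interval (Satterthwaite df on the
#' denominator). May be negative.
#'
#' @param mat numeric matrix, subjects in rows, raters/devices in columns;
#'   must be complete (drop incomplete rows first).
#' @param conf confidence level.
#' @return list: `icc`, `lb`, `ub`, `ms` (the mean squares), `n`, `k`.
#' @export
icc_2way_random_absolute <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete; drop incomplete rows first")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom <= 0) 0 else (msr - mse) / denom
  alpha <- 1 - conf
  lb <- ub <- NA_real_
  if (mse <= 1e-300 && msc <= msr * 1e-12) {
    # degenerate: identical raters, CI collapses
    lb <- ub <- icc
  } else if (icc < 1) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v_num <- (a * msc + b * mse)^2
    v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    v <- v_num / v_den
    # for strongly negative ICC the Satterthwaite df collapse and qf warns
    # about tail accuracy; the bounds are still well-defined
    f_l <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
    f_u <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
    lb <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ub <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  list(icc = icc, lb = lb, ub = ub,
       ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k)
}

#' Benchmark label for an ICC value
#'
#' `poor` for ICC at or below 0.4, `moderate` in (0.4, 0.6), `good` in
#' [0.6, 0.75), `excellent` at or above 0.75.
#'
#' @param icc ICC value(s), at most 1.
#' @return character vector of labels.
#' @export
classify_agreement <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12))
  vapply(icc, function(v) {
    if (v <= 0.4) "poor"
    else if (v < 0.6) "moderate"
    else if (v < 0.75) "good"
    else "excellent"
  }, character(1))
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y paired numeric vectors, n >= 3, both with nonzero variance.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Pearson correlation requires at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Test-retest reliability across two visits
#'
#' ICC(2,1) on the subjects x visits matrix plus the Pearson correlation
#' between visits.
#'
#' @param visit1,visit2 endpoint values paired by subject.
#' @return list: `icc` (with `lb`, `ub`), `pearson` (`r`, `p`), `n`.
#' @export
test_retest <- function(visit1, visit2) {
  ok <- complete.cases(visit1, visit2)
  m <- cbind(visit1[ok], visit2[ok])
  icc <- icc_2way_random_absolute(m)
  pr <- pearson_cor(m[, 1], m[, 2])
  list(icc = icc, pearson = pr, n = nrow(m))
}

#' Agreement table between a test and a reference device
#'
#' For every task x endpoint combination present in both inputs, computes
#' the full agreement panel: bias with limits of agreement, mean absolute
#' difference, mean percent error, ICC(2,1) with bounds and benchmark label,
#' and Pearson's R with p-value. Subjects missing either side are dropped
#' listwise per combination.
#'
#' @param test,ref tidy data.frames `subject, task, endpoint, value` (e.g.
#'   the `cross_visit` element of [aggregate_endpoints()] for one location
#'   each).
#' @return data.frame of class `agreement_table`, one row per task x
#'   endpoint: `task, endpoint, n, bias, loa_lower, loa_upper, mad, mpe,
#'   icc, icc_lb, icc_ub, icc_label, pearson_r, pearson_p`.
#' @export
agreement_summary <- function(test, ref) {
  need <- c("subject", "task", "endpoint", "value")
  stopifnot(all(need %in% names(test)), all(need %in% names(ref)))
  m <- merge(test[need], ref[need],
             by = c("subject", "task", "endpoint"),
             suffixes = c("_test", "_ref"))
  m <- m[complete.cases(m$value_test, m$value_ref), ]
  combos <- unique(m[c("task", "endpoint")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- m[m$task == combos$task[i] & m$endpoint == combos$endpoint[i], ]
    if (nrow(sub) < 3) return(NULL)
    ba <- bland_altman(sub$value_test, sub$value_ref)
    em <- error_metrics(sub$value_test, sub$value_ref)
    icc <- icc_2way_random_absolute(cbind(sub$value_test, sub$value_ref))
    pr <- tryCatch(pearson_cor(sub$value_test, sub$value_ref),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(task = combos$task[i], endpoint = combos$endpoint[i],
               n = ba$n, bias = ba$bias, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper, mad = em$mad, mpe = em$mpe,
               icc = icc$icc, icc_lb = icc$lb, icc_ub = icc$ub,
               icc_label = classify_agreement(icc$icc),
               pearson_r = pr$r, pearson_p = pr$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' @export
print.agreement_table <- function(x, digits = 3, ...) {
  cat("Agreement table (test vs reference)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
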