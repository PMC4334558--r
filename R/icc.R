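## Inter-rater reliability: single-measure intraclass correlation from a
## two-way model with absolute agreement, ICC(A,1) - subjects random, the
## raters a fixed factor. Confidence interval by the F-based approximation
## of McGraw & Wong.

#' ICC(A,1): two-way, single measures, absolute agreement
#'
#' Decomposes the n x k ratings table by two-way ANOVA (rows = subjects,
#' columns = raters) and returns
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' with a 95% confidence interval from the McGraw & Wong F-based
#' approximation.
#'
#' @param ratings numeric n x k matrix (n subjects, k >= 2 raters), no
#'   missing cells
#' @param alpha confidence level complement (default 0.05 for a 95% CI)
#' @return list of class `icc_result`: `icc`, `ci95` (length 2), `model_tag`,
#'   mean squares `ms` (MSR, MSC, MSE), `n`, `k`
#' @examples
#' icc_a1(cbind(c(1, 2, 3, 4, 5), c(1.1, 2, 2.9, 4.2, 5)))
#' @export
icc_a1 <- function(ratings, alpha = 0.05) {
  ratings <- as.matrix(ratings)
  stopifnot_msg(is.numeric(ratings) && !anyNA(ratings),
                "ratings must be a complete numeric matrix")
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot_msg(k >= 2, "need at least 2 raters")
  stopifnot_msg(n >= 2, "need at least 2 subjects")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * (1 + abs(grand))) {
    abort("ICC undefined: zero between-subject variance")
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  ## McGraw & Wong CI for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(
    icc = icc, ci95 = c(lower, upper),
    model_tag = "ICC(A,1) two-way mixed absolute agreement",
    ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k
  ), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s: ICC = %.3f, 95%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$model_tag, x$icc, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}
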