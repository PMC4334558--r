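## The statistical battery: Welch-Satterthwaite inference from summary
## statistics, the D'Agostino-Pearson omnibus normality test, the
## Brown-Forsythe variance-homogeneity test, two-way ANOVA (Type-II sums of
## squares when unbalanced), Mann-Whitney U (exact by enumeration on small
## samples), the two-sample Kolmogorov-Smirnov test, Pearson/Spearman
## correlation, and noncentral-t power for the two-sample t test.

#' Construct a test result
#'
#' The common container for every test in the battery: a named statistic,
#' (possibly fractional) degrees of freedom, p-value, an optional effect CI,
#' and a note recording which branch of the analysis logic produced it.
#'
#' @param statistic named numeric scalar
#' @param df degrees of freedom (scalar or length 2), possibly fractional
#' @param p_value p-value in `[0, 1]`
#' @param ci95 optional effect confidence interval
#' @param method human-readable test name
#' @param decision_path optional note on the decision branch
#' @param extra optional list of additional fields
#' @return list of class `test_result`
#' @export
test_result <- function(statistic, df = NULL, p_value = NA_real_, ci95 = NULL,
                        method = "", decision_path = NULL, extra = list()) {
  stopifnot_msg(is.na(p_value) || (p_value >= 0 && p_value <= 1),
                "p_value must lie in [0, 1]")
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   ci95 = ci95, method = method, decision_path = decision_path),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else sprintf(", df = %s",
                                            paste(signif(x$df, 6), collapse = ", "))
  ci <- if (is.null(x$ci95)) "" else sprintf(", 95%% CI [%.3f, %.3f]",
                                             x$ci95[1], x$ci95[2])
  cat(sprintf("%s: %s = %.4f%s, p = %.4g%s\n", x$method,
              names(x$statistic)[1], x$statistic[1], dfs, x$p_value, ci))
  if (!is.null(x$decision_path)) cat("  path:", x$decision_path, "\n")
  invisible(x)
}

#' Welch two-sample t test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Satterthwaite fractional
#' degrees of freedom, a two-sided p-value, and the CI of the difference in
#' population means.
#'
#' @param m1,s1,n1 mean, SD, size of group 1
#' @param m2,s2,n2 mean, SD, size of group 2
#' @param alpha CI level complement
#' @return `test_result` with extra fields `mean_diff` and `se`
#' @examples
#' welch_t_summary(4.87, 1.27, 80, 2.78, 0.51, 44)
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  stopifnot_msg(s1 > 0 && s2 > 0, "group SDs must be positive")
  stopifnot_msg(n1 >= 2 && n2 >= 2, "group sizes must be >= 2")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t_stat <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  half <- stats::qt(1 - alpha / 2, df) * se
  test_result(c(t = t_stat), df = df, p_value = p,
              ci95 = c((m1 - m2) - half, (m1 - m2) + half),
              method = "Welch two-sample t (Satterthwaite df)",
              extra = list(mean_diff = m1 - m2, se = se))
}

#' Pooled-variance two-sample t test from summary statistics
#' @inheritParams welch_t_summary
#' @return `test_result`
#' @export
pooled_t_summary <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  stopifnot_msg(s1 > 0 && s2 > 0, "group SDs must be positive")
  stopifnot_msg(n1 >= 2 && n2 >= 2, "group sizes must be >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  half <- stats::qt(1 - alpha / 2, df) * se
  test_result(c(t = t_stat), df = df, p_value = p,
              ci95 = c((m1 - m2) - half, (m1 - m2) + half),
              method = "Student two-sample t (pooled variance)",
              extra = list(mean_diff = m1 - m2, se = se))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' `K^2 = Z(g1)^2 + Z(g2)^2` combining the transformed skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) statistics, referred to a
#' chi-square with 2 df. Requires n >= 20 (the moment approximations are
#' unreliable below).
#'
#' @param x numeric sample
#' @return `test_result` with extra fields `z_skew`, `z_kurt`
#' @export
normality_omnibus <- function(x) {
  n <- length(x)
  stopifnot_msg(n >= 20, "normality_omnibus requires n >= 20 (got %d)", n)
  if (stats::sd(x) == 0) abort("constant sample: normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  ## skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))

  ## kurtosis transform (Anscombe & Glynn 1983)
  e_g2 <- 3 * (n - 1) / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - e_g2) / sqrt(var_g2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- z1^2 + z2^2
  test_result(c(K2 = k2), df = 2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
              method = "D'Agostino-Pearson omnibus normality",
              extra = list(z_skew = z1, z_kurt = z2, skewness = g1, kurtosis = g2))
}

#' Brown-Forsythe test for homogeneity of variances
#'
#' Levene-type one-way ANOVA on the absolute deviations from the group
#' medians.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2)
#' @return `test_result` (F statistic, df1 = G-1, df2 = N-G)
#' @export
variance_homogeneity <- function(groups) {
  stopifnot_msg(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  stopifnot_msg(all(vapply(groups, length, 1L) >= 2), "each group needs n >= 2")
  z <- lapply(groups, function(g) abs(g - stats::median(g)))
  all_z <- unlist(z)
  ng <- vapply(z, length, 1L)
  gmeans <- vapply(z, mean, 1)
  grand <- mean(all_z)
  ss_between <- sum(ng * (gmeans - grand)^2)
  ss_within <- sum(vapply(z, function(g) sum((g - mean(g))^2), 1))
  df1 <- length(groups) - 1
  df2 <- sum(ng) - length(groups)
  f_stat <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df1) / (ss_within / df2)
  }
  p <- if (is.infinite(f_stat)) 0 else stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  test_result(c(F = f_stat), df = c(df1, df2), p_value = p,
              method = "Brown-Forsythe variance homogeneity")
}

#' Two-way fixed-effects ANOVA
#'
#' Classical sums of squares for balanced designs; Type-II sums of squares
#' (each main effect adjusted for the other, interaction last) when the
#' design is unbalanced. F statistics use the residual mean square of the
#' full model with interaction.
#'
#' @param y response vector
#' @param factor_a,factor_b factors (or coercible); each must have >= 2
#'   levels
#' @return named list of `test_result` objects: `A`, `B`, `AB`
#' @export
anova_two_way <- function(y, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot_msg(nlevels(a) >= 2, "factor_a has a single level")
  stopifnot_msg(nlevels(b) >= 2, "factor_b has a single level")
  stopifnot_msg(length(y) == length(a) && length(y) == length(b),
                "y and factors must have equal length")
  dat <- data.frame(y = y, a = a, b = b)
  rss <- function(fml) sum(stats::resid(stats::lm(fml, data = dat))^2)
  rss_a <- rss(y ~ a); rss_b <- rss(y ~ b); rss_ab <- rss(y ~ a + b)
  fit_full <- stats::lm(y ~ a * b, data = dat)
  rss_full <- sum(stats::resid(fit_full)^2)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_res <- stats::df.residual(fit_full)
  ss_a <- rss_b - rss_ab          # A adjusted for B (Type II)
  ss_b <- rss_a - rss_ab
  ss_ab <- rss_ab - rss_full
  mse <- rss_full / df_res
  mk <- function(ss, df1, label) {
    f <- (ss / df1) / mse
    test_result(c(F = f), df = c(df1, df_res),
                p_value = stats::pf(f, df1, df_res, lower.tail = FALSE),
                method = sprintf("two-way ANOVA: %s", label),
                extra = list(ss = ss))
  }
  list(A = mk(ss_a, df_a, "factor A"),
       B = mk(ss_b, df_b, "factor B"),
       AB = mk(ss_ab, df_ab, "A x B interaction"))
}

## exact two-sided Mann-Whitney p by enumerating all group assignments
mwu_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(ix) {
    u1 <- sum(r[ix]) - nx * (nx + 1) / 2
    min(u1, nx * ny - u1)
  })
  u_obs <- {
    u1 <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    min(u1, nx * ny - u1)
  }
  mean(u_all <= u_obs + 1e-9)
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U1, U2)` with midrank ties. For small samples
#' (`n1 + n2 <= 16`) the two-sided p-value is exact, by enumeration of all
#' group assignments (correct under ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples
#' @return `test_result` with extra fields `U1`, `U2`
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot_msg(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u2 <- nx * ny - u1
  u <- min(u1, u2)
  if (nx + ny <= 16) {
    p <- mwu_exact_p(x, y)
    path <- "exact enumeration"
    z <- NA_real_
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma2 <- nx * ny / 12 * ((nx + ny + 1) - tie_term)
    mu <- nx * ny / 2
    z <- (u - mu + 0.5) / sqrt(sigma2)  # continuity-corrected toward the mean
    p <- min(1, 2 * stats::pnorm(z))
    path <- "normal approximation with tie correction"
  }
  test_result(c(U = u), p_value = p, method = "Mann-Whitney U",
              decision_path = path, extra = list(U1 = u1, U2 = u2, z = z))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic Kolmogorov p-value.
#'
#' @param x,y numeric samples
#' @return `test_result`
#' @export
ks_two_sample <- function(x, y) {
  stopifnot_msg(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), 1)
  fy <- vapply(grid, function(g) mean(y <= g), 1)
  d <- max(abs(fx - fy))
  lambda <- d * sqrt(length(x) * length(y) / (length(x) + length(y)))
  if (lambda == 0) {
    p <- 1
  } else {
    k <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  test_result(c(D = d), p_value = p, method = "two-sample Kolmogorov-Smirnov")
}

#' Correlation test (Pearson or Spearman)
#'
#' Spearman's rho is Pearson's r computed on midranks. The p-value uses the
#' t approximation `t = r sqrt((n-2)/(1-r^2))` on n-2 df.
#'
#' @param x,y numeric vectors (n >= 3)
#' @param method "pearson" or "spearman"
#' @return `test_result`
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot_msg(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stopifnot_msg(n >= 3, "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero-variance input: correlation undefined")
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  stat_name <- if (method == "pearson") "r" else "rho"
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  test_result(stats::setNames(r, stat_name), df = n - 2, p_value = p,
              method = sprintf("%s correlation", method))
}

#' Power of the two-sided two-sample t test (noncentral t)
#'
#' Noncentrality `ncp = d * sqrt(n1 n2 / (n1 + n2))` for effect size `d`
#' (Cohen), df = n1 + n2 - 2.
#'
#' @param n1,n2 group sizes
#' @param effect_size_d Cohen's d (>= 0)
#' @param alpha two-sided significance level
#' @return power in `[0, 1]`
#' @export
power_two_sample_t <- function(n1, n2, effect_size_d, alpha = 0.05) {
  stopifnot_msg(effect_size_d >= 0, "effect size must be >= 0")
  df <- n1 + n2 - 2
  ncp <- effect_size_d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Summary statistics of a sample
#' @param x numeric vector (n >= 2)
#' @return list: `mean`, `sd`, `n`, `median`, `iqr`
#' @export
summary_stats <- function(x) {
  stopifnot_msg(length(x) >= 2, "need n >= 2")
  list(mean = mean(x), sd = stats::sd(x), n = length(x),
       median = stats::median(x),
       iqr = unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7))))
}
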