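# The statistical battery: frozen oracles, algebraic identities,
# dual-route checks against independent implementations.

test_that("Welch from summaries: algebraic identities", {
  # identical groups: t = 0, CI symmetric about 0
  r0 <- welch_t_summary(5, 1, 30, 5, 1, 30)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$ci95[1], -r0$ci95[2])
  # equal SDs and sizes: Satterthwaite collapses to n1 + n2 - 2 exactly
  r1 <- welch_t_summary(4, 1.3, 25, 3, 1.3, 25)
  expect_equal(r1$df, 48)
  # matches base t.test on raw data
  set.seed(10)
  x <- rnorm(30, 5, 2); y <- rnorm(20, 3, 1)
  rw <- welch_t_summary(mean(x), sd(x), 30, mean(y), sd(y), 20)
  bt <- t.test(x, y)
  expect_equal(unname(rw$statistic), unname(bt$statistic), tolerance = 1e-10)
  expect_equal(rw$df, unname(bt$parameter), tolerance = 1e-10)
  expect_equal(rw$ci95, as.numeric(bt$conf.int), tolerance = 1e-10)
  rp <- pooled_t_summary(mean(x), sd(x), 30, mean(y), sd(y), 20)
  bp <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(rp$statistic), unname(bp$statistic), tolerance = 1e-10)
})

test_that("D'Agostino-Pearson matches frozen external oracle values", {
  # values frozen from an independent reference implementation
  x <- c(59.202, 53.555, 57.873, 64.769, 53.425, 46.315, 54.339, 56.262,
         41.909, 53.075, 53.822, 51.625, 52.247, 49.0, 50.075, 51.88,
         42.577, 56.913, 48.795, 44.713, 44.24, 59.59, 52.607, 40.041,
         46.399, 41.513, 43.509, 52.843, 55.927, 56.692, 48.611, 48.404,
         42.995, 54.196, 40.243, 50.47, 52.77, 38.729, 60.137, 38.765,
         52.085, 54.1, 50.508, 48.929, 54.421, 39.946, 53.635, 49.643,
         53.466, 65.888, 38.709, 35.756, 62.18, 43.178, 62.235, 40.007,
         65.316, 73.439, 47.743, 60.165)
  r <- normality_omnibus(x)
  expect_equal(unname(r$statistic), 0.8605011641322153, tolerance = 1e-9)
  expect_equal(r$p_value, 0.6503461092318124, tolerance = 1e-9)
  y <- c(0.312, 0.958, 1.37, 2.125, 0.038, 0.162, 0.955, 2.613, 0.965,
         0.064, 0.411, 3.323, 2.533, 0.162, 0.417, 1.073, 2.047, 1.123,
         3.317, 1.668, 2.247, 3.344, 8.095, 0.022, 2.416, 10.128, 9.471,
         0.418, 0.213, 2.232, 5.999, 2.425, 2.811, 0.553, 0.883, 0.036,
         2.145, 2.389, 0.17, 4.79)
  r2 <- normality_omnibus(y)
  expect_equal(unname(r2$statistic), 25.263609226337227, tolerance = 1e-9)
  expect_lt(r2$p_value, 1e-5)
  expect_error(normality_omnibus(rnorm(10)), "n >= 20")
  expect_error(normality_omnibus(rep(2, 30)), "constant")
})

test_that("omnibus test has power against heavy skew", {
  rejections <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    normality_omnibus(rexp(500))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("Brown-Forsythe equals the definitional oracle and its invariances", {
  # identical groups: F = 0
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(variance_homogeneity(g)$statistic), 0)
  # hand oracle on a small table: one-way ANOVA on |x - median|
  a <- c(3, 7, 8, 1); b <- c(10, 30, 20, 25, 40)
  z <- c(abs(a - median(a)), abs(b - median(b)))
  grp <- factor(rep(1:2, c(4, 5)))
  or <- anova(lm(z ~ grp))
  r <- variance_homogeneity(list(a, b))
  expect_equal(unname(r$statistic), or$`F value`[1], tolerance = 1e-12)
  expect_equal(r$p_value, or$`Pr(>F)`[1], tolerance = 1e-12)
  # shifting one group leaves F unchanged
  r2 <- variance_homogeneity(list(a + 100, b))
  expect_equal(unname(r2$statistic), unname(r$statistic), tolerance = 1e-12)
})

test_that("two-way ANOVA: closed forms, Type-II on unbalanced data", {
  # balanced 2x2, zero noise: hand-computed sums of squares
  a <- rep(c("a1", "a2"), each = 10)
  b <- rep(rep(c("b1", "b2"), each = 5), 2)
  mu <- c(a1b1 = 10, a1b2 = 14, a2b1 = 20, a2b2 = 30)
  y <- mu[paste0(a, b)]
  res <- anova_two_way(y, a, b)
  # classical between-group sums of squares (10 observations per level)
  expect_equal(res$A$ss, sum((tapply(y, a, mean) - mean(y))^2) * 10,
               tolerance = 1e-9)
  expect_equal(res$B$ss, sum((tapply(y, b, mean) - mean(y))^2) * 10,
               tolerance = 1e-9)
  cellm <- tapply(y, paste(a, b), mean)
  inter <- cellm - rep(tapply(y, a, mean), each = 2) -
    rep(tapply(y, b, mean), 2) + mean(y)
  expect_equal(res$AB$ss, 5 * sum(inter^2), tolerance = 1e-9)

  # only factor A varies: SS_B = 0, SS_AB = 0
  y2 <- ifelse(a == "a1", 1, 2)
  res2 <- anova_two_way(y2, a, b)
  expect_equal(res2$B$ss, 0, tolerance = 1e-12)
  expect_equal(res2$AB$ss, 0, tolerance = 1e-12)

  # unbalanced: Type-II SS equal the added-last SS from sequential fits
  set.seed(5)
  n <- c(7, 12, 9, 5)
  au <- rep(c("a1", "a1", "a2", "a2"), n)
  bu <- rep(c("b1", "b2", "b1", "b2"), n)
  yu <- rnorm(sum(n), 10 + (au == "a2") * 2 + (bu == "b2") * 1)
  resu <- anova_two_way(yu, au, bu)
  seq_ab <- anova(lm(yu ~ factor(bu) + factor(au)))  # A after B
  seq_ba <- anova(lm(yu ~ factor(au) + factor(bu)))  # B after A
  expect_equal(resu$A$ss, seq_ab$`Sum Sq`[2], tolerance = 1e-9)
  expect_equal(resu$B$ss, seq_ba$`Sum Sq`[2], tolerance = 1e-9)

  expect_error(anova_two_way(1:4, rep("x", 4), c("u", "u", "v", "v")),
               "single level")
})

test_that("Mann-Whitney: exact enumeration, ties, identities", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  # x == y elementwise: U = n^2 / 2
  x <- c(1, 5, 9)
  re <- mann_whitney_u(x, x)
  expect_equal(unname(re$statistic), 9 / 2)
  # no ties: exact p equals base wilcox.test exact p (independent route)
  set.seed(8)
  for (i in 1:5) {
    xs <- sample(1:100, 6); ys <- sample(1:100, 7) + 0.5  # no ties possible
    r1 <- mann_whitney_u(xs, ys)
    bw <- wilcox.test(xs, ys, exact = TRUE)
    expect_equal(r1$p_value, bw$p.value, tolerance = 1e-12)
    expect_equal(min(unname(bw$statistic), 42 - unname(bw$statistic)),
                 unname(r1$statistic))
  }
  # with ties the exact p still comes from full enumeration; U uses midranks
  rt <- mann_whitney_u(c(1, 2, 2), c(2, 3))
  rks <- rank(c(1, 2, 2, 2, 3))
  u1 <- sum(rks[1:3]) - 6
  expect_equal(unname(rt$statistic), min(u1, 6 - u1))
  # large samples: normal approximation close to base wilcox.test
  set.seed(9)
  xl <- rnorm(30); yl <- rnorm(25, 0.5)
  rl <- mann_whitney_u(xl, yl)
  bl <- wilcox.test(xl, yl, exact = FALSE, correct = TRUE)
  expect_equal(rl$p_value, bl$p.value, tolerance = 1e-6)
})

test_that("Kolmogorov-Smirnov: identities and statistic oracle", {
  x <- c(1, 2, 3)
  expect_equal(unname(ks_two_sample(x, x)$statistic), 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  expect_equal(unname(ks_two_sample(1:5, 11:15)$statistic), 1)
  set.seed(12)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(15, 0.3)
    expect_equal(unname(ks_two_sample(a, b)$statistic),
                 unname(suppressWarnings(ks.test(a, b))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("correlations: identities and permutation oracle", {
  x <- 1:10
  expect_equal(unname(correlation(x, 2 * x + 1)$statistic), 1)
  xc <- c(-3, -1, 0.5, 1, 2, 4, 5, 7)
  rs <- correlation(xc, xc^3, "spearman")
  rp <- correlation(xc, xc^3, "pearson")
  expect_equal(unname(rs$statistic), 1)
  expect_lt(unname(rp$statistic), 1)
  expect_error(correlation(rep(1, 5), 1:5), "zero-variance")

  # permutation oracle at n = 8
  for (s in c(31, 51)) {
    set.seed(s)
    xs <- rnorm(8); ys <- rnorm(8) + 0.5 * xs
    robs <- correlation(xs, ys)
    set.seed(1)
    rperm <- replicate(20000, abs(cor(xs, sample(ys))))
    p_perm <- mean(rperm >= abs(robs$statistic))
    expect_lt(abs(robs$p_value - p_perm), 0.02)
  }
})

test_that("noncentral-t power: limits and independent route", {
  expect_equal(power_two_sample_t(40, 40, 0, alpha = 0.05), 0.05, tolerance = 1e-9)
  expect_gt(power_two_sample_t(1e4, 1e4, 0.5), 0.999)
  # base power.t.test solves the same noncentral-t problem (equal n); it
  # drops the opposite-tail term, which is < 1e-3 at these sizes
  for (n in c(20, 50, 120)) {
    expect_equal(power_two_sample_t(n, n, 0.5),
                 power.t.test(n = n, delta = 0.5, sd = 1)$power,
                 tolerance = 1e-3)
  }
})

test_that("summary_stats matches base definitions", {
  set.seed(2)
  v <- rnorm(50, 4, 1.5)
  s <- summary_stats(v)
  expect_equal(s$mean, mean(v))
  expect_equal(s$iqr, unname(diff(quantile(v, c(0.25, 0.75)))))
})
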