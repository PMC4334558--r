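## The full cohort analysis: reliability, rater/side effects, the
## normality / homoscedasticity gates in front of the group comparison, the
## gender x group ANOVA with its log-transform branch, subtype and
## MRI-subsample comparisons, and the correlation battery. Each result
## carries the decision path that produced it.

oneway_anova <- function(y, g) {
  g <- factor(g)
  stopifnot_msg(nlevels(g) >= 2, "grouping factor has a single level")
  ng <- tapply(y, g, length)
  gm <- tapply(y, g, mean)
  grand <- mean(y)
  ss_b <- sum(ng * (gm - grand)^2)
  ss_w <- sum((y - gm[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  f <- (ss_b / df1) / (ss_w / df2)
  test_result(c(F = f), df = c(df1, df2),
              p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
              method = "one-way ANOVA")
}

#' Run the full statistical analysis on a cohort table
#'
#' Reproduces the canonical decision flow: per-side/per-rater ICC within
#' each group; a rater x side two-way ANOVA per group (if neither factor is
#' significant, the right-side first-rater series becomes the analysis
#' series); D'Agostino-Pearson normality and Brown-Forsythe
#' homoscedasticity gates selecting pooled-t, Welch-t or Mann-Whitney for
#' the group comparison; achieved power at a medium effect size; an age
#' comparison across control / relapsing-remitting / progressive; the
#' gender x group ANOVA with a log-transform branch when homoscedasticity
#' fails on the raw scale; relapsing-remitting vs progressive comparison;
#' the correlation battery of CCT against disease duration, EDSS, onset age
#' and age; and a Kolmogorov-Smirnov plus Mann-Whitney check that the MRI
#' subsample is representative of the whole patient group.
#'
#' @param cohort `cohort_table` (see [gen_cohort()] / [read_cohort()])
#' @param config list: `alpha` (default 0.05), `seed` (MRI subsample draw,
#'   default 1), `mri_n_rr` / `mri_n_p` (subsample sizes, defaults 25 / 12),
#'   `power_effect_size` (default 0.5)
#' @return list of class `cct_analysis` with sections `icc`, `rater_side`,
#'   `canonical_series`, `summaries`, `group_comparison`, `power`, `age`,
#'   `gender`, `subtype`, `correlations`, `mri_subsample`, `config`
#' @export
run_full_analysis <- function(cohort, config = list()) {
  validate_cohort(cohort)
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L
  n_rr_sub <- config$mri_n_rr %||% 25L
  n_p_sub <- config$mri_n_p %||% 12L
  d_power <- config$power_effect_size %||% 0.5

  ms <- cohort[cohort$group == "MS", ]
  ctrl <- cohort[cohort$group == "control", ]
  stopifnot_msg(nrow(ms) >= 2 && nrow(ctrl) >= 2, "both groups need n >= 2")

  ## 1. reliability per group and side
  icc <- list(
    ms_right = icc_a1(cbind(ms$cct_r1_right, ms$cct_r2_right), alpha),
    ms_left = icc_a1(cbind(ms$cct_r1_left, ms$cct_r2_left), alpha),
    control_right = icc_a1(cbind(ctrl$cct_r1_right, ctrl$cct_r2_right), alpha),
    control_left = icc_a1(cbind(ctrl$cct_r1_left, ctrl$cct_r2_left), alpha)
  )

  ## 2. rater x side ANOVA per group (stacked readings)
  stack_group <- function(df) {
    data.frame(
      y = c(df$cct_r1_right, df$cct_r1_left, df$cct_r2_right, df$cct_r2_left),
      rater = rep(c("r1", "r1", "r2", "r2"), each = nrow(df)),
      side = rep(c("right", "left", "right", "left"), each = nrow(df))
    )
  }
  rater_side <- lapply(list(MS = ms, control = ctrl), function(df) {
    st <- stack_group(df)
    anova_two_way(st$y, st$rater, st$side)
  })
  rs_p <- unlist(lapply(rater_side, function(a) {
    c(a$A$p_value, a$B$p_value, a$AB$p_value)
  }))
  no_rater_side_effect <- all(rs_p > alpha)
  canonical_series <- "cct_r1_right"
  canonical_note <- if (no_rater_side_effect) {
    "no rater or side effect: right-side first-rater series used"
  } else {
    "rater/side effect detected; right-side first-rater series used by convention"
  }

  x_ms <- ms[[canonical_series]]
  x_ctrl <- ctrl[[canonical_series]]

  ## 3. normality + homoscedasticity gates -> group comparison
  norm_ms <- normality_omnibus(x_ms)
  norm_ctrl <- normality_omnibus(x_ctrl)
  bf <- variance_homogeneity(list(ms = x_ms, control = x_ctrl))
  normal_ok <- norm_ms$p_value > alpha && norm_ctrl$p_value > alpha
  homosced_ok <- bf$p_value > alpha
  s_ms <- summary_stats(x_ms); s_ctrl <- summary_stats(x_ctrl)
  if (!normal_ok) {
    cmp <- mann_whitney_u(x_ms, x_ctrl)
    cmp$decision_path <- paste("normality rejected -> Mann-Whitney;",
                               cmp$decision_path)
  } else if (!homosced_ok) {
    cmp <- welch_t_summary(s_ms$mean, s_ms$sd, s_ms$n,
                           s_ctrl$mean, s_ctrl$sd, s_ctrl$n, alpha)
    cmp$decision_path <- "normality ok, homoscedasticity rejected -> Welch (Satterthwaite df)"
  } else {
    cmp <- pooled_t_summary(s_ms$mean, s_ms$sd, s_ms$n,
                            s_ctrl$mean, s_ctrl$sd, s_ctrl$n, alpha)
    cmp$decision_path <- "normality and homoscedasticity ok -> pooled t"
  }

  power <- power_two_sample_t(s_ms$n, s_ctrl$n, d_power, alpha)

  ## 4. age balance across control / RR / P
  age_groups <- ifelse(cohort$group == "control", "control", cohort$subtype)
  age_bf <- variance_homogeneity(split(cohort$age, age_groups))
  age_anova <- oneway_anova(cohort$age, age_groups)

  ## 5. gender x group on CCT, log branch if heteroscedastic
  cct_all <- cohort[[canonical_series]]
  cells <- interaction(cohort$sex, cohort$group)
  bf_raw <- variance_homogeneity(split(cct_all, cells))
  if (bf_raw$p_value <= alpha) {
    y_gender <- log(cct_all)
    bf_log <- variance_homogeneity(split(y_gender, cells))
    gender_path <- sprintf(
      "homoscedasticity rejected on raw CCT (p = %.3g); log transform applied (BF p = %.3g)",
      bf_raw$p_value, bf_log$p_value)
  } else {
    y_gender <- cct_all
    bf_log <- NULL
    gender_path <- "homoscedasticity ok on raw CCT"
  }
  gender_anova <- anova_two_way(y_gender, cohort$sex, cohort$group)
  for (nm in names(gender_anova)) gender_anova[[nm]]$decision_path <- gender_path

  ## 6. RR vs P
  rr <- ms[[canonical_series]][!is.na(ms$subtype) & ms$subtype == "RR"]
  pp <- ms[[canonical_series]][!is.na(ms$subtype) & ms$subtype == "P"]
  subtype_cmp <- if (length(rr) >= 1 && length(pp) >= 1) {
    mann_whitney_u(rr, pp)
  } else NULL

  ## 7. correlation battery (within the patient group)
  corr_vars <- c(duration = "duration_y", edss = "edss",
                 onset_age = "onset_age", age = "age")
  correlations <- lapply(corr_vars, function(v) {
    ok <- !is.na(ms[[v]])
    if (sum(ok) < 3) return(NULL)
    correlation(x_ms[ok], ms[[v]][ok], method = "pearson")
  })

  ## 8. MRI subsample vs whole patient group
  mri_subsample <- NULL
  idx_rr <- which(!is.na(ms$subtype) & ms$subtype == "RR")
  idx_p <- which(!is.na(ms$subtype) & ms$subtype == "P")
  if (length(idx_rr) >= n_rr_sub && length(idx_p) >= n_p_sub) {
    sel <- with_seed(child_seed(seed, 11L),
                     c(sample(idx_rr, n_rr_sub), sample(idx_p, n_p_sub)))
    x_sub <- ms[[canonical_series]][sel]
    mri_subsample <- list(
      n = length(sel),
      summary = summary_stats(x_sub),
      ks = ks_two_sample(x_sub, x_ms),
      mwu = mann_whitney_u(x_sub, x_ms)
    )
  }

  structure(list(
    icc = icc,
    rater_side = rater_side,
    canonical_series = canonical_series,
    canonical_note = canonical_note,
    summaries = list(ms = s_ms, control = s_ctrl),
    group_comparison = cmp,
    normality = list(ms = norm_ms, control = norm_ctrl),
    homoscedasticity = bf,
    power = power,
    age = list(bf = age_bf, anova = age_anova),
    gender = list(bf_raw = bf_raw, bf_log = bf_log, anova = gender_anova,
                  log_transformed = bf_raw$p_value <= alpha),
    subtype = subtype_cmp,
    correlations = correlations,
    mri_subsample = mri_subsample,
    config = list(alpha = alpha, seed = seed, mri_n_rr = n_rr_sub,
                  mri_n_p = n_p_sub, power_effect_size = d_power)
  ), class = "cct_analysis")
}

#' @export
print.cct_analysis <- function(x, ...) {
  cat("== Cohort analysis ==\n")
  cat(sprintf("groups: patients n = %d (mean %.2f s, sd %.2f), controls n = %d (mean %.2f s, sd %.2f)\n",
              x$summaries$ms$n, x$summaries$ms$mean, x$summaries$ms$sd,
              x$summaries$control$n, x$summaries$control$mean, x$summaries$control$sd))
  cat("\n-- inter-rater reliability --\n")
  for (nm in names(x$icc)) {
    cat(sprintf("  %-14s ICC = %.3f [%.3f, %.3f]\n", nm, x$icc[[nm]]$icc,
                x$icc[[nm]]$ci95[1], x$icc[[nm]]$ci95[2]))
  }
  cat("\n-- canonical series --\n  ", x$canonical_note, "\n", sep = "")
  cat("\n-- group comparison --\n")
  print(x$group_comparison)
  cat(sprintf("  achieved power at d = %.2f: %.3f\n",
              x$config$power_effect_size, x$power))
  if (!is.null(x$subtype)) {
    cat("\n-- RR vs P --\n"); print(x$subtype)
  }
  cat("\n-- correlations (patients) --\n")
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    if (!is.null(cr)) {
      cat(sprintf("  CCT vs %-10s r = %+.3f, p = %.3g\n", nm,
                  cr$statistic[1], cr$p_value))
    }
  }
  if (!is.null(x$mri_subsample)) {
    cat("\n-- MRI subsample vs whole patient group --\n")
    cat(sprintf("  K-S D = %.4f (p = %.3g); Mann-Whitney U = %.0f (p = %.3g)\n",
                x$mri_subsample$ks$statistic[1], x$mri_subsample$ks$p_value,
                x$mri_subsample$mwu$statistic[1], x$mri_subsample$mwu$p_value))
  }
  invisible(x)
}
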