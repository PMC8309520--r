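#' Paired t-test with Cohen's d on pre/post measurements
#'
#' Computes the paired t statistic on the differences `post - pre`
#' (`t = mean(d) / (sd(d) / sqrt(n))`, df = n - 1, two-sided p) and the
#' paired-design effect size `Cohen's d = mean(d) / sd(d)` with the sample
#' (n - 1) standard deviation. A Shapiro-Wilk normality check on the
#' differences is reported as advisory only; the test itself is always the
#' t-test.
#'
#' @param pre,post Numeric vectors of equal length >= 3, aligned by unit.
#' @return One-row tibble `(t, df, p_value, cohens_d, mean_diff,
#'   shapiro_p)`.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 3, 5, 6))
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must align.")
  n <- length(pre)
  if (n < 3) abort("Need at least 3 pairs.")
  d <- post - pre
  s <- sd(d)
  if (!isTRUE(s > 0)) abort("Zero variance of the differences; t undefined.")
  t_stat <- mean(d) / (s / sqrt(n))
  shapiro_p <- tryCatch(stats::shapiro.test(d)$p.value,
                        error = function(e) NA_real_)
  tibble::tibble(t = t_stat, df = n - 1,
                 p_value = 2 * pt(-abs(t_stat), n - 1),
                 cohens_d = mean(d) / s, mean_diff = mean(d),
                 shapiro_p = shapiro_p)
}

#' ANCOVA comparing two groups with a baseline covariate
#'
#' Fits the linear model `outcome ~ baseline + group` and reports the
#' F-test for the group term adjusted for the pre-viewing baseline, with
#' partial eta-squared `SS_group / (SS_group + SS_residual)` as effect
#' size.
#'
#' @param baseline Numeric covariate (pre-viewing measurement).
#' @param outcome Numeric response (post-viewing measurement).
#' @param group Two-level grouping vector (e.g. 2D vs HMD).
#' @return One-row tibble `(F, df1, df2, p_value, partial_eta_sq)`.
#' @export
ancova_one_covariate <- function(baseline, outcome, group) {
  n <- length(outcome)
  if (length(baseline) != n || length(group) != n) {
    abort("`baseline`, `outcome` and `group` must align.")
  }
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) < 3)) {
    abort("`group` must have two levels with >= 3 units each.")
  }
  if (!isTRUE(sd(baseline) > 0)) abort("Baseline has zero variance.")
  if (!anyNA(suppressWarnings(cor(baseline, as.integer(g)))) &&
      abs(cor(baseline, as.integer(g))) > 1 - 1e-12) {
    abort("Baseline is collinear with the group factor.")
  }
  fit <- lm(outcome ~ baseline + g)
  an <- anova(fit)  # sequential; group entered last = baseline-adjusted
  ss_g <- an["g", "Sum Sq"]; ss_r <- an["Residuals", "Sum Sq"]
  tibble::tibble(F = an["g", "F value"], df1 = 1, df2 = n - 3,
                 p_value = an["g", "Pr(>F)"],
                 partial_eta_sq = ss_g / (ss_g + ss_r))
}

#' Partial correlation of two variables given covariates
#'
#' Correlates the residuals of `x` and `y` after regressing each on the
#' covariate(s) — the multiple-regression route to a partial correlation.
#' With a single covariate this equals the closed form
#' `(r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2))`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @return One-row tibble `(r, df, p_value)`; df = n - 2 - k for k
#'   covariates.
#' @export
partial_correlation <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  n <- length(x)
  if (length(y) != n || nrow(z) != n) abort("Inputs must align.")
  if (n < 4) abort("Need at least 4 observations.")
  if (!isTRUE(sd(x) > 0) || !isTRUE(sd(y) > 0) ||
      any(apply(z, 2, sd) == 0)) {
    abort("Constant input; partial correlation undefined.")
  }
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  r <- cor(rx, ry)
  k <- ncol(z)
  df <- n - 2 - k
  t_stat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of hypotheses in the family (>= 1).
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 3)  # 0.0167, the three pupillary indicators
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 1) {
  if (n_tests < 1) abort("`n_tests` must be >= 1.")
  family_alpha / n_tests
}

cohort_wide <- function(cohort, value) {
  tidyr::pivot_wider(cohort[, c("subject", "condition", "phase", value)],
                     names_from = "phase",
                     values_from = dplyr::all_of(value))
}

#' Full study-level statistical report on a cohort table
#'
#' Reproduces the analysis structure applied to the three pupillary
#' indicators and the total SSQ score: a paired t-test (pre vs post)
#' within each viewing condition with Cohen's d; an ANCOVA comparing
#' post-viewing values between conditions with the pre-viewing value as
#' covariate and partial eta-squared; and the partial correlation between
#' post-viewing SSQ and each indicator with the pre-viewing SSQ and
#' indicator values as covariates. Pupillary indicators are flagged at the
#' Bonferroni-corrected alpha / 3; the SSQ row at the family alpha.
#'
#' @param cohort Tibble with columns `subject`, `condition` (`"2D"` /
#'   `"HMD"`), `phase` (`"pre"` / `"post"`), `mPD`, `sPD`, `prc`,
#'   `ssq_total` — one row per subject x condition x phase (see
#'   [simulate_cohort()]).
#' @param alpha Family-wise alpha (default 0.05).
#' @return A tibble of class `ms_stats_report` with one row per
#'   (indicator, analysis): columns `indicator`, `analysis`, `condition`,
#'   `statistic`, `df1`, `df2`, `p_value`, `effect`, `effect_type`,
#'   `alpha_used`, `significant`. The corrected alpha is attached as
#'   attribute `alpha_corrected`.
#' @export
cohort_stats <- function(cohort, alpha = 0.05) {
  need <- c("subject", "condition", "phase", "mPD", "sPD", "prc", "ssq_total")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  cells <- dplyr::count(cohort, .data$subject)
  bad <- cells$subject[cells$n != 4]
  if (length(bad) > 0) {
    abort(paste0("Subjects without all 4 sessions (pre/post x 2D/HMD): ",
                 paste(bad, collapse = ", "), "."))
  }
  if (length(unique(cohort$subject)) < 3) {
    abort("Need at least 3 complete subjects.")
  }
  indicators <- c("mPD", "sPD", "prc")
  a_pupil <- bonferroni_alpha(alpha, length(indicators))
  rows <- list()
  for (ind in c(indicators, "ssq_total")) {
    a_used <- if (ind == "ssq_total") alpha else a_pupil
    wide <- cohort_wide(cohort, ind)
    for (cond in c("2D", "HMD")) {
      wc <- wide[wide$condition == cond, ]
      tt <- paired_t(wc$pre, wc$post)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        indicator = ind, analysis = "paired_t", condition = cond,
        statistic = tt$t, df1 = tt$df, df2 = NA_real_, p_value = tt$p_value,
        effect = tt$cohens_d, effect_type = "cohens_d",
        alpha_used = a_used, significant = tt$p_value < a_used)
    }
    av <- ancova_one_covariate(wide$pre, wide$post, wide$condition)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      indicator = ind, analysis = "ancova", condition = "HMD vs 2D",
      statistic = av$F, df1 = av$df1, df2 = av$df2, p_value = av$p_value,
      effect = av$partial_eta_sq, effect_type = "partial_eta_sq",
      alpha_used = a_used, significant = av$p_value < a_used)
    if (ind != "ssq_total") {
      wi <- cohort_wide(cohort, ind)
      ws <- cohort_wide(cohort, "ssq_total")
      stopifnot(identical(wi$subject, ws$subject),
                identical(wi$condition, ws$condition))
      pc <- partial_correlation(ws$post, wi$post,
                                cbind(ssq_pre = ws$pre, ind_pre = wi$pre))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        indicator = ind, analysis = "partial_cor", condition = "all",
        statistic = pc$r, df1 = pc$df, df2 = NA_real_, p_value = pc$p_value,
        effect = pc$r, effect_type = "partial_r",
        alpha_used = a_used, significant = pc$p_value < a_used)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  attr(out, "alpha_corrected") <- a_pupil
  class(out) <- c("ms_stats_report", class(out))
  out
}
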