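# Per-feature group comparison and effect sizes.

#' Cohen's d standardized mean difference
#'
#' Uses the unweighted pooled SD, `sqrt((sd1^2 + sd2^2) / 2)`. This variant
#' (rather than the sample-size-weighted pooled SD) is the one that
#' reproduces the published per-feature effect-size column from the printed
#' group means and SDs.
#'
#' @param mean1,sd1 Mean and SD of the first group.
#' @param mean2,sd2 Mean and SD of the second group.
#' @return Non-negative standardized difference; symmetric in group order and
#'   invariant to rescaling all four inputs by a common positive factor.
#' @export
#' @examples
#' cohens_d(115.3, 9.0, 108.8, 16.2) # ~0.50, walking cadence
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (any(sd1 <= 0) || any(sd2 <= 0)) stopf("SDs must be positive")
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Classify a Cohen's d effect size
#'
#' Bands: negligible below 0.2, small 0.2-0.49, medium 0.5-0.79, large from
#' 0.8 upward.
#'
#' @param d Non-negative effect size (vectorized).
#' @return Character vector of classes.
#' @export
classify_effect <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stopf("d must be non-negative")
  as.character(cut(d, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
                   labels = c("negligible", "small", "medium", "large")))
}

#' Rank-sum (Mann-Whitney/Wilcoxon) two-sample test
#'
#' Statistic is the rank sum of the first sample using midranks. For total
#' sample size at most 10 the two-sided p-value is computed by full
#' enumeration of all group assignments (exact even under ties); otherwise
#' the normal approximation with tie correction is used (no continuity
#' correction).
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined n for which exact enumeration is used.
#' @return List with `statistic` (rank sum of `x`), `p_value`, and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10L) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0L || ny == 0L) stopf("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  EW <- nx * (n + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[idx], nrow = nx))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = W, p_value = 1, method = "normal"))
  z <- (W - EW) / sqrt(v)
  list(statistic = W, p_value = 2 * stats::pnorm(-abs(z)), method = "normal")
}

# Shapiro-Wilk screen; returns TRUE when the sample looks normal at `alpha`.
# Degenerate samples (constant, or after thinning at very large n) are
# treated as non-normal so they fall through to the rank branch.
looks_normal <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L) return(FALSE)
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p > alpha
}

#' Two-group comparison of one feature
#'
#' Screens each group for normality (Shapiro-Wilk at 0.05); if both pass, a
#' pooled-variance two-sample t test is used (equivalent to a one-way ANOVA
#' with two groups), otherwise the rank-sum test. When a covariate (BMI in
#' the canonical pipeline) is supplied, the group-term p-value from the
#' least-squares fit `value ~ group + covariate` is additionally reported;
#' this covariate-adjusted OLS stands in for repeated-measures modelling,
#' which is not possible once features are 48-h averages.
#'
#' @param rg_values,fg_values Feature values in the robust and frail groups.
#' @param covariate Optional numeric covariate aligned with
#'   `c(rg_values, fg_values)`.
#' @param alpha Normality-screening significance level.
#' @return List of class `group_comparison`: group summaries, `test_used`
#'   (`"parametric"` or `"rank"`), `statistic`, `p_value`, and
#'   `adjusted_p` (NA when no covariate is given).
#' @export
compare_feature <- function(rg_values, fg_values, covariate = NULL,
                            alpha = 0.05) {
  if (length(rg_values) == 0L || length(fg_values) == 0L) {
    stopf("both groups must be non-empty")
  }
  if (length(rg_values) < 3L || length(fg_values) < 3L) {
    stopf("normality screening needs at least 3 values per group")
  }
  all_vals <- c(rg_values, fg_values)
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  if (stats::var(all_vals) == 0) {
    res <- list(test_used = "rank", statistic = 0, p_value = 1)
  } else if (looks_normal(rg_values, alpha) && looks_normal(fg_values, alpha)) {
    n1 <- length(rg_values); n2 <- length(fg_values)
    sp2 <- ((n1 - 1) * stats::var(rg_values) + (n2 - 1) * stats::var(fg_values)) /
      (n1 + n2 - 2)
    tstat <- (mean(rg_values) - mean(fg_values)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
    res <- list(test_used = "parametric", statistic = tstat, p_value = p)
  } else {
    rs <- rank_sum_test(rg_values, fg_values)
    res <- list(test_used = "rank", statistic = rs$statistic,
                p_value = rs$p_value)
  }
  adjusted_p <- NA_real_
  if (!is.null(covariate)) {
    if (length(covariate) != length(all_vals)) {
      stopf("covariate must align with c(rg_values, fg_values)")
    }
    grp <- rep(c(0L, 1L), c(length(rg_values), length(fg_values)))
    fit <- stats::lm(all_vals ~ grp + covariate)
    ct <- stats::coef(summary(fit))
    adjusted_p <- if ("grp" %in% rownames(ct)) ct["grp", 4L] else NA_real_
  }
  structure(c(list(rg_summary = summ(rg_values), fg_summary = summ(fg_values)),
              res, list(adjusted_p = adjusted_p)),
            class = "group_comparison")
}

#' Per-feature comparison table for a cohort
#'
#' One row per feature: per-group mean and SD, the screening-selected test's
#' p-value, the BMI-adjusted p-value, Cohen's d (unweighted pooled SD), and
#' its class.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param adjust_bmi Include the covariate-adjusted p-value column.
#' @return data.frame shaped like the published feature-comparison table.
#' @export
feature_comparison_table <- function(cohort, adjust_bmi = TRUE) {
  tab <- feature_table()
  keep <- tab$name %in% names(cohort)
  tab <- tab[keep, , drop = FALSE]
  rg <- cohort$frailty_status == 0L
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    v <- cohort[[tab$name[i]]]
    cmp <- compare_feature(v[rg], v[!rg],
                           covariate = if (adjust_bmi) c(cohort$bmi[rg], cohort$bmi[!rg]))
    d <- cohens_d(cmp$rg_summary[["mean"]], cmp$rg_summary[["sd"]],
                  cmp$fg_summary[["mean"]], cmp$fg_summary[["sd"]])
    data.frame(feature = tab$name[i], unit = tab$unit[i],
               rg_mean = cmp$rg_summary[["mean"]], rg_sd = cmp$rg_summary[["sd"]],
               fg_mean = cmp$fg_summary[["mean"]], fg_sd = cmp$fg_summary[["sd"]],
               test = cmp$test_used, p_value = cmp$p_value,
               bmi_adjusted_p = cmp$adjusted_p,
               effect_size = d, effect_class = classify_effect(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square statistic for a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with no continuity
#' correction.
#'
#' @param tab Matrix of counts.
#' @return List with `statistic`, `df`, and `p_value`.
#' @export
chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be non-negative")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Demographics and phenotype summary table
#'
#' Per-group mean and SD for the continuous demographics, count (%) for
#' gender and each phenotype flag, and the Pearson chi-square statistic for
#' the gender-by-group table. SDs are reported as NA for single-participant
#' groups.
#'
#' @param cohort A cohort data frame.
#' @return data.frame with one row per demographic/phenotype quantity.
#' @export
demographics_table <- function(cohort) {
  if (nrow(cohort) == 0L) stopf("cohort is empty")
  rg <- cohort[cohort$frailty_status == 0L, , drop = FALSE]
  fg <- cohort[cohort$frailty_status == 1L, , drop = FALSE]
  msd <- function(v) {
    if (length(v) == 0L) return("")
    s <- if (length(v) > 1L) sprintf("%.1f", stats::sd(v)) else "NA"
    sprintf("%.1f +/- %s", mean(v), s)
  }
  cnt <- function(flag, grp) {
    n <- nrow(grp)
    if (n == 0L) return("")
    k <- sum(grp[[flag]] == if (flag == "gender") "female" else 1L)
    sprintf("%d (%.1f)", k, 100 * k / n)
  }
  cont <- c(age = "age", height_cm = "height_cm", weight_kg = "weight_kg",
            bmi = "bmi")
  rows <- lapply(names(cont), function(nm) {
    data.frame(quantity = nm, rg = msd(rg[[cont[[nm]]]]),
               fg = msd(fg[[cont[[nm]]]]), statistic = NA_real_,
               stringsAsFactors = FALSE)
  })
  gender_stat <- NA_real_
  if (nrow(rg) > 0L && nrow(fg) > 0L) {
    tb <- rbind(c(sum(rg$gender == "female"), sum(rg$gender != "female")),
                c(sum(fg$gender == "female"), sum(fg$gender != "female")))
    if (all(rowSums(tb) > 0L) && all(colSums(tb) > 0L)) {
      gender_stat <- chisq_stat(tb)$statistic
    }
  }
  rows <- c(rows, list(data.frame(quantity = "female", rg = cnt("gender", rg),
                                  fg = cnt("gender", fg),
                                  statistic = gender_stat,
                                  stringsAsFactors = FALSE)))
  rows <- c(rows, lapply(phenotype_names(), function(p) {
    data.frame(quantity = paste0("presence_of_", p), rg = cnt(p, rg),
               fg = cnt(p, fg), statistic = NA_real_,
               stringsAsFactors = FALSE)
  }))
  do.call(rbind, rows)
}
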