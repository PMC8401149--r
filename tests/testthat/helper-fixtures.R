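# Shared fixtures, built in code at test time.

# Small default-spec cohort, memoized per seed within a test run.
.fixture_env <- new.env(parent = emptyenv())
fixture_cohort <- function(seed = 1L, ...) {
  key <- paste0("cohort_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(default_cohort_spec(seed = seed, ...))
  }
  .fixture_env[[key]]
}

# Six-feature spec with two strong planted features (Cohen's d = 0.9) and
# four weak ones (d = 0.25), no phenotype coupling and independent features
# (correlated null features act as suppressor variables and legitimately
# carry multivariate signal, which would confound rank-recovery checks).
planted_spec <- function(seed, d_strong = 0.9, d_weak = 0.25) {
  fs <- data.frame(
    name = paste0("f", 1:6),
    display = paste0("f", 1:6),
    unit = "n",
    phenotype_class = rep(c("slowness_weakness", "exhaustion", "inactivity"), 2L),
    rg_mean = c(rep(50 + d_strong * 10, 2L), rep(50 + d_weak * 10, 4L)),
    rg_sd = 10, fg_mean = 50, fg_sd = 10,
    support = "nonnegative", distribution = "truncnorm",
    significant = TRUE, stringsAsFactors = FALSE)
  cohort_spec(feature_specs = fs, coupling = 0, seed = seed,
              within_group_correlation = 0)
}

# O(n^2) pair-counting AUC oracle, independent of the rank implementation.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force two-sided permutation p-value for the rank-sum statistic.
rank_sum_oracle <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_along(x)])
  ew <- length(x) * (n + 1) / 2
  sets <- utils::combn(n, length(x))
  stats <- apply(sets, 2L, function(ix) sum(r[ix]))
  mean(abs(stats - ew) >= abs(obs - ew) - 1e-9)
}

# Published per-feature effect sizes (printed alongside the group moments).
printed_effect_sizes <- function() {
  c(walking_cadence = 0.50, n_stand_to_sit = 0.30,
    duration_stand_to_sit = 0.42, n_sit_to_stand = 0.32,
    duration_sit_to_stand = 0.61, longest_walking_bout = 0.68,
    walking_steps_per_episode = 0.43, walking_steps = 0.69,
    pct_sitting = 0.26, pct_standing = 0.81, pct_walking = 0.82,
    pct_lying = 0.24)
}
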