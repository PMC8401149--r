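#' The 12 pendant-sensor activity features and their published group moments
#'
#' Returns the schema of the twelve 48-h-averaged physical-activity features
#' measured by a sternum-worn pendant sensor, together with the per-group
#' mean/SD used as defaults by the synthetic cohort generator: one row per
#' feature with its display name, unit, associated Fried phenotype class,
#' robust-group (RG) and pre-frail/frail-group (FG) moments, support bounds,
#' and the marginal family used to simulate it.
#'
#' Feature-to-phenotype mapping: walking cadence and the four postural
#' transition features indicate slowness/weakness; longest walking bout and
#' walking steps per episode indicate exhaustion; total walking steps and the
#' four posture percentages indicate inactivity. The weight-loss phenotype has
#' no associated sensor feature.
#'
#' @return A data.frame with columns `name` (canonical snake_case identifier),
#'   `display`, `unit`, `phenotype_class`, `rg_mean`, `rg_sd`, `fg_mean`,
#'   `fg_sd`, `support` (`"nonnegative"` or `"percentage"`), `distribution`
#'   (`"truncnorm"` or `"lognormal"`), and `significant` (logical; FALSE only
#'   for `pct_lying`, the sole feature not discriminating the groups).
#' @export
#' @examples
#' feature_table()[, c("name", "phenotype_class", "rg_mean", "fg_mean")]
feature_table <- function() {
  tab <- data.frame(
    name = c("walking_cadence", "n_stand_to_sit", "duration_stand_to_sit",
             "n_sit_to_stand", "duration_sit_to_stand", "longest_walking_bout",
             "walking_steps_per_episode", "walking_steps", "pct_sitting",
             "pct_standing", "pct_walking", "pct_lying"),
    display = c("Walking cadence", "Number of stand-to-sit",
                "Duration of stand-to-sit", "Number of sit-to-stand",
                "Duration of sit-to-stand", "Longest walking bout",
                "Walking steps per episode", "Walking steps", "% of sitting",
                "% of standing", "% of walking", "% of lying"),
    unit = c("steps/min", "n", "s", "n", "s", "n", "n", "n",
             "%", "%", "%", "%"),
    phenotype_class = c(rep("slowness_weakness", 5L), rep("exhaustion", 2L),
                        rep("inactivity", 5L)),
    rg_mean = c(115.3, 134.2, 3.9, 137.0, 3.9, 1372.7, 32.5, 4788.5,
                34.3, 17.9, 6.8, 41.0),
    rg_sd   = c(9.0, 70.8, 0.6, 66.0, 0.6, 1702.5, 18.9, 2667.6,
                11.0, 4.8, 3.1, 12.3),
    fg_mean = c(108.8, 114.3, 4.3, 117.1, 4.6, 472.9, 25.4, 3004.6,
                37.6, 13.7, 4.3, 44.4),
    fg_sd   = c(16.2, 59.9, 1.2, 59.0, 1.5, 749.8, 13.8, 2531.5,
                13.9, 5.5, 3.0, 16.4),
    support = c(rep("nonnegative", 8L), rep("percentage", 4L)),
    distribution = c("truncnorm", "truncnorm", "truncnorm", "truncnorm",
                     "truncnorm", "lognormal", "truncnorm", "lognormal",
                     "truncnorm", "truncnorm", "truncnorm", "truncnorm"),
    significant = c(rep(TRUE, 11L), FALSE),
    stringsAsFactors = FALSE
  )
  tab
}

# Canonical order of the four posture-percentage features (a composition of
# the 24-h day; their group means sum to exactly 100 in both groups).
posture_features <- function() {
  c("pct_sitting", "pct_standing", "pct_walking", "pct_lying")
}

#' Names of the five Fried phenotype indicator columns
#' @return Character vector in canonical column order.
#' @export
phenotype_names <- function() {
  c("slowness", "weakness", "exhaustion", "weight_loss", "inactivity")
}

# Map a vector of feature identifiers (canonical or display form) to
# canonical snake_case names; errors on anything unrecognized.
canonical_feature_names <- function(x) {
  tab <- feature_table()
  alias <- c(stats::setNames(tab$name, tab$name),
             stats::setNames(tab$name, tab$display),
             stats::setNames(tab$name, tolower(tab$display)))
  out <- alias[as.character(x)]
  if (anyNA(out)) {
    stopf("unknown feature name(s): %s",
          paste(x[is.na(out)], collapse = ", "))
  }
  unname(out)
}

#' Construct a synthetic-cohort specification
#'
#' A cohort spec bundles everything the generator needs: group sizes, the
#' within-FG phenotype prevalences, per-feature per-group moments, the latent
#' within-group correlation, the phenotype-coupling strength, and a seed.
#'
#' @param n_robust,n_frail Group sizes (robust group RG; pre-frail/frail
#'   group FG). Defaults 73 and 186, the published cohort.
#' @param phenotype_prevalence Named numeric vector of within-FG prevalences
#'   for `slowness`, `weakness`, `exhaustion`, `weight_loss`, `inactivity`.
#' @param feature_specs Data frame in the shape of [feature_table()].
#' @param within_group_correlation Exchangeable latent-normal correlation
#'   applied to the non-posture features (default 0.3).
#' @param coupling Phenotype-coupling strength: 0 makes FG feature values
#'   independent of which phenotype flags are set, 1 separates flag-on and
#'   flag-off FG participants by the full RG-FG mean gap (default 1).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_robust = 73L, n_frail = 186L,
                        phenotype_prevalence = c(slowness = 0.694,
                                                 weakness = 0.640,
                                                 exhaustion = 0.301,
                                                 weight_loss = 0.091,
                                                 inactivity = 0.403),
                        feature_specs = feature_table(),
                        within_group_correlation = 0.3,
                        coupling = 1.0,
                        seed = 1L) {
  if (!is_count(n_robust) || !is_count(n_frail)) {
    stopf("n_robust and n_frail must be non-negative integers")
  }
  pn <- phenotype_names()
  if (!all(pn %in% names(phenotype_prevalence))) {
    stopf("phenotype_prevalence must name all of: %s", paste(pn, collapse = ", "))
  }
  phenotype_prevalence <- phenotype_prevalence[pn]
  if (!all(is_prob(phenotype_prevalence))) {
    stopf("phenotype prevalences must lie in [0, 1]")
  }
  required <- c("name", "unit", "phenotype_class", "rg_mean", "rg_sd",
                "fg_mean", "fg_sd", "support", "distribution")
  if (!all(required %in% names(feature_specs))) {
    stopf("feature_specs is missing column(s): %s",
          paste(setdiff(required, names(feature_specs)), collapse = ", "))
  }
  if (any(feature_specs$rg_sd <= 0) || any(feature_specs$fg_sd <= 0)) {
    stopf("feature SDs must be positive")
  }
  pct <- feature_specs$support == "percentage"
  if (any(feature_specs$rg_mean[pct] < 0 | feature_specs$rg_mean[pct] > 100) ||
      any(feature_specs$fg_mean[pct] < 0 | feature_specs$fg_mean[pct] > 100)) {
    stopf("percentage-feature means must lie in [0, 100]")
  }
  if (!is.numeric(within_group_correlation) ||
      within_group_correlation < 0 || within_group_correlation >= 1) {
    stopf("within_group_correlation must lie in [0, 1)")
  }
  if (!is.numeric(coupling) || coupling < 0) {
    stopf("coupling must be non-negative")
  }
  structure(list(n_robust = as.integer(n_robust),
                 n_frail = as.integer(n_frail),
                 phenotype_prevalence = phenotype_prevalence,
                 feature_specs = feature_specs,
                 within_group_correlation = within_group_correlation,
                 coupling = coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort specification matching the published study
#'
#' Populates a [cohort_spec()] with the published cohort structure: 73 robust
#' and 186 pre-frail/frail participants, within-FG phenotype prevalences of
#' 69.4% (slowness), 64.0% (weakness), 30.1% (exhaustion), 9.1% (weight
#' loss), and 40.3% (inactivity), and all twelve per-group feature moments
#' from [feature_table()].
#'
#' @param seed Integer seed stored in the spec.
#' @param ... Overrides passed through to [cohort_spec()].
#' @return A `cohort_spec` object.
#' @export
#' @examples
#' spec <- default_cohort_spec(seed = 42)
#' spec$n_robust; spec$n_frail
default_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(seed = seed, ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  groups: %d robust (RG), %d pre-frail/frail (FG)\n",
              x$n_robust, x$n_frail))
  cat(sprintf("  phenotype prevalence (FG): %s\n",
              paste(sprintf("%s=%.3f", names(x$phenotype_prevalence),
                            x$phenotype_prevalence), collapse = ", ")))
  cat(sprintf("  features: %d; correlation=%.2f; coupling=%.2f; seed=%d\n",
              nrow(x$feature_specs), x$within_group_correlation,
              x$coupling, x$seed))
  invisible(x)
}

# Per-group demographic moments used by the generator (age in years, height
# in cm, BMI in kg/m^2; proportion female). Weight is derived from BMI and
# height because the published weight/height/BMI triplets are mutually
# inconsistent and BMI is the covariate the analysis adjusts for.
demographic_params <- function() {
  list(
    rg = list(age = c(74.4, 6.6), height = c(165.1, 8.9),
              bmi = c(24.6, 8.0), p_female = 0.726),
    fg = list(age = c(76.6, 8.4), height = c(163.3, 10.1),
              bmi = c(29.1, 8.0), p_female = 0.618)
  )
}
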