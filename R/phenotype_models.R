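# Fixed-feature-set logistic models for frailty and its phenotypes.

#' Fixed feature sets for the five phenotype models
#'
#' The physical-frailty model uses the 11 significant features (all except
#' `pct_lying`, the only feature not discriminating the groups); slowness and
#' weakness use the five slowness/weakness features; exhaustion uses the two
#' exhaustion features; inactivity uses the four significant inactivity
#' features (total walking steps and the sitting/standing/walking
#' percentages). There is no weight-loss model because no sensor feature maps
#' to weight loss.
#'
#' @return Named list of specs, each with `model_name`, `dependent` (outcome
#'   column), and `features` (ordered canonical names).
#' @export
model_feature_sets <- function() {
  tab <- feature_table()
  sw <- tab$name[tab$phenotype_class == "slowness_weakness"]
  ex <- tab$name[tab$phenotype_class == "exhaustion"]
  inact <- setdiff(tab$name[tab$phenotype_class == "inactivity"], "pct_lying")
  spec <- function(model_name, dependent, features) {
    list(model_name = model_name, dependent = dependent, features = features)
  }
  list(
    physical_frailty = spec("physical_frailty", "frailty_status",
                            tab$name[tab$significant]),
    slowness = spec("slowness", "slowness", sw),
    weakness = spec("weakness", "weakness", sw),
    exhaustion = spec("exhaustion", "exhaustion", ex),
    inactivity = spec("inactivity", "inactivity", inact)
  )
}

#' Fit the five phenotype models on a cohort
#'
#' Fits each fixed-feature-set logistic model on the full cohort and reports
#' its in-sample AUC. Phenotype outcomes are compared among all participants:
#' robust participants count as phenotype-negative, since they carry no
#' Fried phenotype by definition. A model whose outcome has a single class
#' in the cohort is skipped with a recorded reason.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param specs Model specs, by default [model_feature_sets()].
#' @return Named list; per model either `list(spec, model, auc)` or
#'   `list(spec, skipped = reason)`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 3))
#' fits <- fit_phenotype_models(cohort)
#' sapply(fits, function(f) f$auc)
fit_phenotype_models <- function(cohort, specs = model_feature_sets()) {
  lapply(specs, function(sp) {
    y <- cohort[[sp$dependent]]
    if (is.null(y)) {
      return(list(spec = sp, skipped = sprintf("missing outcome column '%s'",
                                               sp$dependent)))
    }
    if (length(unique(y)) < 2L) {
      return(list(spec = sp,
                  skipped = sprintf("outcome '%s' has a single class",
                                    sp$dependent)))
    }
    X <- as.matrix(cohort[, sp$features, drop = FALSE])
    model <- fit_logistic(X, y)
    list(spec = sp, model = model,
         auc = roc_auc(predict_proba(model, X), y))
  })
}

#' Summarize phenotype-model fits as a table
#'
#' @param fits Output of [fit_phenotype_models()].
#' @return data.frame with model name, feature list, AUC, and skip reason.
#' @export
phenotype_model_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$spec$model_name,
               features = paste(f$spec$features, collapse = ", "),
               auc = if (is.null(f$auc)) NA_real_ else f$auc,
               skipped = if (is.null(f$skipped)) "" else f$skipped,
               stringsAsFactors = FALSE)
  }))
}
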