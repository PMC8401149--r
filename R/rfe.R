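# Balanced-bootstrap recursive feature elimination.
#
# The algorithm: (1) build B pairs of balanced training / out-of-bag
# validation sets, equalizing the class sizes by subsampling the larger
# class to the smaller class's size before resampling; (2)-(5) per recursive
# loop with k active features, fit k candidate logistic models per pair,
# average each candidate's AUC over the B pairs, and eliminate one feature;
# (6) repeat down to l_stop active features. Total fits follow the closed
# form B * (a - l + 1) * (a + l) / 2 for a starting features and stop size l.

#' Closed-form fit count of the elimination loop
#'
#' `B * n * (a + l) / 2` with `n = a - l + 1` loops: each loop with k active
#' features fits k models per bootstrap pair, and k runs from `a` down to
#' `l`. At the published scale (a = 11, l = 2, B = 2000) this is 130,000.
#'
#' @param a Number of starting features.
#' @param l Number of features in the last loop.
#' @param B Number of bootstrap pairs.
#' @return Integer fit count.
#' @export
eq1_fit_count <- function(a, l = 2L, B = 2000L) {
  stopifnot(a >= l, l >= 1L, B >= 1L)
  as.integer(B * (a - l + 1) * (a + l) / 2)
}

#' Balanced bootstrap training/validation pairs
#'
#' For each pair the larger class is subsampled without replacement down to
#' the smaller class's size; the resulting balanced pool is resampled with
#' replacement within class (so every training set is exactly 50/50); the
#' pool rows never drawn into the training set form the out-of-bag
#' validation set. Pairs whose validation set is empty or single-class are
#' redrawn, up to 100 retries each. Deterministic given the seed.
#'
#' @param cohort Cohort data frame with `frailty_status` and feature columns.
#' @param B Number of pairs (the published analysis uses 2000).
#' @param seed Integer seed.
#' @param features Feature columns to carry (default: all known features
#'   present in the cohort).
#' @return Object of class `bootstrap_pairs`: the feature matrix, labels,
#'   and per-pair training (with repetition) and validation row indices.
#' @export
make_bootstrap_pairs <- function(cohort, B = 2000L, seed = 1L,
                                 features = intersect(feature_table()$name,
                                                      names(cohort))) {
  if (!is_count(B, min = 1L)) stopf("B must be a positive integer")
  if (length(features) == 0L) stopf("no feature columns found")
  y <- cohort$frailty_status
  if (is.null(y) || length(unique(y)) < 2L) {
    stopf("cohort must contain both frailty classes")
  }
  X <- as.matrix(cohort[, features, drop = FALSE])
  storage.mode(X) <- "double"
  idx0 <- which(y == 0L)
  idx1 <- which(y == 1L)
  # the smaller class is the reference; the larger one gets subsampled
  if (length(idx0) <= length(idx1)) {
    ref <- idx0; big <- idx1
  } else {
    ref <- idx1; big <- idx0
  }
  n_ref <- length(ref)
  pairs <- vector("list", B)
  retries <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (attempt in seq_len(100L)) {
        sub <- sample(big, n_ref, replace = FALSE)
        train <- c(ref[sample.int(n_ref, n_ref, replace = TRUE)],
                   sub[sample.int(n_ref, n_ref, replace = TRUE)])
        pool <- c(ref, sub)
        valid <- setdiff(pool, unique(train))
        if (length(valid) > 0L && length(unique(y[valid])) == 2L) break
        retries <- retries + 1L
        if (attempt == 100L) {
          stopf("pair %d: no valid out-of-bag split after 100 retries", b)
        }
      }
      pairs[[b]] <- list(pair_id = b, train = train, valid = valid)
    }
  })
  structure(list(X = X, y = as.numeric(y), features = features,
                 pairs = pairs, n_ref = n_ref, B = B, seed = seed,
                 retries = retries),
            class = "bootstrap_pairs")
}

#' @export
print.bootstrap_pairs <- function(x, ...) {
  cat(sprintf("<bootstrap_pairs> B=%d; balanced training %d+%d; %d feature(s); seed=%d\n",
              x$B, x$n_ref, x$n_ref, length(x$features), x$seed))
  invisible(x)
}

# Fit one logistic model and return its AUC on the given evaluation rows;
# NA (counted by the caller) when the fit fails.
fit_auc <- function(Xtr, ytr, Xev, yev) {
  m <- tryCatch(fit_logistic(Xtr, ytr), error = function(e) NULL)
  if (is.null(m)) return(NA_real_)
  tryCatch(roc_auc(predict_proba(m, Xev), yev), error = function(e) NA_real_)
}

#' Recursive feature elimination over bootstrap pairs
#'
#' Per recursive loop with k active features, k candidate models are fitted
#' on every pair's training set and their training-set AUCs averaged over
#' pairs. Under `criterion = "leave_one_out"` (default) candidate i omits
#' feature i and the feature whose omission model has the *highest* mean AUC
#' is eliminated (its absence costs the least); under
#' `criterion = "univariate"` candidate i contains only feature i and the
#' feature with the *lowest* mean single-feature AUC is eliminated. Ties are
#' broken by eliminating the feature with the larger index in the input
#' ordering. Loops run until `l_stop` features remain active, and the final
#' elimination fixes the complete ranking (rank 1 = most retained).
#'
#' @param pairs A [make_bootstrap_pairs()] object.
#' @param features Ordered starting features (default: all features in
#'   `pairs`). The canonical pipeline passes the 11 significant features.
#' @param criterion `"leave_one_out"` or `"univariate"`.
#' @param l_stop Number of active features in the last loop (at least 2).
#' @return Object of class `elimination_trace`: `loops` (per-loop active
#'   set, per-feature mean AUC, removed feature), `ranking` (named integer,
#'   1 = best), `fit_count`, `expected_fit_count` from [eq1_fit_count()],
#'   and `n_failed` fit failures.
#' @export
run_rfe <- function(pairs, features = pairs$features,
                    criterion = c("leave_one_out", "univariate"),
                    l_stop = 2L) {
  stopifnot(inherits(pairs, "bootstrap_pairs"))
  criterion <- match.arg(criterion)
  if (anyDuplicated(features)) stopf("duplicate feature names")
  if (!all(features %in% pairs$features)) {
    stopf("unknown feature(s): %s",
          paste(setdiff(features, pairs$features), collapse = ", "))
  }
  a <- length(features)
  if (!is_count(l_stop, min = 2L) || a < l_stop) {
    stopf("need |features| >= l_stop >= 2")
  }
  B <- pairs$B
  # materialize per-pair training data once; indices are fixed across loops
  tr_X <- lapply(pairs$pairs, function(p) pairs$X[p$train, , drop = FALSE])
  tr_y <- lapply(pairs$pairs, function(p) pairs$y[p$train])

  active <- features
  loops <- list()
  fit_count <- 0L
  n_failed <- 0L
  while (length(active) >= l_stop) {
    k <- length(active)
    auc_sum <- numeric(k)
    auc_n <- integer(k)
    for (b in seq_len(B)) {
      Xb <- tr_X[[b]][, active, drop = FALSE]
      yb <- tr_y[[b]]
      for (i in seq_len(k)) {
        cols <- if (criterion == "leave_one_out") -i else i
        av <- fit_auc(Xb[, cols, drop = FALSE], yb,
                      Xb[, cols, drop = FALSE], yb)
        fit_count <- fit_count + 1L
        if (is.na(av)) n_failed <- n_failed + 1L
        else { auc_sum[i] <- auc_sum[i] + av; auc_n[i] <- auc_n[i] + 1L }
      }
    }
    mean_auc <- ifelse(auc_n > 0L, auc_sum / pmax(auc_n, 1L), NA_real_)
    target <- if (criterion == "leave_one_out") max(mean_auc, na.rm = TRUE)
              else min(mean_auc, na.rm = TRUE)
    cand <- which(abs(mean_auc - target) < 1e-12)
    # deterministic tie-break: the candidate latest in the input ordering
    pick <- cand[which.max(match(active[cand], features))]
    loops[[length(loops) + 1L]] <- list(
      active = active,
      mean_auc = stats::setNames(mean_auc, active),
      removed = active[pick])
    active <- active[-pick]
  }
  # ranking: survivors first (ordered by importance in the last loop), then
  # eliminated features in reverse order of removal
  last <- loops[[length(loops)]]
  surv_auc <- last$mean_auc[active]
  surv_order <- if (criterion == "leave_one_out") {
    active[order(surv_auc)]          # lowest omission AUC = most needed
  } else {
    active[order(-surv_auc)]         # highest univariate AUC = most needed
  }
  removed_rev <- rev(vapply(loops, function(l) l$removed, character(1L)))
  ranking <- stats::setNames(seq_len(a), c(surv_order, removed_rev))
  expected <- eq1_fit_count(a, l_stop, B)
  if (fit_count != expected) {
    warnf("fit count %d differs from closed form %d", fit_count, expected)
  }
  structure(list(loops = loops, ranking = ranking, fit_count = fit_count,
                 expected_fit_count = expected, criterion = criterion,
                 l_stop = as.integer(l_stop), B = B, n_failed = n_failed),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> %s; %d loop(s); %d fits (closed form %d); %d failed\n",
              x$criterion, length(x$loops), x$fit_count,
              x$expected_fit_count, x$n_failed))
  cat("ranking:\n")
  print(x$ranking)
  invisible(x)
}

# Evaluate one feature subset over all pairs; returns a pairs-by-metric
# matrix for the requested surface ("training" or "validation").
eval_subset <- function(pairs, feats, surface, threshold) {
  B <- pairs$B
  metric_names <- c("auc", "sensitivity", "specificity", "accuracy",
                    "ppv", "npv")
  out <- matrix(NA_real_, B, length(metric_names),
                dimnames = list(NULL, metric_names))
  failed <- 0L
  for (b in seq_len(B)) {
    p <- pairs$pairs[[b]]
    Xtr <- pairs$X[p$train, feats, drop = FALSE]
    ytr <- pairs$y[p$train]
    m <- tryCatch(fit_logistic(Xtr, ytr), error = function(e) NULL)
    if (is.null(m)) { failed <- failed + 1L; next }
    if (surface == "training") {
      Xev <- Xtr; yev <- ytr
    } else {
      Xev <- pairs$X[p$valid, feats, drop = FALSE]
      yev <- pairs$y[p$valid]
    }
    cm <- tryCatch(confusion_metrics(predict_proba(m, Xev), yev, threshold),
                   error = function(e) NULL)
    if (is.null(cm)) { failed <- failed + 1L; next }
    out[b, ] <- cm$metrics[metric_names]
  }
  attr(out, "failed") <- failed
  out
}

#' Performance as a function of the number of top-ranked features
#'
#' For k = 1 ... a, fits the top-k-ranked features on every pair's training
#' set and evaluates AUC, sensitivity, specificity, accuracy, PPV, and NPV
#' on the training sets (the published figure's convention) and on the
#' out-of-bag validation sets, reporting the mean and normal-approximation
#' 95% CI of the mean over pairs.
#'
#' @param pairs A [make_bootstrap_pairs()] object.
#' @param ranking Named integer ranking (from [run_rfe()]); rank 1 = best.
#' @param threshold Classification threshold.
#' @param k_values Subset sizes to evaluate (default 1 to all).
#' @return data.frame in long format: `n_features`, `surface`, `metric`,
#'   `mean`, `lower`, `upper`. Failed fits are skipped; the total skip count
#'   is in `attr(, "n_failed")`.
#' @export
performance_curve <- function(pairs, ranking, threshold = 0.5,
                              k_values = seq_along(ranking)) {
  stopifnot(inherits(pairs, "bootstrap_pairs"))
  if (!all(names(ranking) %in% pairs$features)) {
    stopf("ranking covers unknown features")
  }
  ordered_feats <- names(sort(ranking))
  rows <- list()
  n_failed <- 0L
  for (k in k_values) {
    feats <- ordered_feats[seq_len(k)]
    for (surface in c("training", "validation")) {
      res <- eval_subset(pairs, feats, surface, threshold)
      n_failed <- n_failed + attr(res, "failed")
      for (m in colnames(res)) {
        ci <- mean_ci(res[, m])
        rows[[length(rows) + 1L]] <- data.frame(
          n_features = k, surface = surface, metric = m,
          mean = ci[["mean"]], lower = ci[["lower"]], upper = ci[["upper"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Select the optimal feature subset from a performance curve
#'
#' Returns the top-k features for the smallest k whose mean training AUC
#' falls inside `auc_band` and (when `phenotype_coverage` is on) whose top-k
#' set includes at least one feature from every phenotype class represented
#' in the ranking. If no k satisfies both constraints, the smallest k
#' meeting the AUC band alone is returned with a warning; if no k meets the
#' band at all, the k with the highest mean AUC is returned with a warning.
#'
#' @param curve Output of [performance_curve()].
#' @param ranking Named integer ranking.
#' @param auc_band Acceptable AUC interval (default `c(0.7, 0.8)`, the
#'   published acceptability band).
#' @param phenotype_coverage Require class coverage (default TRUE).
#' @param surface Which surface's AUC to use (default `"training"`).
#' @return Character vector of selected features (best rank first).
#' @export
select_optimal <- function(curve, ranking, auc_band = c(0.7, 0.8),
                           phenotype_coverage = TRUE,
                           surface = "training") {
  stopifnot(length(auc_band) == 2L, auc_band[1] < auc_band[2])
  ordered_feats <- names(sort(ranking))
  tab <- feature_table()
  cls <- stats::setNames(tab$phenotype_class, tab$name)
  classes_present <- unique(stats::na.omit(cls[ordered_feats]))
  aucs <- curve[curve$metric == "auc" & curve$surface == surface, ]
  aucs <- aucs[order(aucs$n_features), ]
  in_band <- aucs$n_features[aucs$mean >= auc_band[1] &
                               aucs$mean <= auc_band[2]]
  covers <- function(k) {
    got <- unique(stats::na.omit(cls[ordered_feats[seq_len(k)]]))
    all(classes_present %in% got)
  }
  for (k in in_band) {
    if (!phenotype_coverage || covers(k)) {
      return(ordered_feats[seq_len(k)])
    }
  }
  if (length(in_band) > 0L) {
    warnf("no subset in the AUC band covers all phenotype classes; returning the AUC-only solution")
    return(ordered_feats[seq_len(in_band[1L])])
  }
  warnf("no subset size reaches the AUC band; returning the best-AUC size")
  k <- aucs$n_features[which.max(aucs$mean)]
  ordered_feats[seq_len(k)]
}

#' Out-of-bag validation of a final feature set
#'
#' Fits the given feature set on every pair's training set and evaluates all
#' six metrics on the corresponding out-of-bag validation set, reporting the
#' mean and 95% CI of the mean over pairs (the published validation table's
#' convention).
#'
#' @param pairs A [make_bootstrap_pairs()] object.
#' @param feature_set Non-empty character vector of features.
#' @param threshold Classification threshold.
#' @return data.frame with `metric`, `mean`, `lower`, `upper`;
#'   `attr(, "n_failed")` counts skipped pairs.
#' @export
validate_final <- function(pairs, feature_set, threshold = 0.5) {
  stopifnot(inherits(pairs, "bootstrap_pairs"))
  if (length(feature_set) == 0L) stopf("feature set is empty")
  if (!all(feature_set %in% pairs$features)) {
    stopf("unknown feature(s): %s",
          paste(setdiff(feature_set, pairs$features), collapse = ", "))
  }
  res <- eval_subset(pairs, feature_set, "validation", threshold)
  rows <- lapply(colnames(res), function(m) {
    ci <- mean_ci(res[, m])
    data.frame(metric = m, mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- attr(res, "failed")
  out
}
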