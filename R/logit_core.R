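# Self-contained binary logistic regression, ROC/AUC, and confusion-matrix
# metrics. Written in-package (rather than wrapping glm) because the
# bootstrap elimination loop needs a solver with deterministic separation
# handling, an instrumentable fit path, and stored standardization.

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares. Features are z-scored on the training data by default and the
#' scaling is stored in the model, so prediction is invariant to affine
#' rescaling of the inputs. When the solver detects separation (any
#' standardized coefficient exceeding 15 in magnitude, or a singular working
#' system), it refits with a small ridge penalty (lambda = 1e-3) and flags
#' the model; this keeps unattended resampling loops robust.
#'
#' @param X Numeric matrix or data.frame, cases by features.
#' @param y Binary outcome (0/1 or logical), length `nrow(X)`.
#' @param standardize Z-score columns on the training data (default TRUE).
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @param ridge Ridge penalty used on detected separation.
#' @return Object of class `frail_logit`: `feature_names`, `beta0` and
#'   `betas` on the raw input scale, `beta0_std`/`betas_std` on the
#'   standardized scale, `center`/`scale` (NULL when `standardize = FALSE`),
#'   `converged`, `n_iterations`, and `separation` (TRUE when the ridge
#'   fallback engaged).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- rbinom(100, 1, plogis(x[, 1] - x[, 2]))
#' fit <- fit_logistic(x, y)
#' coef(fit)
fit_logistic <- function(X, y, standardize = TRUE, tol = 1e-8,
                         max_iter = 100L, ridge = 1e-3) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  if (nrow(X) != length(y)) stopf("nrow(X) must equal length(y)")
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stopf("degenerate labels: need at least 2 cases of each class")
  }
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  ctr <- NULL; scl <- NULL
  col_sd <- sqrt(pmax(colSums(X^2) - n * colMeans(X)^2, 0) / (n - 1L))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- col_sd
    if (any(!is.finite(scl)) || any(scl <= 0)) {
      stopf("constant (zero-variance) feature column(s): %s",
            paste(nms[!is.finite(scl) | scl <= 0], collapse = ", "))
    }
    X <- scale(X, center = ctr, scale = scl)
    dimnames(X) <- list(NULL, nms)
  } else if (any(col_sd == 0)) {
    stopf("constant (zero-variance) feature column(s)")
  }
  Xd <- cbind(1, X)
  p <- ncol(Xd)

  irls <- function(lambda, iter_budget = max_iter) {
    beta <- numeric(p)
    pen <- diag(c(0, rep(lambda, p - 1L)), p)
    for (it in seq_len(iter_budget)) {
      eta <- drop(Xd %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      Xw <- Xd * w
      sys <- crossprod(Xw, Xd) + pen
      rhs <- crossprod(Xw, z)
      new_beta <- tryCatch(drop(solve(sys, rhs)), error = function(e) NULL)
      if (is.null(new_beta) || any(!is.finite(new_beta))) {
        return(list(beta = beta, iter = it, converged = FALSE,
                    diverged = TRUE))
      }
      delta <- max(abs(new_beta - beta))
      beta <- new_beta
      if (max(abs(beta[-1L])) > 15 && lambda == 0) {
        return(list(beta = beta, iter = it, converged = FALSE,
                    diverged = TRUE))
      }
      if (delta < tol) {
        return(list(beta = beta, iter = it, converged = TRUE,
                    diverged = FALSE))
      }
    }
    list(beta = beta, iter = iter_budget, converged = FALSE, diverged = FALSE)
  }

  fit <- irls(0)
  separation <- FALSE
  # slow multi-feature divergence (several redundant separating features
  # sharing the growth) shows as non-convergence with large standardized
  # coefficients rather than a single runaway one; treat it as separation
  if (fit$diverged ||
      (!fit$converged && max(abs(fit$beta[-1L])) > 5)) {
    separation <- TRUE
    fit <- irls(ridge, iter_budget = 3L * max_iter)
  }
  if (!fit$converged) {
    if (!separation) stopf("IRLS did not converge in %d iterations", max_iter)
    # ridge fit not converged either: keep best effort but mark it
  }
  beta <- fit$beta
  if (standardize) {
    betas_raw <- beta[-1L] / scl
    beta0_raw <- beta[1L] - sum(beta[-1L] * ctr / scl)
  } else {
    betas_raw <- beta[-1L]
    beta0_raw <- beta[1L]
  }
  structure(list(feature_names = nms,
                 beta0 = unname(beta0_raw),
                 betas = stats::setNames(unname(betas_raw), nms),
                 beta0_std = unname(beta[1L]),
                 betas_std = stats::setNames(unname(beta[-1L]), nms),
                 center = ctr, scale = scl,
                 converged = fit$converged,
                 n_iterations = fit$iter,
                 separation = separation),
            class = "frail_logit")
}

#' @export
coef.frail_logit <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$betas)
}

#' @export
print.frail_logit <- function(x, ...) {
  cat(sprintf("<frail_logit> %d feature(s); converged=%s (%d iter)%s\n",
              length(x$feature_names), x$converged, x$n_iterations,
              if (x$separation) "; ridge fallback (separation)" else ""))
  print(coef(x))
  invisible(x)
}

#' Predicted class-1 probabilities from a logistic model
#'
#' Applies the model's stored standardization (if any) and the inverse-logit
#' link. When `X` has column names they are matched against the model's
#' feature names (order-insensitive); a missing feature column is an error.
#'
#' @param model A `frail_logit` (or the fixed-coefficient model from
#'   [eq4_model()]).
#' @param X Matrix or data.frame of feature values.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "frail_logit"))
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    missing <- setdiff(model$feature_names, colnames(X))
    if (length(missing) > 0L) {
      stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
    }
    X <- X[, model$feature_names, drop = FALSE]
  } else if (ncol(X) != length(model$feature_names)) {
    stopf("X has %d columns; model expects %d", ncol(X),
          length(model$feature_names))
  }
  storage.mode(X) <- "double"
  drop(stats::plogis(model$beta0 + X %*% model$betas))
}

#' @export
predict.frail_logit <- function(object, newdata, type = "response", ...) {
  predict_proba(object, newdata)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with ties counted one half, equivalent to
#' trapezoidal integration of the ROC curve over all thresholds: the
#' probability that a randomly chosen positive scores above a randomly
#' chosen negative.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in [0, 1]; errors when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stopf("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts and classification metrics at a threshold
#'
#' Classifies `probabilities >= threshold` as positive and reports true/false
#' positive/negative counts plus sensitivity, specificity, accuracy, PPV
#' (tp / (tp + fp)), NPV (tn / (tn + fn)), and the AUC of the probabilities.
#' Metrics are stored as proportions in [0, 1]; reporting layers render them
#' as percentages. A metric with a zero denominator is NA, not zero.
#'
#' @param probabilities Scores in [0, 1].
#' @param labels Binary labels.
#' @param threshold Classification threshold on the probability (default 0.5).
#' @return List of class `frail_metrics` with elements `counts` (tp, fp, tn,
#'   fn) and `metrics` (auc, sensitivity, specificity, accuracy, ppv, npv).
#' @export
confusion_metrics <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  if (length(probabilities) == 0L) stopf("empty input")
  if (length(probabilities) != length(labels)) stopf("length mismatch")
  if (any(probabilities < -1e-9 | probabilities > 1 + 1e-9)) {
    stopf("probabilities must lie in [0, 1]")
  }
  pred <- as.numeric(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  auc <- if (sum(labels == 1) > 0L && sum(labels == 0) > 0L) {
    roc_auc(probabilities, labels)
  } else NA_real_
  structure(list(
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    metrics = c(auc = auc,
                sensitivity = safe_div(tp, tp + fn),
                specificity = safe_div(tn, tn + fp),
                accuracy = safe_div(tp + tn, tp + fp + tn + fn),
                ppv = safe_div(tp, tp + fp),
                npv = safe_div(tn, tn + fn))
  ), class = "frail_metrics")
}

# ---- fixed-coefficient four-feature scorer --------------------------------

#' Published four-feature frailty model coefficients
#'
#' The fixed raw-scale coefficients of the published four-feature logistic
#' frailty model: intercept 6.1883 and slopes -0.0885 (% of standing),
#' -0.1405 (% of walking), -0.0003 (walking cadence), -0.0341 (longest
#' walking bout, steps). All four features are protective, so the modelled
#' probability is P(pre-frail/frail).
#'
#' @return Named numeric vector of the five coefficients.
#' @export
eq4_coefficients <- function() {
  c(intercept = 6.1883, pct_standing = -0.0885, pct_walking = -0.1405,
    walking_cadence = -0.0003, longest_walking_bout = -0.0341)
}

#' Fixed-coefficient frailty model as a `frail_logit`
#'
#' @return A `frail_logit` carrying the published raw-scale coefficients
#'   (no standardization), usable with [predict_proba()].
#' @export
eq4_model <- function() {
  cf <- eq4_coefficients()
  structure(list(feature_names = names(cf)[-1L],
                 beta0 = unname(cf[[1L]]),
                 betas = cf[-1L],
                 beta0_std = unname(cf[[1L]]),
                 betas_std = cf[-1L],
                 center = NULL, scale = NULL,
                 converged = TRUE, n_iterations = 0L, separation = FALSE),
            class = "frail_logit")
}

#' Score frailty probability with the published four-feature model
#'
#' Evaluates the fixed-coefficient model on raw (unstandardized) inputs.
#' Inputs outside plausible physical ranges trigger a warning, not an error.
#'
#' @param standing_pct Percentage of 24 h spent standing.
#' @param walking_pct Percentage of 24 h spent walking.
#' @param cadence Walking cadence, steps/min (90th percentile).
#' @param longest_bout Steps in the longest unbroken walking bout.
#' @return Probability of pre-frail/frail status, in [0, 1] (vectorized).
#' @export
#' @examples
#' score_eq4(17.9, 6.8, 115.3, 1372.7) # robust-group mean profile
score_eq4 <- function(standing_pct, walking_pct, cadence, longest_bout) {
  rng_warn <- function(v, lo, hi, what) {
    if (any(v < lo | v > hi, na.rm = TRUE)) {
      warnf("%s outside plausible range [%g, %g]", what, lo, hi)
    }
  }
  rng_warn(standing_pct, 0, 100, "standing_pct")
  rng_warn(walking_pct, 0, 100, "walking_pct")
  rng_warn(cadence, 0, 250, "cadence")
  rng_warn(longest_bout, 0, 5e4, "longest_bout")
  cf <- eq4_coefficients()
  stats::plogis(cf[["intercept"]] +
                cf[["pct_standing"]] * standing_pct +
                cf[["pct_walking"]] * walking_pct +
                cf[["walking_cadence"]] * cadence +
                cf[["longest_walking_bout"]] * longest_bout)
}
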