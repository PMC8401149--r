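test_that("fit_logistic matches the closed-form 2x2 log odds ratio", {
  # binary predictor with counts [[20,10],[10,20]]: slope = ln((20*20)/(10*10))
  x <- c(rep(0, 30), rep(1, 30))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  fit <- fit_logistic(matrix(x, ncol = 1), y, standardize = FALSE)
  expect_equal(unname(fit$betas), log(4), tolerance = 1e-6)
  fit_std <- fit_logistic(matrix(x, ncol = 1), y)  # raw-scale back-transform
  expect_equal(unname(fit_std$betas), log(4), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("fit_logistic rejects degenerate inputs", {
  X <- cbind(a = rnorm(20), b = rep(3, 20))
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(X, y), "constant")
  expect_error(fit_logistic(matrix(rnorm(20)), rep(1, 20)), "degenerate")
  expect_error(fit_logistic(matrix(rnorm(20)), c(0, rep(1, 19))), "degenerate")
  expect_error(fit_logistic(matrix(rnorm(10)), rep(c(0.5, 1), 5)), "binary")
})

test_that("separation engages the ridge fallback instead of failing", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  expect_true(fit$separation)
  p <- predict_proba(fit, matrix(x, ncol = 1))
  expect_gt(roc_auc(p, y), 0.99)
})

test_that("parameter recovery on simulated data", {
  set.seed(11)
  n <- 20000
  X <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$beta0 - (-1)), 0.1)
  expect_lt(abs(fit$betas[["a"]] - 0.8), 0.1)
  expect_lt(abs(fit$betas[["b"]] - (-0.5)), 0.1)
})

test_that("prediction is invariant to affine rescaling of the inputs", {
  set.seed(12)
  X <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(100, 1, plogis(X[, 1] - X[, 2]))
  f1 <- fit_logistic(X, y)
  Xs <- sweep(sweep(X, 2, c(10, -5, 2)), 2, c(3, 0.5, 100), "*")
  f2 <- fit_logistic(Xs, y)
  expect_equal(predict_proba(f1, X), predict_proba(f2, Xs), tolerance = 1e-6)
})

test_that("predict_proba honours names, order, and the logit identity", {
  set.seed(13)
  X <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(X[, 1]))
  fit <- fit_logistic(X, y)
  shuffled <- X[, c("b", "a")]
  expect_equal(predict_proba(fit, shuffled), predict_proba(fit, X))
  expect_error(predict_proba(fit, X[, "a", drop = FALSE]), "missing feature")
  # linear predictor 0 -> probability 0.5
  m <- eq4_model()
  zero_lp <- c(pct_standing = 0, pct_walking = 0, walking_cadence = 0,
               longest_walking_bout = 6.1883 / 0.0341)
  expect_equal(unname(predict_proba(m, t(zero_lp))), 0.5, tolerance = 1e-12)
  # monotone in the linear predictor
  p <- predict_proba(m, cbind(pct_standing = 0, pct_walking = 0,
                              walking_cadence = 0,
                              longest_walking_bout = seq(0, 500, 50)))
  expect_true(all(diff(p) < 0))
})

test_that("roc_auc equals O(n^2) pair counting, with ties", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- sample(seq_len(max(2, n %/% 2)), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels),
                 label = sprintf("instance %d (n=%d)", i, n))
  }
})

test_that("roc_auc properties: perfection, symmetry, monotone invariance", {
  y <- rep(c(0, 1), each = 10)
  s <- c(rnorm(10, 0), rnorm(10, 10))
  expect_equal(roc_auc(s, y), 1)
  set.seed(15)
  s2 <- rnorm(20)
  expect_equal(roc_auc(s2, y) + roc_auc(-s2, y), 1)
  expect_equal(roc_auc(s2, y), roc_auc(exp(s2), y))   # strictly increasing map
  expect_error(roc_auc(s2, rep(1, 20)), "both classes")
  # null case: scores independent of labels
  set.seed(16)
  big_y <- rbinom(20000, 1, 0.5)
  expect_lt(abs(roc_auc(rnorm(20000), big_y) - 0.5), 0.02)
})

test_that("confusion metrics implement the predictive-value formulas", {
  # tp=3 fp=1 tn=9 fn=1 at threshold 0.5
  prob <- c(0.9, 0.8, 0.7, 0.6, rep(0.1, 9), 0.2)
  lab <- c(1, 1, 1, 0, rep(0, 9), 1)
  cm <- confusion_metrics(prob, lab)
  expect_equal(unname(cm$counts), c(3, 1, 9, 1))
  expect_equal(cm$metrics[["ppv"]] * 100, 75)
  expect_equal(cm$metrics[["npv"]] * 100, 90)
  expect_equal(cm$metrics[["sensitivity"]], 3 / 4)
  expect_equal(cm$metrics[["specificity"]], 9 / 10)
  expect_equal(cm$metrics[["accuracy"]], 12 / 14)
  # all correct
  cm2 <- confusion_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(cm2$metrics[c("sensitivity", "specificity", "accuracy")]),
               c(1, 1, 1))
  # zero denominator -> NA, not zero
  cm3 <- confusion_metrics(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 0))
  expect_true(is.na(cm3$metrics[["ppv"]]))
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
  expect_error(confusion_metrics(c(0.5, 1.5), c(0, 1)), "\\[0, 1\\]")
})

test_that("the fixed four-feature scorer carries the printed coefficients", {
  cf <- eq4_coefficients()
  expect_identical(unname(cf),
                   c(6.1883, -0.0885, -0.1405, -0.0003, -0.0341))
  # monotone decreasing in % standing
  p <- score_eq4(seq(0, 40, 5), 5, 110, 300)
  expect_true(all(diff(p) < 0))
  # robust-group mean profile scores lower than frail-group mean profile
  p_rg <- score_eq4(17.9, 6.8, 115.3, 1372.7)
  p_fg <- score_eq4(13.7, 4.3, 108.8, 472.9)
  expect_lt(p_rg, p_fg)
  # direct evaluation oracle
  lp_rg <- 6.1883 - 0.0885 * 17.9 - 0.1405 * 6.8 - 0.0003 * 115.3 -
    0.0341 * 1372.7
  expect_equal(p_rg, 1 / (1 + exp(-lp_rg)), tolerance = 1e-12)
  expect_warning(score_eq4(150, 5, 110, 300), "plausible range")
  # scorer agrees with the model object through predict_proba
  X <- cbind(pct_standing = c(17.9, 13.7), pct_walking = c(6.8, 4.3),
             walking_cadence = c(115.3, 108.8),
             longest_walking_bout = c(1372.7, 472.9))
  expect_equal(unname(predict_proba(eq4_model(), X)),
               c(p_rg, p_fg), tolerance = 1e-12)
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(17)
  X <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(X[, 1]))
  fit <- fit_logistic(X, y)
  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  back <- read_model_json(f)
  expect_equal(predict_proba(back, X), predict_proba(fit, X), tolerance = 1e-10)
  expect_equal(back$feature_names, fit$feature_names)
})
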