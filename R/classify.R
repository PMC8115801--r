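#' Classifier specification
#'
#' Two model families with one train/score contract: an RBF-kernel support
#' vector machine (`"svm"`) and linear logistic regression (`"logreg"`).
#' Hyperparameters follow the widely used library defaults: SVM cost 1 and
#' kernel width `gamma = 1 / (n_features * Var(X))` (the pooled variance of
#' all feature entries), logistic regression by maximum likelihood.
#'
#' @param family `"svm"` or `"logreg"`.
#' @param cost SVM soft-margin cost C.
#' @param gamma `"scale"` for the variance heuristic or an explicit positive
#'   scalar.
#' @param feature_subset optional subset of
#'   `c("n1_mean","n1_sd","p3_mean","p3_sd")` to train on.
#' @param seed optional seed carried along for reproducibility bookkeeping.
#' @return an object of class `mw_model_spec`.
#' @export
model_spec <- function(family = c("svm", "logreg"), cost = 1.0,
                       gamma = "scale", feature_subset = NULL, seed = NULL) {
  family <- match.arg(family)
  assert_that(cost > 0, "classify", "cost must be positive")
  if (!is.null(feature_subset)) {
    bad <- setdiff(feature_subset, feature_names())
    assert_that(length(bad) == 0, "classify",
                paste("unknown feature(s):", paste(bad, collapse = ", ")))
  }
  structure(list(family = family, cost = cost, gamma = gamma,
                 feature_subset = feature_subset, seed = seed),
            class = "mw_model_spec")
}

#' Fit a classifier
#'
#' @param x feature table or matrix; only `spec$feature_subset` columns are
#'   used when given.
#' @param y binary labels (0 = on task, 1 = mind wandering).
#' @param spec an `mw_model_spec`.
#' @return an `mw_model`: the fitted state plus the scoring contract that
#'   larger decision scores mean more mind-wandering-like.
#' @export
fit_model <- function(x, y, spec = model_spec()) {
  feats <- spec$feature_subset %||% feature_names()
  x <- as.matrix(as.data.frame(x)[, feats, drop = FALSE])
  y <- as.integer(y)
  assert_that(length(unique(y)) == 2, "classify",
              "training labels must contain both classes")
  fit <- if (spec$family == "svm") {
    g <- if (identical(spec$gamma, "scale")) {
      v <- mean((x - mean(x))^2)
      1 / (ncol(x) * max(v, 1e-12))
    } else spec$gamma
    e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
               cost = spec$cost, gamma = g, scale = FALSE)
  } else {
    suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                                    family = stats::binomial()))
  }
  structure(list(spec = spec, features = feats, fit = fit),
            class = "mw_model")
}

#' Continuous decision scores
#'
#' Larger scores are more mind-wandering-like. For the SVM the score is the
#' signed distance to the margin boundary (oriented towards class 1); for
#' logistic regression it is the linear predictor, so thresholding at 0 is
#' thresholding the probability at 0.5. Class predictions used for
#' accuracy/MCC/confusion are `score > 0`.
#'
#' @param model an `mw_model`.
#' @param x feature table or matrix with the training columns.
#' @return numeric score vector.
#' @export
decision_scores <- function(model, x) {
  xd <- as.data.frame(x)
  missing <- setdiff(model$features, colnames(xd))
  assert_that(length(missing) == 0, "classify",
              paste("missing feature column(s):", paste(missing, collapse = ", ")))
  xm <- as.matrix(xd[, model$features, drop = FALSE])
  if (model$spec$family == "svm") {
    pr <- stats::predict(model$fit, xm, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm orients positive decision values towards the first label in
    # the column name ("0/1" vs "1/0"); flip so positive means class 1
    s <- as.numeric(dv[, 1])
    if (startsWith(colnames(dv)[1], "0")) s <- -s
    s
  } else {
    as.numeric(cbind(1, xm) %*% stats::coef(model$fit))
  }
}

#' Predicted class labels
#'
#' @param model an `mw_model`.
#' @param x feature rows.
#' @return integer vector of 0/1 predictions (`score > 0`).
#' @export
predict_labels <- function(model, x) {
  as.integer(decision_scores(model, x) > 0)
}
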