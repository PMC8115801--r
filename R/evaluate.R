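# Person-dependent (5-fold) and person-independent (leave-one-subject-out)
# evaluation, with SMOTE applied inside training folds only.

#' Stratified fold assignment
#'
#' Shuffles rows, then assigns each class's members cyclically to folds so
#' fold sizes differ by at most one overall and each class is split as
#' evenly as it permits. With a single class this degrades to plain
#' shuffled folds.
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed optional seed.
#' @return integer fold id (1..k) per row.
#' @export
make_folds <- function(labels, k, seed = NULL) {
  n <- length(labels)
  assert_that(k >= 2 && k <= n, "evaluate", "need 2 <= k <= n")
  with_seed(seed, {
    ord <- sample.int(n)                      # shuffle, then stabilize by class
    ord <- ord[order(labels[ord])]
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Person-dependent (within-subject) evaluation
#'
#' k-fold cross-validation over one subject's blocks. SMOTE is applied to
#' the training rows of each fold only; test predictions are pooled across
#' folds and the metrics computed once on the pooled predictions (per-fold
#' metrics on 5 rows are unstable). Fold-wise accuracies are also returned.
#'
#' @param features one subject's (normalized) feature rows.
#' @param spec an `mw_model_spec`.
#' @param k number of folds.
#' @param balance an `mw_balance_config`.
#' @param seed seed for fold shuffling and SMOTE.
#' @return an `mw_metrics` report (with `fold_accuracy` attached), or
#'   `NULL` with a warning when the subject fails the minority-count rule.
#' @export
person_dependent_eval <- function(features, spec = model_spec(), k = 5L,
                                  balance = balance_config(), seed = NULL) {
  lab <- features$label
  n_min <- min(sum(lab == 0), sum(lab == 1))
  if (n_min < balance$min_minority_per_subject) {
    warning(sprintf("subject %s: minority class %d < %d; skipped",
                    features$subject_id[1], n_min,
                    balance$min_minority_per_subject), call. = FALSE)
    return(NULL)
  }
  folds <- make_folds(lab, k, seed = seed)
  scores <- numeric(nrow(features)); pred <- integer(nrow(features))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    bal <- smote(features[tr, feature_names(), drop = FALSE], lab[tr],
                 balance, seed = derive_seed(seed %||% 0, f))
    xtr <- as.data.frame(bal$x)
    m <- fit_model(xtr, bal$y, spec)
    scores[te] <- decision_scores(m, features[te, , drop = FALSE])
    pred[te] <- as.integer(scores[te] > 0)
    fold_acc[f] <- mean(pred[te] == lab[te])
  }
  rep_ <- metrics_report(scores, pred, lab)
  rep_$fold_accuracy <- fold_acc
  rep_
}

#' Person-dependent evaluation over a cohort
#'
#' Applies the minority-count exclusion rule, runs
#' [person_dependent_eval()] per retained subject and aggregates with the
#' mean and its standard error.
#'
#' @param features cohort feature table (normalized).
#' @param spec,k,balance,seed as in [person_dependent_eval()].
#' @return an `mw_cohort_result`.
#' @export
person_dependent_cohort <- function(features, spec = model_spec(), k = 5L,
                                    balance = balance_config(), seed = NULL) {
  ex <- exclude_low_minority_subjects(features, balance)
  ids <- unique(ex$features$subject_id)
  reports <- list()
  for (i in seq_along(ids)) {
    rows <- ex$features[ex$features$subject_id == ids[i], , drop = FALSE]
    r <- person_dependent_eval(rows, spec, k, balance,
                               seed = derive_seed(seed %||% 0, 1000 + i))
    if (!is.null(r)) reports[[ids[i]]] <- r
  }
  cohort_result(reports, excluded = ex$excluded, dispersion = "se")
}

#' Person-independent (leave-one-subject-out) evaluation
#'
#' One iteration per retained subject: that subject's rows are the test
#' set, all other subjects' rows the training set (training and test never
#' share a subject id). SMOTE balances the pooled training rows of each
#' iteration; metrics are computed on the held-out subject and aggregated
#' with the mean and standard deviation.
#'
#' @param features cohort feature table.
#' @param spec an `mw_model_spec`.
#' @param balance an `mw_balance_config`.
#' @param seed seed for the per-iteration SMOTE draws.
#' @param normalization `"per_subject"` normalizes every subject (including
#'   the held-out one) against their own on-task mean, as published;
#'   `"training"` estimates the per-feature on-task mean from the training
#'   subjects only and subtracts it from the test rows, avoiding the use of
#'   the held-out subject's labels. `"none"` expects pre-normalized input.
#' @return an `mw_cohort_result`; `$splits` records the train/test subject
#'   ids of every iteration for leakage auditing.
#' @export
person_independent_eval <- function(features, spec = model_spec(),
                                    balance = balance_config(), seed = NULL,
                                    normalization = c("per_subject",
                                                      "training", "none")) {
  normalization <- match.arg(normalization)
  ex <- exclude_low_minority_subjects(features, balance)
  feats <- ex$features
  ids <- unique(feats$subject_id)
  assert_that(length(ids) >= 3, "evaluate",
              sprintf("fewer than 3 subjects (%d) for leave-one-subject-out",
                      length(ids)))
  if (normalization == "per_subject") feats <- normalize_features(feats)
  reports <- list(); splits <- list()
  for (i in seq_along(ids)) {
    te <- feats$subject_id == ids[i]
    train <- feats[!te, , drop = FALSE]
    test <- feats[te, , drop = FALSE]
    if (normalization == "training") {
      on <- train$label == 0
      for (f in feature_names()) {
        mu <- mean(train[on, f])
        train[[f]] <- train[[f]] - mu
        test[[f]] <- test[[f]] - mu
      }
    }
    bal <- smote(train[, feature_names(), drop = FALSE], train$label,
                 balance, seed = derive_seed(seed %||% 0, 2000 + i))
    m <- fit_model(as.data.frame(bal$x), bal$y, spec)
    s <- decision_scores(m, test)
    reports[[ids[i]]] <- metrics_report(s, as.integer(s > 0), test$label)
    splits[[ids[i]]] <- list(test = ids[i], train = setdiff(ids, ids[i]))
  }
  res <- cohort_result(reports, excluded = ex$excluded, dispersion = "sd")
  res$splits <- splits
  res
}

cohort_result <- function(reports, excluded, dispersion = c("sd", "se")) {
  dispersion <- match.arg(dispersion)
  per <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(subject_id = id, accuracy = r$accuracy, auc = r$auc,
               mcc = r$mcc, n_test_rows = r$n_test_rows)
  }))
  disp <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    if (dispersion == "sd") stats::sd(v) else stats::sd(v) / sqrt(length(v))
  }
  agg <- data.frame(
    metric = c("accuracy", "auc", "mcc"),
    mean = c(mean(per$accuracy), mean(per$auc, na.rm = TRUE), mean(per$mcc)),
    dispersion = c(disp(per$accuracy), disp(per$auc), disp(per$mcc)))
  structure(list(per_subject = per, aggregate = agg,
                 dispersion_type = dispersion, reports = reports,
                 excluded = excluded),
            class = "mw_cohort_result")
}

#' @export
print.mw_cohort_result <- function(x, ...) {
  cat(sprintf("<mw_cohort_result> %d subjects (%d excluded), dispersion = %s\n",
              nrow(x$per_subject), length(x$excluded), x$dispersion_type))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-9s %.3f (%s = %.3f)\n", agg$metric[i], agg$mean[i],
                toupper(x$dispersion_type), agg$dispersion[i]))
  invisible(x)
}

#' Single-feature ablation
#'
#' Runs one person-independent evaluation per feature, training on that
#' feature alone, to rank features by their individual predictive value.
#'
#' @param features cohort feature table.
#' @param spec base `mw_model_spec` (its `feature_subset` is overridden).
#' @param which_features features to ablate over (default all four).
#' @param balance,seed,normalization as in [person_independent_eval()].
#' @return data.frame with one row per feature: mean accuracy, AUC, MCC.
#' @export
feature_ablation <- function(features, spec = model_spec(),
                             which_features = feature_names(),
                             balance = balance_config(), seed = NULL,
                             normalization = "per_subject") {
  bad <- setdiff(which_features, feature_names())
  assert_that(length(bad) == 0, "evaluate",
              paste("unknown feature(s):", paste(bad, collapse = ", ")))
  rows <- lapply(which_features, function(f) {
    sp <- spec; sp$feature_subset <- f
    r <- person_independent_eval(features, sp, balance, seed, normalization)
    a <- r$aggregate
    data.frame(feature = f, accuracy = a$mean[a$metric == "accuracy"],
               auc = a$mean[a$metric == "auc"], mcc = a$mean[a$metric == "mcc"])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
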