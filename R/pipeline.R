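#' Assemble a full run configuration
#'
#' Bundles the per-stage configurations plus the evaluation choices into
#' one serializable object; a run's config echo suffices to reproduce it
#' bit for bit.
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param generator an `mw_generator_config`.
#' @param features an `mw_feature_spec`.
#' @param balance an `mw_balance_config`.
#' @param model an `mw_model_spec`.
#' @param mode evaluation mode: `"across"` (leave-one-subject-out),
#'   `"within"` (per-subject 5-fold), or `"both"`.
#' @param normalization normalization mode for across-subject evaluation
#'   (see [person_independent_eval()]).
#' @param k_folds folds for within-subject evaluation.
#' @param ablate also run the single-feature ablation.
#' @param stats also run the univariate ANOVA / t-test stage.
#' @param write_epoch_arrays write per-subject epoch containers (large).
#' @return an object of class `mw_run_config`.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(),
                       features = feature_spec(),
                       balance = balance_config(),
                       model = model_spec(),
                       mode = c("across", "within", "both"),
                       normalization = "per_subject",
                       k_folds = 5L,
                       ablate = FALSE,
                       stats = TRUE,
                       write_epoch_arrays = FALSE) {
  mode <- match.arg(mode)
  structure(list(seed = as.integer(seed), generator = generator,
                 features = features, balance = balance, model = model,
                 mode = mode, normalization = normalization,
                 k_folds = as.integer(k_folds), ablate = ablate,
                 stats = stats, write_epoch_arrays = write_epoch_arrays),
            class = "mw_run_config")
}

#' Run the full pipeline
#'
#' simulate -> extract features -> normalize -> evaluate (and optionally
#' univariate stats and single-feature ablation), writing every stage's
#' outputs under `out_dir`: per-subject event tables (and epoch containers
#' if requested), `features.csv`, `results.json` and `stats.txt`. The log
#' records seeds, subject exclusions and dropped blocks. Identical configs
#' produce identical artifacts.
#'
#' @param config an `mw_run_config`.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results
#'   (`cohort`, `features`, `evaluation`, `stats`, `ablation`).
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say("[simulate] cohort of %d subjects (seed %d)",
      config$generator$n_subjects, seed)
  cohort <- generate_cohort(config$generator, seed = derive_seed(seed, 1))

  for (s in cohort) {
    write_events(s, file.path(out_dir, paste0(s$subject_id, "_events.tsv")))
    if (isTRUE(config$write_epoch_arrays))
      write_epochs(s, file.path(out_dir, paste0(s$subject_id, "_epochs")))
  }

  say("[features] extracting block-level ERP features")
  feats <- cohort_features(cohort, config$features)
  write_features(feats, file.path(out_dir, "features.csv"))

  results <- list(config = serialize_config(config))
  if (config$mode %in% c("across", "both")) {
    say("[evaluate] leave-one-subject-out (person-independent)")
    r <- person_independent_eval(feats, config$model, config$balance,
                                 seed = derive_seed(seed, 3),
                                 normalization = config$normalization)
    results$across <- summarize_cohort_result(r)
  }
  if (config$mode %in% c("within", "both")) {
    say("[evaluate] %d-fold within-subject (person-dependent)", config$k_folds)
    feats_n <- normalize_features(feats)
    r <- person_dependent_cohort(feats_n, config$model, config$k_folds,
                                 config$balance,
                                 seed = derive_seed(seed, 4))
    results$within <- summarize_cohort_result(r)
  }
  ablation <- NULL
  if (isTRUE(config$ablate)) {
    say("[evaluate] single-feature ablation")
    ablation <- feature_ablation(feats, config$model,
                                 balance = config$balance,
                                 seed = derive_seed(seed, 5),
                                 normalization = config$normalization)
    results$ablation <- ablation
  }
  stats_out <- NULL
  if (isTRUE(config$stats)) {
    say("[stats] univariate ANOVA and paired t-tests")
    stats_out <- univariate_summary(cohort, config$features)
    writeLines(stats_out$text, file.path(out_dir, "stats.txt"))
    results$stats <- stats_out$table
  }
  write_results(results, file.path(out_dir, "results.json"))
  say("[done] artifacts in %s", out_dir)
  invisible(list(cohort = cohort, features = feats, evaluation = results,
                 stats = stats_out, ablation = ablation))
}

summarize_cohort_result <- function(r) {
  pooled_cm <- Reduce(function(acc, rep_) Map(`+`, acc, rep_$confusion),
                      r$reports[-1], r$reports[[1]]$confusion)
  list(per_subject = r$per_subject, aggregate = r$aggregate,
       dispersion_type = r$dispersion_type, excluded = r$excluded,
       confusion_normalized =
         as.data.frame(normalize_confusion(pooled_cm)))
}

univariate_summary <- function(cohort, spec) {
  cells <- cell_means_table(cohort, spec)
  rows <- lapply(c(n1 = "n1", p3 = "p3"), function(v) {
    a <- anova_2x2(cells, v)
    data.frame(component = toupper(v),
               F_attention = a$F_attention, p_attention = a$p_attention,
               F_tone = a$F_tone, p_tone = a$p_tone,
               F_interaction = a$F_interaction,
               p_interaction = a$p_interaction,
               df1 = a$df1, df2 = a$df2)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rt <- tryCatch(rt_attention_test(cohort), error = function(e) NULL)
  txt <- c("Univariate 2x2 attention x tone ANOVA on ERP cell means",
           utils::capture.output(print(format(tab, digits = 3))))
  if (!is.null(rt))
    txt <- c(txt, "",
             sprintf("Reaction time: on task %.0f ms vs mind wandering %.0f ms, t(%d) = %.2f, p = %.3f",
                     rt$mean_on_task, rt$mean_mind_wandering, rt$df, rt$t, rt$p))
  list(table = tab, cells = cells, rt = rt, text = txt)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Read / write a run configuration as YAML
#'
#' The file mirrors the [run_config()] sections (`generator`, `features`,
#' `balance`, `model`, plus top-level `seed`, `mode`, `normalization`,
#' `k_folds`, `ablate`, `stats`); omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return an `mw_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(section, ctor) {
    args <- y[[section]] %||% list()
    if (section == "features" && !is.null(args$n1)) {
      # accept a serialized feature spec as well as constructor arguments
      args <- list(filter_band_hz = args$filter_band_hz,
                   baseline_window_ms = args$baseline_window_ms,
                   n1_window_ms = args$n1$window_ms,
                   n1_channels = args$n1$channels,
                   p3_window_ms = args$p3$window_ms,
                   p3_channels = args$p3$channels,
                   trials_per_block = args$trials_per_block,
                   min_trials = args$min_trials)
    }
    args <- lapply(args, function(a)
      if (is.list(a) && all(vapply(a, is.atomic, TRUE))) unlist(a) else a)
    do.call(ctor, args[!vapply(args, is.null, TRUE)])
  }
  run_config(
    seed = y$seed %||% 1L,
    generator = pick("generator", generator_config),
    features = pick("features", feature_spec),
    balance = pick("balance", balance_config),
    model = pick("model", model_spec),
    mode = y$mode %||% "across",
    normalization = y$normalization %||% "per_subject",
    k_folds = y$k_folds %||% 5L,
    ablate = y$ablate %||% FALSE,
    stats = y$stats %||% TRUE,
    write_epoch_arrays = y$write_epoch_arrays %||% FALSE)
}

#' @rdname read_run_config
#' @param config an `mw_run_config` to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path)
  invisible(path)
}
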