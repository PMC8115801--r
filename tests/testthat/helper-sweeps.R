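# Cohort-level Monte-Carlo sweeps shared by the acceptance tests; results
# are cached so the null arm is computed once and reused.

.sweep_cache <- new.env(parent = emptyenv())

loso_sweep <- function(mw_attenuation, seeds, families = c("svm", "logreg"),
                       templates_fn = NULL) {
  key <- paste0("att", mw_attenuation, "_", length(seeds), "_",
                paste(families, collapse = ""))
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  cfg <- generator_config(mw_attenuation = mw_attenuation, render = "preprobe")
  tpl <- if (is.null(templates_fn)) default_templates(cfg) else templates_fn(cfg)
  per_seed <- lapply(seeds, function(sd) {
    f <- simulate_features(cfg, seed = sd, templates = tpl)
    vapply(families, function(fam) {
      # training-cohort normalization: the held-out subject's labels are
      # never used, so a null generator must sit at chance
      r <- suppressMessages(suppressWarnings(
        person_independent_eval(f, model_spec(fam),
                                seed = derive_seed(sd, 99),
                                normalization = "training")))
      c(auc = r$aggregate$mean[r$aggregate$metric == "auc"],
        mcc = r$aggregate$mean[r$aggregate$metric == "mcc"])
    }, c(auc = 0, mcc = 0))
  })
  arr <- simplify2array(per_seed)          # metric x family x seed
  out <- apply(arr, 1:2, mean)
  .sweep_cache[[key]] <- out
  out
}

null_seeds <- function() 1000 * (1:20) + 7
arm_seeds <- function() 1000 * (1:8) + 7
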