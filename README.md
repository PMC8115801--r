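# mindwandr

Detection of mind wandering from ERP features in oddball-task EEG — a
simulation and analysis pipeline in R.

## What problem this solves

Mind wandering (attention drifting from an external task to internal
thought) has no reliable overt behavioral marker; it is usually measured by
interrupting participants with thought probes ("on task" or
"mind wandering?"). EEG offers a way to detect it unobtrusively: in an
auditory oddball task, the stimulus-evoked **N1** (negative, ~100 ms,
fronto-central) and **P3** (positive, ~400–600 ms, parietal) components are
attenuated when attention turns inward.

`mindwandr` implements the full detection pipeline for researchers working
on covert attention-state decoding:

1. **Simulation** — cohorts of oddball sessions (1500 tones, 0.8/0.2
   standard/target, 25 thought-probe blocks, 512 Hz epochs of −1000 to
   +2000 ms) with attention-state-dependent N1/P3 Gaussian components,
   1/f + white noise, artifact flags, and per-subject mind-wandering rates
   drawn from a truncated Beta (mean 0.55, range 0.20–0.88).
2. **ERP features** — per block, the last ≤10 clean pre-probe standard-tone
   trials are band-passed (1–15 Hz, zero-phase), baselined (−200–0 ms), and
   reduced to four features: mean and SD of the per-trial N1 minimum
   (80–120 ms, FC1/FCz/FC2) and P3 maximum (400–600 ms, P1/Pz/P2).
3. **Balancing** — SMOTE oversampling of the minority attention state
   (synthetic rows are convex combinations of minority nearest neighbors),
   with exclusion of subjects reporting fewer than 5 minority blocks.
4. **Classification & evaluation** — RBF-kernel SVM and logistic
   regression; person-dependent 5-fold CV (SMOTE inside training folds,
   pooled test predictions) and person-independent leave-one-subject-out
   evaluation; accuracy, AUC (rank/pair counting), MCC, per-actual-class
   normalized confusion matrices, and single-feature ablation.
5. **Univariate statistics** — 2×2 attention × tone fixed-effects ANOVA on
   per-subject cell means (error df 4n − 4), post-hoc paired t-tests, and
   the behavioral reaction-time contrast.

The methods vignette (`vignettes/mindwandr-methods.Rmd`) documents the
signal model, every default, and the design decisions — including the
filter's amplitude transfer on the templates and a label-leakage analysis
of per-subject feature normalization under leave-one-subject-out
evaluation.

## Worked example

```r
library(mindwandr)

cfg   <- generator_config(render = "preprobe")   # 14-subject oddball design
feats <- simulate_features(cfg, seed = 5)        # simulate + block features
head(feats[, c("subject_id", "block", "label", "n1_mean", "p3_mean")], 3)
#>   subject_id block label   n1_mean  p3_mean
#> 1        S01     1     1 -4.818157 5.351633
#> 2        S01     2     1 -3.693080 4.917607
#> 3        S01     3     1 -7.787800 5.798258

person_independent_eval(feats, model_spec("svm"), seed = 1)
#> excluded subject(s) with minority class < 5: S06, S13
#> <mw_cohort_result> 12 subjects (2 excluded), dispersion = sd
#>   accuracy  0.630 (SD = 0.146)
#>   auc       0.694 (SD = 0.114)
#>   mcc       0.306 (SD = 0.231)

feature_ablation(feats, model_spec("svm"), seed = 2)
#>   feature  accuracy       auc        mcc
#> 1 n1_mean 0.6666667 0.6986461 0.35402848
#> 2   n1_sd 0.5166667 0.5185806 0.03251433
#> 3 p3_mean 0.5800000 0.5895477 0.15563500
#> 4   p3_sd 0.5133333 0.5158424 0.01624062
```

Each feature row is one block: `label` is the thought-probe response (0 on
task, 1 mind wandering), `n1_mean` the average filtered N1 peak over that
block's pre-probe standard tones (µV). With the default mind-wandering
attenuation of 0.3, the leave-one-subject-out SVM detects the state well
above chance (mean AUC 0.694 across the 12 retained subjects; two subjects
were excluded for reporting fewer than 5 minority-class blocks, mirroring
the pipeline's exclusion rule). The ablation table ranks features by their
individual LOSO performance.

A full run — events tables, `features.csv`, `results.json`, univariate
stats — from one config object:

```r
run_pipeline(run_config(seed = 1, mode = "both"), "out/")
```

or from the shell via the thin CLI front-end:

```sh
exec/mindwandr run --seed 1 --out out/
exec/mindwandr evaluate --features out/features.csv --mode across --model svm --seed 1 --out res.json
```

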