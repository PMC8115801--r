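---
title: "Detecting mind wandering from ERP features: models, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mind wandering from ERP features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mind wandering — attention drifting from an external task to internal,
task-unrelated thought — leaves no reliable overt behavioral trace, so it is
usually measured by interrupting people with *thought probes* ("were you on
task or mind wandering?"). A long-standing goal is to detect the state
unobtrusively from physiology. Scalp EEG offers a candidate signature:
stimulus-evoked potentials (ERPs) are attenuated when attention is directed
inward. In an auditory oddball task (frequent *standard* tones, rare
*target* tones requiring a button press), the early sensory **N1**
(negative, ~100 ms, fronto-central) and the later cognitive **P3**
(positive, ~400–600 ms, parietal) are both reduced during self-reported mind
wandering.

`mindwandr` implements, end to end, a detection pipeline built on that
observation: simulate (or ingest) epoched oddball EEG with thought-probe
labels, reduce each inter-probe block to four ERP features, balance the two
attention-state classes, and classify — both *person-dependent* (5-fold
cross-validation within a subject's blocks) and *person-independent*
(leave-one-subject-out, LOSO). Because no public dataset accompanies the
design the package emulates, the synthetic generator is a first-class,
tested component: it defines the study conditions under which every claim in
the test suite is evaluated.

## The simulated experiment

One session mirrors the oddball protocol:

* 1500 pure tones — 1200 standards (800 Hz) and 300 targets (1000 Hz),
  probability 0.8/0.2 — 200 ms long, inter-trial interval jittered uniformly
  on 800–1200 ms;
* 25 blocks, each ending in a thought probe answered "on task" or
  "mind wandering"; every trial inherits its block's probe response;
* epochs of 3000 ms (−1000 to +2000 ms around tone onset) at 512 Hz over six
  electrodes (FC1, FCz, FC2, P1, Pz, P2 — the analysis montage; a larger
  montage is a config option);
* per-subject mind-wandering rate drawn from a Beta distribution
  moment-matched to mean 0.55 and SD 0.198, truncated to [0.20, 0.88] by
  rejection. The SD is the reported cohort standard error (5.3%) scaled by
  √14; the truncation bounds are the reported range.

Two tone-sequencing modes exist because the published counts and block
durations are not mutually consistent (1500 tones at ~1.2 s pitch is ~30
minutes, while 25 blocks of 45–75 s is ~25). The default
`tone_mode = "exact"` takes the counts as primary: exactly 60 tones per
block, with block durations then emerging at ≈72 s from the ITI draws —
inside the stated 45–75 s range, though not uniform over it.
`tone_mode = "duration"` instead draws durations uniformly from 45–75 s and
fills them with Bernoulli(0.2) tones, so counts vary.

### Signal model

Each epoch is

\[
x_c(t) \;=\; \sum_{k \in \{N1, P3\}} j_k \, A_k(\text{state},\text{tone})\,
g_{k,c}\, \phi_k(t) \;+\; \varepsilon_c(t),
\]

where \(\phi_k\) is a Gaussian bump (N1: latency 100 ms, width σ = 20 ms,
negative; P3: latency 500 ms, σ = 80 ms, positive; truncated to zero beyond
4σ), \(g_{k,c}\) a per-channel topography gain (N1 loads on the
fronto-central sites, P3 on the parietal ones), \(j_k \sim
\mathcal N(1, 0.1^2)\) a per-trial multiplicative jitter, and \(A_k\) the
amplitude table: on-task standards −5 µV (N1) and 4 µV (P3), targets −7 and
8 µV, with mind-wandering amplitudes equal to on-task amplitudes scaled by
\(1 - a\) for the attenuation factor \(a\) (`mw_attenuation`, default 0.3;
\(a = 0\) is the null generator). Gaussian bumps were chosen because only
measurement windows, not waveform shapes, are specified for these
components; they are smooth, band-limited, and analytically checkable.

The noise \(\varepsilon\) is the sum of a \(1/f\) process (RMS 10 µV,
exponent 1) and white noise (SD 2 µV) — magnitudes typical of single-trial
scalp EEG after standard cleaning. Both parts are synthesized jointly in the
frequency domain: each complex spectral draw with amplitude
\(\sqrt{(10\,\hat g(f))^2 + 2^2}\) yields two independent real traces (its
real and imaginary parts), and a flat spectrum is exactly iid in time, so
the white component is distributionally identical to direct sampling.

Artifacts are modeled as per-trial Bernoulli flags (p = 0.05) with no
waveform corruption — only the downstream exclusion logic consumes them.
Target-tone reaction times are Gaussian with state-dependent means (511 ms
on task, 535 ms mind wandering), trial SD 90 ms and a per-subject offset
(SD 30 ms); they feed only the behavioral t-test.

What the generator does **not** emulate: volume-conducted correlated noise
across channels, eye-blink/muscle artifact waveforms, between-subject ERP
amplitude and latency differences, drifting vigilance, or any acquisition
chain (reference, notch, ICA). Passing tests therefore demonstrate the
*pipeline's* correctness and calibration under controlled conditions, not
performance on real recordings. The absence of between-subject amplitude
variation matters for one conclusion in particular (see *Normalization and
leakage*).

`render = "preprobe"` synthesizes waveforms only for the trials that
pre-probe selection will return; every label, tone, onset and artifact flag
is still drawn for the full session first, so selection, counts and events
tables are identical to `render = "all"`. Monte-Carlo sweeps use this mode;
the trials it skips are pure noise that no analysis path reads.

## Feature extraction

Per trial, the analysis channels of interest are averaged first (N1:
FC1/FCz/FC2; P3: P1/Pz/P2), then the virtual trace is band-pass filtered at
1–15 Hz, baseline-corrected to the −200–0 ms window mean, and the peak taken
as the window extremum (N1: minimum over 80–120 ms; P3: maximum over
400–600 ms; window endpoints inclusive, times mapped to the nearest
sample). Averaging channels before filtering is an exact reordering of
linear steps, done once per session over all selected trials for speed.

The filter is a zero-phase (two-pass) 4th-order recursive Butterworth
band-pass applied with odd-reflection padding of 512 samples per side; only
the band is prescribed, the realization is the package's choice. The
recursion runs vectorized across traces and matches a reference
forward-backward filter to ~1e−6 on band-limited signals.

A consequence worth stating plainly: this filter does **not** pass the
component templates unchanged. Its amplitude transfer is ≈0.87 for the N1
template and ≈0.59 for P3 — a 1 Hz high-pass inevitably bites into a
monophasic bump as wide as a P3 (σ = 80 ms), a classic source of high-pass
distortion in ERP work. The pipeline is internally consistent (peaks are
measured after filtering, as in the protocol it follows), and all
state *contrasts* scale exactly by \(1 - a\) by linearity, but recovered
absolute amplitudes are the *filtered* template peaks. The noiseless
round-trip tests assert exactly that, against an independent
`signal::filtfilt` oracle.

Per block, up to the **last 10 non-artifact trials before the probe** are
selected, restricted to **standard tones** (targets are too rare in a
10-trial window — about two — for stable estimates), and reduced to four
features: `n1_mean`, `n1_sd`, `p3_mean`, `p3_sd` — the mean and *sample*
standard deviation (n−1; unbiased at these small n) of the per-trial peaks.
Blocks with fewer than two usable standard trials are dropped with a
warning, since a sample SD needs two observations. Per-trial peaks are
taken first and then summarized (not the peak of the average waveform),
reading the block summary as a summary *of trial-level measures*.

## Class balance

Probe responses are imbalanced (55% mind wandering on average, with wide
subject-to-subject spread), so training sets are balanced with SMOTE: each
synthetic minority row is \(x + \gamma (z - x)\) for a real minority row
\(x\), one of its \(k = 5\) (Euclidean) nearest minority neighbors \(z\),
and \(\gamma \sim U(0,1)\); parents cycle deterministically over the
minority rows until the classes are equal, and majority rows are never
touched. If the minority class has fewer than \(k + 1\) members, \(k\) is
reduced with a warning. Subjects with fewer than 5 minority blocks are
excluded outright — too few real rows to interpolate among. SMOTE is
applied strictly inside training folds.

## Classification and evaluation

Two families behind one train/score contract (larger score = more
mind-wandering-like; class prediction at score 0):

* **RBF-kernel SVM** (`e1071`/libsvm), cost C = 1 and
  \(\gamma = 1/(d \cdot \mathrm{Var}(X))\) — the era's library defaults, as
  no tuning grid is reported;
* **logistic regression** by maximum likelihood (`stats::glm`); its score is
  the linear predictor, so the 0 threshold is probability 0.5. At four
  features and ~300 balanced training rows, ridge shrinkage at the common
  default strength is numerically negligible, so the fit is unpenalized.

AUC is computed from the continuous decision values by rank (Mann–Whitney)
pair counting with ties at 0.5; MCC and accuracy from the confusion counts
with mind wandering as the positive class; confusion matrices are also
reported normalized per *actual* class (columns sum to 1).

**Person-dependent:** stratified-where-possible shuffled 5-fold CV over a
subject's ~25 blocks, SMOTE inside each training fold, and metrics computed
once on the test predictions pooled across folds — per-fold AUC over 5 rows
is too unstable to average (fold-wise accuracies are reported alongside).
Cohort aggregation uses the mean and its standard error.

**Person-independent:** leave-one-subject-out; the held-out subject's rows
never meet the training set, SMOTE runs on the pooled training rows of each
iteration, and aggregation uses the mean and standard deviation. Requires
at least 3 retained subjects. Single-feature ablation repeats the LOSO
evaluation once per feature.

### Normalization and leakage

Features are centered per subject and per feature on the subject's own
*on-task* block mean (`normalize_features()`), making subjects comparable
despite idiosyncratic absolute amplitudes. Applied verbatim in LOSO,
however, this uses the held-out subject's probe labels — information a
deployed detector would not have. The package therefore exposes both modes
in `person_independent_eval()`:

* `normalization = "per_subject"` — the published scheme, the pipeline
  default;
* `normalization = "training"` — the per-feature on-task mean is estimated
  from the training subjects only and subtracted from the test rows.

The difference is measurable: under the null generator (no attentional
modulation), the per-subject mode evaluates slightly *above* chance — the
label-dependent centering alone is weakly informative — while the training
mode sits at chance. For that reason the chance-calibration checks in the
test suite and the acceptance script use `"training"`; the per-subject mode
remains the default because it is the published procedure. Note the
caveat cuts the other way on realism: this generator has no between-subject
amplitude differences, which is precisely what per-subject normalization
exists to remove in real data.

## Univariate statistics

The sanity-check analyses on per-subject cell means (per-trial peaks of the
selected pre-probe trials, averaged within each attention × tone cell):

* `anova_2x2()` — two-factor fixed-effects ANOVA with interaction on the
  4n cell means, each effect on 1 df against an error term with 4n − 4 df
  (52 at n = 14). The reported df structure of the design this follows
  matches the fixed-effects layout, not a within-subject error term (which
  would give n − 1 = 13); the df-matching version is therefore primary.
  Degenerate all-equal input yields F = 0 by convention. For the balanced
  layout, each main-effect F equals the squared contrast t computed with
  the pooled MSE — an exact identity the tests verify numerically.
* `paired_t()` / `attention_posthoc()` — paired two-tailed t-tests of the
  attention contrast per tone, df = n − 1.
* `rt_attention_test()` — per-subject mean target reaction times by state,
  compared with a paired t (on-task minus mind-wandering, so slowing under
  mind wandering gives t < 0).

## Numerical and design choices, collected

* Sample count per epoch is `round(3.0 s × 512 Hz)` = 1536; time zero lies
  exactly on a sample; window-to-sample mapping rounds to the nearest
  sample and endpoints are inclusive.
* Filter: Butterworth order 2 (4 poles) designed by `signal::butter`,
  two passes, odd-reflection padding 512 samples; DC and 30 Hz are
  suppressed by >20 dB.
* Fold assignment: rows are shuffled, then each class's members are dealt
  cyclically, so fold sizes differ by at most 1 overall and per class.
* Tie handling: AUC ties count 0.5; MCC is 0 whenever a marginal is empty.
* Seeds: one master seed fans out to per-subject and per-stage child seeds
  (`derive_seed()`), so any stage can be rerun in isolation; identical
  configs reproduce identical artifacts bit for bit.
* Monte-Carlo problem sizes used by the test suite: 20 cohorts for null
  calibration; 8 cohorts per attenuation arm for the dose-response sweep
  (arm separations of ~0.1–0.2 AUC dwarf the ~0.01 across-seed standard
  error); 3 cohorts for the ablation ranking.

## Known limitations

* The generator's realism gaps listed above; in particular, chance-level
  LOSO calibration and effect-recovery results here do not by themselves
  predict real-data performance.
* Absolute recovered amplitudes are filtered-template peaks (see the
  transfer discussion); comparisons across filter settings are not
  meaningful without re-deriving the transfer.
* The SVM's behavior far outside the training hull saturates toward a
  constant score; scores are only meaningful near the data.
* `anova_2x2` implements the df-matching fixed-effects layout; a true
  within-subject (subject-blocked) analysis would need a different error
  term and is intentionally out of scope.
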