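cfg6 <- generator_config()   # default six-channel montage

test_that("band-pass filter is zero-phase and matches the reference filter", {
  t <- epoch_time_axis(cfg6)
  pulse <- bump_trace(1, 500, 100, "Pz", cfg6)
  e <- mindwandr:::new_epoch(pulse, cfg6, "standard")
  ef <- bandpass_filter(e)
  # symmetric pulse keeps its peak latency (+- 1 sample)
  expect_lte(abs(which.max(ef$data["Pz", ]) - which.max(pulse["Pz", ])), 1)
  # agreement with an independent filtfilt oracle
  # the oracle settles its backward pass over a short zero pad, so exact
  # agreement is limited to ~1e-4 near the 1 Hz edge
  x <- sin(2 * pi * 7 * t / 1000) + 0.3 * cos(2 * pi * 2 * t / 1000)
  co <- mindwandr:::butter_coefs(c(1, 15), 512)
  expect_lt(max(abs(as.numeric(filtfilt_mat(co$b, co$a, matrix(x, 1))) -
                      oracle_filtfilt(x))), 1e-3)
  set.seed(4)
  xr <- rnorm(1536)
  expect_lt(max(abs(as.numeric(filtfilt_mat(co$b, co$a, matrix(xr, 1))) -
                      oracle_filtfilt(xr))), 5e-3)
})

test_that("stop-band and DC attenuation reach 20 dB", {
  t <- epoch_time_axis(cfg6)
  atten_db <- function(freq) {
    x <- sin(2 * pi * freq * t / 1000)
    e <- mindwandr:::new_epoch(flat_trace(0, cfg6) + rep(x, each = 6),
                               cfg6, "standard")
    y <- bandpass_filter(e)$data["Pz", ]
    20 * log10(stats::sd(y) / stats::sd(x))
  }
  expect_lt(atten_db(30), -20)
  # constant (DC) input is suppressed to numerical dust
  e <- mindwandr:::new_epoch(flat_trace(3, cfg6), cfg6, "standard")
  y <- bandpass_filter(e)$data["FCz", ]
  expect_lt(stats::sd(y) / 3, 10^(-20 / 20))
  expect_error(bandpass_filter(e, c(15, 1)), "band")
  expect_error(bandpass_filter(e, c(1, 400)), "band")
})

test_that("baseline correction zeroes the pre-stimulus window exactly", {
  e <- mindwandr:::new_epoch(flat_trace(3, cfg6), cfg6, "standard")
  expect_true(all(baseline_correct(e)$data == 0))
  # constant offset 1.5 shifts every sample by -1.5
  d <- flat_trace(0, cfg6); d["Pz", ] <- 1.5 + sin(seq_len(ncol(d)) / 50)
  base <- d["Pz", epoch_time_axis(cfg6) >= -200 & epoch_time_axis(cfg6) <= 0]
  e2 <- baseline_correct(mindwandr:::new_epoch(d, cfg6, "standard"))
  expect_equal(e2$data["Pz", ], d["Pz", ] - mean(base), tolerance = 1e-12)
  # random epoch: post-hoc baseline mean < 1e-10
  set.seed(8)
  er <- mindwandr:::new_epoch(flat_trace(0, cfg6) + rnorm(6 * 1536), cfg6,
                              "standard")
  eb <- baseline_correct(er)
  idx <- mindwandr:::window_sample_index(eb$time_ms, c(-200, 0), 512)
  expect_true(all(abs(rowMeans(eb$data[, idx])) < 1e-10))
  expect_error(baseline_correct(er, c(-2000, 0)), "window")
})

test_that("peak extraction averages channels first, then takes the extremum", {
  e0 <- mindwandr:::new_epoch(flat_trace(0, cfg6), cfg6, "standard")
  expect_equal(extract_peak(e0, c("P1", "Pz", "P2"), c(400, 600), "positive"), 0)
  en <- mindwandr:::new_epoch(bump_trace(-5, 100, 20, "FC1", cfg6), cfg6,
                              "standard")
  # single loaded channel diluted by the two flat ones: -5/3
  expect_equal(extract_peak(en, c("FC1", "FCz", "FC2"), c(80, 120), "negative"),
               -5 / 3, tolerance = 1e-3)
  d <- flat_trace(0, cfg6); d["P1", ] <- 2; d["Pz", ] <- 4
  e2 <- mindwandr:::new_epoch(d, cfg6, "standard")
  expect_equal(extract_peak(e2, c("P1", "Pz"), c(400, 600), "positive"), 3)
  expect_error(extract_peak(e2, "Oz", c(400, 600), "positive"), "missing channel")
})

test_that("peak extraction equals a brute-force window scan", {
  set.seed(15)
  spec <- feature_spec()
  t <- epoch_time_axis(cfg6)
  for (i in 1:50) {
    d <- flat_trace(0, cfg6) + rnorm(6 * 1536)
    e <- mindwandr:::new_epoch(d, cfg6, "standard")
    trace <- colMeans(d[spec$n1$channels, ])
    expect_identical(
      extract_peak(e, spec$n1$channels, spec$n1$window_ms, "negative"),
      min(trace[t >= 80 & t <= 120]))
    tracep <- colMeans(d[spec$p3$channels, ])
    expect_identical(
      extract_peak(e, spec$p3$channels, spec$p3$window_ms, "positive"),
      max(tracep[t >= 400 & t <= 600]))
  }
})

test_that("pre-probe selection takes the last clean trials in order", {
  mk <- function(n, artifact) {
    make_block(replicate(n, flat_trace(0, cfg6), simplify = FALSE),
               rep("standard", n), artifact = artifact)
  }
  b <- mk(40, rep(FALSE, 40))
  sel <- select_preprobe_trials(b)
  expect_equal(vapply(sel, `[[`, 0L, "trial_index"), 31:40)
  # last three artifactual: ten clean ones counting backwards are 28..37
  art <- rep(FALSE, 40); art[38:40] <- TRUE
  sel2 <- select_preprobe_trials(mk(40, art))
  expect_equal(vapply(sel2, `[[`, 0L, "trial_index"), 28:37)
  # fewer clean trials than requested: all returned ("up to" semantics)
  art3 <- rep(TRUE, 10); art3[c(2, 4, 6, 8, 9, 10)] <- FALSE
  sel3 <- select_preprobe_trials(mk(10, art3))
  expect_equal(vapply(sel3, `[[`, 0L, "trial_index"), c(2, 4, 6, 8, 9, 10))
})

test_that("block features take per-trial peaks through the filter chain", {
  spec <- feature_spec()
  # ten identical trials: SD exactly zero, mean equals the independent
  # oracle (filter + baseline + window scan on the averaged channels)
  tr <- bump_trace(-3, 100, 20, spec$n1$channels, cfg6)
  b <- make_block(replicate(10, tr, simplify = FALSE), rep("standard", 10))
  f <- block_features(b, spec, subject_id = "X")
  t <- epoch_time_axis(cfg6)
  orc <- oracle_filtfilt(colMeans(tr[spec$n1$channels, ]))
  orc <- orc - mean(orc[t >= -200 & t <= 0])
  expect_equal(f$n1_mean, min(orc[t >= 80 & t <= 120]), tolerance = 1e-6)
  expect_equal(f$n1_sd, 0)
  expect_equal(f$n_trials_used, 10)
  expect_equal(f$label, 0)
  # per-trial P3 peaks in ratio 1:2:3 keep mean/sd = 2 after any linear
  # filter, up to the common gain g: sd/|mean| = (1/2) * sd({1,2,3})/2
  trs <- lapply(c(1, 2, 3), function(a)
    bump_trace(a, 500, 80, spec$p3$channels, cfg6))
  b3 <- make_block(trs, rep("standard", 3))
  f3 <- block_features(b3, spec)
  expect_equal(f3$p3_sd / f3$p3_mean, stats::sd(c(1, 2, 3)) / 2,
               tolerance = 1e-9)
  # 2 targets + 8 standards -> 8 trials used
  b10 <- make_block(replicate(10, tr, simplify = FALSE),
                    c("target", rep("standard", 8), "target"))
  expect_equal(block_features(b10, spec)$n_trials_used, 8)
  # < 2 usable standard trials: dropped with a warning
  b1 <- make_block(list(tr, tr), c("standard", "target"))
  expect_warning(out <- block_features(b1, spec), "dropped")
  expect_null(out)
})

test_that("mind-wandering blocks are labeled 1", {
  tr <- bump_trace(2, 500, 80, c("P1", "Pz", "P2"), cfg6)
  b <- make_block(replicate(3, tr, simplify = FALSE), rep("standard", 3),
                  probe = "mind_wandering")
  expect_equal(block_features(b, feature_spec())$label, 1)
})

test_that("session_features agrees with per-block computation", {
  s <- generate_subject(quick_config(), "S01", seed = 77)
  fs <- session_features(s)
  for (b in c(1, 7, 25)) {
    fb <- block_features(s$blocks[[b]], feature_spec(), subject_id = "S01")
    row <- fs[fs$block == b, ]
    expect_equal(row$n1_mean, fb$n1_mean, tolerance = 1e-9)
    expect_equal(row$p3_sd, fb$p3_sd, tolerance = 1e-9)
    expect_equal(row$n_trials_used, fb$n_trials_used)
  }
})

test_that("noiseless cohorts recover the filtered template amplitudes", {
  cfg <- noiseless_config(n_subjects = 2L, mw_rate_mean = 0.5,
                          mw_rate_sd = 0.15, mw_rate_range = c(0.3, 0.7))
  feats <- simulate_features(cfg, seed = 13)
  expect_equal(nrow(feats), 50)          # 25 blocks per subject, none dropped
  # oracle: pure standard-tone template through the same filter chain
  spec <- feature_spec()
  t <- epoch_time_axis(cfg)
  tpl <- default_templates(cfg)
  fc_trace <- 1.0 * erp_waveform(tpl$n1, "on_task", "standard", t) +
    0.3 * erp_waveform(tpl$p3, "on_task", "standard", t)
  orc <- oracle_filtfilt(fc_trace)
  orc <- orc - mean(orc[t >= -200 & t <= 0])
  n1_expect <- min(orc[t >= 80 & t <= 120])
  on <- feats$label == 0
  expect_equal(unique(round(feats$n1_mean[on], 9)), round(n1_expect, 9),
               tolerance = 5e-3)
  expect_true(all(feats$n1_sd < 1e-6))
  expect_true(all(feats$p3_sd < 1e-6))
  # attenuation carries through the linear chain exactly
  if (any(!on))
    expect_equal(mean(feats$n1_mean[!on]) / mean(feats$n1_mean[on]),
                 1 - cfg$mw_attenuation, tolerance = 1e-6)
})

test_that("per-subject normalization zeroes on-task means and is idempotent", {
  tab <- data.frame(subject_id = rep(c("A", "B"), each = 3),
                    block = rep(1:3, 2), label = c(0, 0, 1, 0, 0, 1),
                    n1_mean = c(1, 3, 4, 0, 2, 5), n1_sd = 1,
                    p3_mean = c(2, 2, 2, 1, 1, 1), p3_sd = 0,
                    n_trials_used = 8L, normalized = 0L)
  nz <- normalize_features(tab)
  expect_equal(nz$n1_mean[1:3], c(-1, 1, 2))    # on-task mean was 2
  expect_equal(nz$n1_mean[4:6], c(-1, 1, 4))
  expect_true(all(abs(tapply(nz$p3_mean[nz$label == 0],
                             nz$subject_id[nz$label == 0], mean)) < 1e-12))
  expect_identical(normalize_features(nz)[, 4:7], nz[, 4:7])
  expect_equal(unique(nz$normalized), 1L)
  # all-identical rows collapse to zero
  tab2 <- tab; tab2$n1_mean <- 7
  expect_true(all(normalize_features(tab2)$n1_mean == 0))
  # a subject without on-task blocks is an error naming the subject
  tab3 <- tab; tab3$label[tab3$subject_id == "B"] <- 1
  expect_error(normalize_features(tab3), "B")
})

test_that("artifact-free default sessions yield 25 rows per subject", {
  cfg <- quick_config(n_subjects = 2L, artifact_probability = 0)
  feats <- simulate_features(cfg, seed = 3)
  expect_equal(as.vector(table(feats$subject_id)), c(25L, 25L))
  expect_true(all(feats$n_trials_used >= 2 & feats$n_trials_used <= 10))
  expect_true(all(feats$n1_sd >= 0 & feats$p3_sd >= 0))
})
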