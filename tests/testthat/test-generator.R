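test_that("exact-proportion tone sequences match the design counts", {
  seq1 <- generate_tone_sequence(seed = 11)
  expect_equal(nrow(seq1), 1500)
  expect_equal(sum(seq1$tone_type == "standard"), 1200)
  expect_equal(sum(seq1$tone_type == "target"), 300)
  expect_true(all(diff(seq1$onset_s) > 0))
  # gap = tone duration (200 ms) + ITI draw in [800, 1200] ms
  gaps <- diff(seq1$onset_s)
  expect_true(all(gaps >= 1.0 - 1e-9 & gaps <= 1.4 + 1e-9))
})

test_that("degenerate target probability yields all standards", {
  cfg <- generator_config(tone_probabilities = c(standard = 1, target = 0))
  s <- generate_tone_sequence(cfg, mode = "bernoulli", n_tones = 200, seed = 1)
  expect_true(all(s$tone_type == "standard"))
  expect_error(generate_tone_sequence(n_tones = 0), "positive")
})

test_that("bernoulli tone draws match their probability", {
  # binomial CI oracle: 20 seeds x 10000 draws, sd of fraction = 0.004
  fr <- vapply(1:20, function(k) {
    s <- generate_tone_sequence(mode = "bernoulli", n_tones = 10000, seed = k)
    mean(s$tone_type == "target")
  }, 0)
  expect_true(all(abs(fr - 0.2) < 0.02))
})

test_that("erp_waveform renders the configured Gaussian analytically", {
  t <- epoch_time_axis(generator_config())
  tpl <- default_templates()$n1
  w <- erp_waveform(tpl, "on_task", "standard", t)
  expect_equal(min(w), -5, tolerance = 1e-3)       # nearest-sample grid
  expect_equal(t[which.min(w)], 100, tolerance = 1 / 0.512)
  # value one width from the latency is amp * exp(-1/2); evaluate the
  # analytic Gaussian at the same sampled time points
  p3 <- component_template("P3", 500, 80, "positive",
                           c(Pz = 1), matrix(6, 2, 2))
  wp <- erp_waveform(p3, "on_task", "standard", t)
  at <- function(ms) wp[which.min(abs(t - ms))]
  t580 <- t[which.min(abs(t - 580))]; t420 <- t[which.min(abs(t - 420))]
  expect_equal(at(580), 6 * exp(-0.5 * ((t580 - 500) / 80)^2))
  expect_equal(at(420), 6 * exp(-0.5 * ((t420 - 500) / 80)^2))
  # identically zero beyond four widths
  expect_true(all(wp[abs(t - 500) > 4 * 80] == 0))
  # zero amplitude -> flat
  z <- component_template("P3", 500, 80, "positive", c(Pz = 1),
                          matrix(0, 2, 2))
  expect_true(all(erp_waveform(z, "on_task", "target", t) == 0))
  expect_error(erp_waveform(component_template("X", 5000, 20, "negative",
                                               c(Pz = 1), matrix(-1, 2, 2)),
                            "on_task", "standard", t), "latency")
})

test_that("template amplitude signs must match polarity", {
  expect_error(component_template("N1", 100, 20, "negative", c(FCz = 1),
                                  matrix(5, 2, 2)), "polarity")
  expect_error(default_templates(mw_attenuation = 1.2), "\\[0, 1\\]")
})

test_that("noiseless epochs reproduce the deterministic template mix", {
  cfg <- noiseless_config()
  e <- simulate_epoch("on_task", "standard", config = cfg, seed = 1)
  expect_s3_class(e, "mw_epoch")
  expect_equal(dim(e$data), c(6, 1536))
  t <- e$time_ms
  win <- t >= 80 & t <= 120
  expect_equal(min(e$data["FCz", win]), -5, tolerance = 1e-3)
  expect_equal(max(e$data["Pz", t >= 400 & t <= 600]), 4, tolerance = 1e-6)
  # mind wandering attenuates amplitudes by the configured factor
  em <- simulate_epoch("mind_wandering", "standard", config = cfg, seed = 2)
  expect_equal(min(em$data["FCz", win]), -5 * (1 - cfg$mw_attenuation),
               tolerance = 1e-3)
  # artifact probability 1 flags every epoch
  cfg1 <- noiseless_config(artifact_probability = 1)
  expect_true(simulate_epoch("on_task", "target", config = cfg1, seed = 3)$artifact)
})

test_that("pure-noise epochs average to zero by the CLT", {
  cfg <- generator_config(noise_white_sd = 1, noise_pink_sd = 0,
                          trial_amplitude_jitter = 0, channels = "FCz")
  zero_tpl <- lapply(default_templates(cfg), function(tpl) {
    tpl$amplitude_uv[] <- 0; tpl
  })
  set.seed(21)
  r <- mindwandr:::render_epochs(rep("on_task", 1000), rep("standard", 1000),
                                 zero_tpl, cfg)
  m <- rowMeans(r$data)                 # per-sample mean over 1000 epochs
  expect_true(mean(abs(m) < 0.1) > 0.995)  # 3.2 sigma at sd 1/sqrt(1000)
  expect_true(all(abs(m) < 0.15))
  expect_lt(abs(mean(m)), 0.01)
})

test_that("subject sessions follow the block/probe design", {
  cfg <- generator_config(render = "preprobe")
  s <- generate_subject(cfg, "S01", seed = 42)
  expect_equal(length(s$blocks), 25)
  probes <- vapply(s$blocks, `[[`, "", "probe_response")
  expect_true(all(probes %in% c("on_task", "mind_wandering")))
  expect_true(all(vapply(s$blocks, function(b) length(b$duration_s), 0L) == 1))
  expect_true(s$mw_rate >= 0.20 && s$mw_rate <= 0.88)
  # every rendered trial carries its block's probe state implicitly through
  # the block structure; tone bookkeeping is complete
  expect_equal(sum(vapply(s$blocks, function(b) length(b$tone_type), 0L)), 1500)
  # duration mode: block lengths drawn from the configured range
  cfgd <- generator_config(tone_mode = "duration", render = "preprobe")
  sd_ <- generate_subject(cfgd, "S02", seed = 7)
  dur <- vapply(sd_$blocks, `[[`, 0, "duration_s")
  expect_true(all(dur >= 45 & dur <= 75))
})

test_that("degenerate mind-wandering range forces every probe", {
  cfg <- generator_config(mw_rate_mean = 1, mw_rate_range = c(1, 1),
                          render = "preprobe")
  s <- generate_subject(cfg, "S01", seed = 5)
  expect_true(all(vapply(s$blocks, `[[`, "", "probe_response") ==
                    "mind_wandering"))
})

test_that("subject mind-wandering rates match the cohort distribution", {
  rates <- rmw_rate(2000, seed = 99)
  expect_true(all(rates >= 0.20 & rates <= 0.88))
  expect_lt(abs(mean(rates) - 0.55), 0.05)   # Monte-Carlo oracle
})

test_that("cohorts are seed-deterministic and streaming extraction matches", {
  cfg <- quick_config(n_subjects = 2L)
  f1 <- simulate_features(cfg, seed = 31)
  f2 <- simulate_features(cfg, seed = 31)
  expect_identical(f1, f2)
  co <- generate_cohort(cfg, seed = 31)
  expect_equal(length(co), 2)
  expect_identical(cohort_features(co), f1)
})
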