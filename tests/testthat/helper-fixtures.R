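# Shared fixtures, built in code.

# Small, fast generator: fewer subjects/blocks than the study design where
# the test is about mechanics rather than the published geometry.
quick_config <- function(...) {
  args <- list(n_subjects = 4L, render = "preprobe",
               mw_rate_range = c(0.3, 0.7), mw_rate_sd = 0.1,
               mw_rate_mean = 0.5)
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}

noiseless_config <- function(...) {
  args <- list(noise_white_sd = 0, noise_pink_sd = 0,
               trial_amplitude_jitter = 0, artifact_probability = 0,
               render = "preprobe")
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}

# Hand-built block containing crafted epochs, bypassing the generator.
# `traces` is a list of channels x samples matrices (one per trial).
make_block <- function(traces, tones, artifact = NULL, probe = "on_task",
                       config = generator_config()) {
  n <- length(traces)
  artifact <- artifact %||% rep(FALSE, n)
  trials <- lapply(seq_len(n), function(i) {
    e <- mindwandr:::new_epoch(traces[[i]], config, tones[i],
                               block_index = 1L, trial_index = i,
                               artifact = artifact[i])
    e
  })
  list(index = 1L, duration_s = 60, probe_response = probe,
       onsets_s = seq_len(n) - 1, tone_type = tones, artifact = artifact,
       rt_ms = rep(NA_real_, n), trials = trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Constant-amplitude epoch data (channels x samples).
flat_trace <- function(value, config = generator_config()) {
  nt <- length(epoch_time_axis(config))
  matrix(value, length(config$channels), nt,
         dimnames = list(config$channels, NULL))
}

# A Gaussian bump injected on selected channels of an otherwise flat epoch.
bump_trace <- function(amp, latency_ms, width_ms, channels,
                       config = generator_config()) {
  t <- epoch_time_axis(config)
  d <- flat_trace(0, config)
  z <- (t - latency_ms) / width_ms
  d[channels, ] <- rep(amp * exp(-0.5 * z^2), each = length(channels))
  d
}

# Per-subject 2x2 attention x tone cell-means table with a chosen value
# generator (defaults to white noise), for ANOVA checks.
random_cells <- function(n_subjects, seed = NULL, value = stats::rnorm) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                       attention = c("on_task", "mind_wandering"),
                       tone = c("standard", "target"),
                       stringsAsFactors = FALSE)
  cells$n1 <- value(nrow(cells))
  cells
}

# Independent zero-phase filter oracle: signal::filtfilt on a single trace
# with the same odd-reflection padding the package uses.
oracle_filtfilt <- function(x, band = c(1, 15), fs = 512, npad = 512) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  n <- length(x)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  signal::filtfilt(bf, xp)[(npad + 1):(npad + n)]
}
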