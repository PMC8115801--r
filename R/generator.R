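#' Generator configuration for synthetic oddball-task EEG sessions
#'
#' Bundles every tunable of the synthetic-session generator. Defaults
#' reproduce the study design the package emulates: an auditory target
#' detection task with 800 Hz standard and 1000 Hz target tones at
#' probabilities 0.8/0.2 (1500 tones in exact-proportion mode: 1200
#' standard, 300 target), 25 blocks each ending in a thought probe,
#' 800-1200 ms inter-trial jitter, 512 Hz epochs spanning -1000..+2000 ms,
#' and a cohort of 14 subjects who report mind wandering 55% of the time
#' (between-subject range 0.20-0.88).
#'
#' @param n_subjects number of subjects in a cohort.
#' @param n_blocks blocks per session; each ends with one thought probe.
#' @param tone_probabilities named pair `c(standard=, target=)`, must sum
#'   to 1.
#' @param tone_mode `"exact"` fixes the session-wide tone counts at
#'   `total_tones * tone_probabilities` (the published design); `"duration"`
#'   draws block durations uniformly from `block_duration_range_s` and fills
#'   them with Bernoulli tones.
#' @param total_tones session tone count used by exact-proportion mode.
#' @param block_duration_range_s block duration bounds (s) for duration mode.
#' @param iti_range_ms inter-trial-interval jitter bounds (ms).
#' @param tone_duration_ms tone duration (ms).
#' @param sampling_rate_hz sampling rate of the epoched data.
#' @param epoch_window_ms epoch window relative to tone onset (ms); must
#'   span 3000 ms.
#' @param channels montage labels; defaults to the six analysis electrodes.
#' @param mw_rate_mean,mw_rate_sd,mw_rate_range mean, SD and truncation
#'   range of the per-subject mind-wandering rate (Beta, moment-matched,
#'   truncated by rejection). The default SD 0.198 is the reported
#'   standard error of 5.3% scaled by sqrt(14).
#' @param mw_attenuation proportional attenuation of ERP component
#'   amplitudes during mind wandering, in `[0, 1]`; 0 means no attentional
#'   modulation (null generator).
#' @param artifact_probability per-trial probability of an artifact flag.
#' @param noise_white_sd white noise SD per sample (uV).
#' @param noise_pink_sd RMS (uV) of the 1/f^a noise component.
#' @param noise_pink_exponent spectral exponent a of the 1/f^a noise.
#' @param trial_amplitude_jitter SD of the multiplicative Gaussian
#'   amplitude jitter applied per trial and component.
#' @param rt_mean_ms named pair of target-tone reaction time means (ms) by
#'   attention state.
#' @param rt_sd_ms,rt_subject_sd_ms within-subject trial SD and
#'   between-subject offset SD of reaction times (ms).
#' @param render `"all"` synthesizes waveforms for every trial;
#'   `"preprobe"` synthesizes only the trials that pre-probe selection
#'   returns (all labels, tone types, artifact flags and counts are still
#'   drawn for the full session, so selection is unchanged).
#' @param seed default seed used by the generator entry points when none is
#'   passed explicitly.
#' @return an object of class `mw_generator_config` (a validated list).
#' @export
generator_config <- function(n_subjects = 14L,
                             n_blocks = 25L,
                             tone_probabilities = c(standard = 0.8, target = 0.2),
                             tone_mode = c("exact", "duration"),
                             total_tones = 1500L,
                             block_duration_range_s = c(45, 75),
                             iti_range_ms = c(800, 1200),
                             tone_duration_ms = 200,
                             sampling_rate_hz = 512,
                             epoch_window_ms = c(-1000, 2000),
                             channels = c("FC1", "FCz", "FC2", "P1", "Pz", "P2"),
                             mw_rate_mean = 0.55,
                             mw_rate_sd = 0.198,
                             mw_rate_range = c(0.20, 0.88),
                             mw_attenuation = 0.3,
                             artifact_probability = 0.05,
                             noise_white_sd = 2,
                             noise_pink_sd = 10,
                             noise_pink_exponent = 1,
                             trial_amplitude_jitter = 0.1,
                             rt_mean_ms = c(on_task = 511, mind_wandering = 535),
                             rt_sd_ms = 90,
                             rt_subject_sd_ms = 30,
                             render = c("all", "preprobe"),
                             seed = NULL) {
  tone_mode <- match.arg(tone_mode)
  render <- match.arg(render)
  if (is.null(names(tone_probabilities)))
    names(tone_probabilities) <- c("standard", "target")
  if (is.null(names(rt_mean_ms)))
    names(rt_mean_ms) <- c("on_task", "mind_wandering")
  assert_that(n_subjects >= 1 && n_blocks >= 1 && total_tones >= 1,
              "generator", "counts must be positive")
  assert_that(all(tone_probabilities >= 0) && all(tone_probabilities <= 1),
              "generator", "tone probabilities must lie in [0, 1]")
  assert_that(abs(sum(tone_probabilities) - 1) < 1e-12,
              "generator", "tone probabilities must sum to 1")
  assert_that(diff(epoch_window_ms) == 3000,
              "generator", "epoch window must span 3000 ms")
  assert_that(mw_rate_range[1] <= mw_rate_mean && mw_rate_mean <= mw_rate_range[2],
              "generator", "mw_rate_mean must lie inside mw_rate_range")
  assert_that(mw_attenuation >= 0 && mw_attenuation <= 1,
              "generator", "mw_attenuation must lie in [0, 1]")
  assert_that(artifact_probability >= 0 && artifact_probability <= 1,
              "generator", "artifact_probability must lie in [0, 1]")
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
    tone_probabilities = tone_probabilities, tone_mode = tone_mode,
    total_tones = as.integer(total_tones),
    block_duration_range_s = block_duration_range_s,
    iti_range_ms = iti_range_ms, tone_duration_ms = tone_duration_ms,
    sampling_rate_hz = sampling_rate_hz, epoch_window_ms = epoch_window_ms,
    channels = channels,
    mw_rate_mean = mw_rate_mean, mw_rate_sd = mw_rate_sd,
    mw_rate_range = mw_rate_range, mw_attenuation = mw_attenuation,
    artifact_probability = artifact_probability,
    noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
    noise_pink_exponent = noise_pink_exponent,
    trial_amplitude_jitter = trial_amplitude_jitter,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    rt_subject_sd_ms = rt_subject_sd_ms,
    render = render, seed = seed)
  class(cfg) <- "mw_generator_config"
  cfg
}

#' Epoch time axis (ms) for a generator configuration
#'
#' Sample count is `round(duration_s * sampling_rate)`; time zero falls
#' exactly on a sample.
#' @param config a `mw_generator_config`.
#' @return numeric vector of sample times in ms.
#' @export
epoch_time_axis <- function(config) {
  fs <- config$sampling_rate_hz
  n <- round(diff(config$epoch_window_ms) / 1000 * fs)
  (seq_len(n) - 1) / fs * 1000 + config$epoch_window_ms[1]
}

#' Define an ERP component template
#'
#' Components are rendered as Gaussian bumps: amplitude at time t is
#' `amp * exp(-((t - latency)/width)^2 / 2)`, truncated to zero beyond four
#' widths from the latency. `amplitude_uv` is a 2x2 table over attention
#' state (rows `on_task`, `mind_wandering`) and tone type (columns
#' `standard`, `target`); every entry must match the component polarity in
#' sign (zero allowed).
#'
#' @param name component label, e.g. `"N1"`.
#' @param latency_ms,width_ms Gaussian center and SD in ms.
#' @param polarity `"negative"` or `"positive"`.
#' @param topography named per-channel gain vector.
#' @param amplitude_uv 2x2 amplitude table (uV), see Details.
#' @return an object of class `mw_component_template`.
#' @export
component_template <- function(name, latency_ms, width_ms, polarity,
                               topography, amplitude_uv) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  amplitude_uv <- as.matrix(amplitude_uv)
  stopifnot(identical(dim(amplitude_uv), c(2L, 2L)))
  rownames(amplitude_uv) <- c("on_task", "mind_wandering")
  colnames(amplitude_uv) <- c("standard", "target")
  sgn <- if (polarity == "negative") -1 else 1
  assert_that(all(amplitude_uv * sgn >= 0), "generator",
              sprintf("component %s: amplitude sign must match polarity", name))
  structure(list(name = name, latency_ms = latency_ms, width_ms = width_ms,
                 polarity = polarity, topography = topography,
                 amplitude_uv = amplitude_uv),
            class = "mw_component_template")
}

#' Default N1 and P3 component templates
#'
#' N1: negative bump at 100 ms (SD 20 ms) loading on the fronto-central
#' sites; on-task amplitudes -5 uV (standard) and -7 uV (target). P3:
#' positive bump at 500 ms (SD 80 ms) loading on the parietal sites;
#' on-task amplitudes 4 uV (standard) and 8 uV (target). Target amplitudes
#' exceed standard ones in magnitude, and mind-wandering amplitudes are the
#' on-task amplitudes scaled by `1 - mw_attenuation`.
#'
#' @param config a `mw_generator_config` (supplies channels and the
#'   attenuation factor).
#' @param mw_attenuation optional override of the attenuation factor.
#' @return named list with elements `n1` and `p3`.
#' @export
default_templates <- function(config = generator_config(),
                              mw_attenuation = config$mw_attenuation) {
  assert_that(mw_attenuation >= 0 && mw_attenuation <= 1, "generator",
              "mw_attenuation must lie in [0, 1]")
  ch <- config$channels
  fc <- grepl("^FC", ch)
  gain_n1 <- ifelse(fc, 1, 0.2)
  gain_p3 <- ifelse(fc, 0.3, 1)
  names(gain_n1) <- names(gain_p3) <- ch
  amp <- function(on_std, on_tgt) {
    on <- c(on_std, on_tgt)
    rbind(on_task = on, mind_wandering = on * (1 - mw_attenuation))
  }
  list(
    n1 = component_template("N1", latency_ms = 100, width_ms = 20,
                            polarity = "negative", topography = gain_n1,
                            amplitude_uv = amp(-5, -7)),
    p3 = component_template("P3", latency_ms = 500, width_ms = 80,
                            polarity = "positive", topography = gain_p3,
                            amplitude_uv = amp(4, 8)))
}

#' Render one component's single-channel waveform
#'
#' Evaluates the Gaussian template at the configured (state, tone)
#' amplitude on the given time axis; identically zero beyond four widths
#' from the latency.
#'
#' @param template a `mw_component_template`.
#' @param state `"on_task"` or `"mind_wandering"`.
#' @param tone `"standard"` or `"target"`.
#' @param time_ms time axis (ms).
#' @return numeric waveform (uV), same length as `time_ms`.
#' @export
erp_waveform <- function(template, state, tone, time_ms) {
  state <- match.arg(state, c("on_task", "mind_wandering"))
  tone <- match.arg(tone, c("standard", "target"))
  assert_that(template$latency_ms >= min(time_ms) &&
                template$latency_ms <= max(time_ms),
              "generator", "component latency lies outside the epoch window")
  amp <- template$amplitude_uv[state, tone]
  z <- (time_ms - template$latency_ms) / template$width_ms
  w <- amp * exp(-0.5 * z^2)
  w[abs(z) > 4] <- 0
  w
}

#' Draw per-subject mind-wandering rates
#'
#' Beta distribution moment-matched to `mw_rate_mean` / `mw_rate_sd`,
#' truncated to `mw_rate_range` by rejection.
#'
#' @param n number of draws.
#' @param config a `mw_generator_config`.
#' @param seed optional seed.
#' @return numeric vector of rates inside `mw_rate_range`.
#' @export
rmw_rate <- function(n, config = generator_config(), seed = NULL) {
  lo0 <- config$mw_rate_range[1]; hi0 <- config$mw_rate_range[2]
  if (hi0 - lo0 < 1e-12) return(rep(lo0, n))   # degenerate range
  m <- config$mw_rate_mean
  v <- config$mw_rate_sd^2
  ab <- m * (1 - m) / v - 1
  assert_that(ab > 0, "generator", "mw_rate_sd too large for a Beta law")
  shape1 <- m * ab
  shape2 <- (1 - m) * ab
  lo <- config$mw_rate_range[1]; hi <- config$mw_rate_range[2]
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rbeta(max(n, 16L), shape1, shape2)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  })
}

#' Generate a tone sequence with onsets
#'
#' Tones are separated by the tone duration plus a uniform inter-trial
#' interval draw. In `"exact"` mode the session-wide standard/target counts
#' match `total_tones * tone_probabilities` exactly (a random permutation);
#' in `"bernoulli"` mode each tone is an independent draw.
#'
#' @param config a `mw_generator_config`.
#' @param mode `"exact"` or `"bernoulli"`.
#' @param n_tones number of tones (defaults to `config$total_tones`).
#' @param seed optional seed.
#' @return data.frame with columns `tone_type` (factor standard/target) and
#'   `onset_s` (strictly increasing, first onset 0).
#' @export
generate_tone_sequence <- function(config = generator_config(),
                                   mode = c("exact", "bernoulli"),
                                   n_tones = config$total_tones,
                                   seed = NULL) {
  mode <- match.arg(mode)
  assert_that(n_tones >= 1, "generator", "n_tones must be positive")
  p_tgt <- config$tone_probabilities[["target"]]
  with_seed(seed, {
    if (mode == "exact") {
      n_target <- round(n_tones * p_tgt)
      types <- sample(rep(c("standard", "target"),
                          c(n_tones - n_target, n_target)))
    } else {
      types <- ifelse(stats::runif(n_tones) < p_tgt, "target", "standard")
    }
    gaps <- config$tone_duration_ms / 1000 +
      stats::runif(n_tones, config$iti_range_ms[1], config$iti_range_ms[2]) / 1000
    onsets <- cumsum(c(0, gaps[-n_tones]))
    data.frame(tone_type = factor(types, levels = c("standard", "target")),
               onset_s = onsets)
  })
}

# Gaussian noise with spectrum sqrt((pink_sd * f^-a/2)^2 + white_sd^2),
# i.e. the sum of an independent 1/f^a process (RMS pink_sd) and white
# noise (SD white_sd), synthesized directly in the frequency domain: each
# complex spectral draw yields two independent real noise traces (real and
# imaginary parts), and a flat spectrum is exactly iid in time.
# Returns an nt x m matrix.
shaped_noise <- function(nt, m, pink_sd, white_sd, exponent, fs) {
  if (m == 0) return(matrix(0, nt, 0))
  k <- seq_len(nt) - 1
  f <- pmin(k, nt - k) * fs / nt            # two-sided frequency axis
  g <- ifelse(f > 0, f^(-exponent / 2), 0)
  g <- g / sqrt(mean(g^2))                  # unit pink variance (Parseval)
  amp <- sqrt(nt * ((pink_sd * g)^2 + white_sd^2))
  mc <- ceiling(m / 2)
  w <- matrix(complex(real = stats::rnorm(nt * mc),
                      imaginary = stats::rnorm(nt * mc)), nt, mc)
  x <- stats::mvfft(w * amp, inverse = TRUE) / nt
  out <- matrix(0, nt, m)
  out[, seq(1, m, by = 2)] <- Re(x)
  if (m > 1) out[, seq(2, m, by = 2)] <- Im(x[, seq_len(m %/% 2), drop = FALSE])
  out
}

# Synthesize n epochs at once. states/tones are length-n character vectors.
# Returns list(data = nt x (nc*n) matrix, jitter = n x n_components).
render_epochs <- function(states, tones, templates, config) {
  n <- length(states)
  time_ms <- epoch_time_axis(config)
  nt <- length(time_ms)
  nc <- length(config$channels)
  E <- shaped_noise(nt, nc * n, config$noise_pink_sd, config$noise_white_sd,
                    config$noise_pink_exponent, config$sampling_rate_hz)
  jit <- matrix(1, n, length(templates),
                dimnames = list(NULL, names(templates)))
  if (config$trial_amplitude_jitter > 0)
    jit[] <- stats::rnorm(n * length(templates), mean = 1,
                          sd = config$trial_amplitude_jitter)
  for (ci in seq_along(templates)) {
    tpl <- templates[[ci]]
    z <- (time_ms - tpl$latency_ms) / tpl$width_ms
    bump <- exp(-0.5 * z^2)
    bump[abs(z) > 4] <- 0
    amps <- tpl$amplitude_uv[cbind(states, tones)] * jit[, ci]
    gains <- tpl$topography[config$channels]
    # bump (nt) x topography (nc) x per-trial amplitude (n), flattened
    E <- E + bump %o% as.vector(gains %o% amps)
  }
  list(data = E, jitter = jit)
}

#' Simulate a single epoch
#'
#' Signal model: sum over component templates of (amplitude for the
#' attention state and tone) x (per-channel topography gain) x
#' (multiplicative trial jitter), plus 1/f and white noise. The artifact
#' flag is an independent Bernoulli draw at `artifact_probability`.
#'
#' @param state attention state, `"on_task"` or `"mind_wandering"`.
#' @param tone `"standard"` or `"target"`.
#' @param templates component template list (see [default_templates()]).
#' @param config a `mw_generator_config`.
#' @param seed optional seed.
#' @return an object of class `mw_epoch`: channels x samples matrix `data`
#'   (uV), `time_ms`, `tone_type`, `artifact`, sampling rate.
#' @export
simulate_epoch <- function(state, tone, templates = default_templates(config),
                           config = generator_config(), seed = NULL) {
  state <- match.arg(state, c("on_task", "mind_wandering"))
  tone <- match.arg(tone, c("standard", "target"))
  assert_that(all(c("n1", "p3") %in% names(templates)), "generator",
              "templates for N1 and P3 must be present")
  with_seed(seed, {
    r <- render_epochs(state, tone, templates, config)
    artifact <- stats::runif(1) < config$artifact_probability
    new_epoch(t(r$data), config, tone, artifact = artifact)
  })
}

new_epoch <- function(data, config, tone, block_index = NA_integer_,
                      trial_index = NA_integer_, artifact = FALSE) {
  rownames(data) <- config$channels
  structure(list(data = data, time_ms = epoch_time_axis(config),
                 tone_type = tone, block_index = block_index,
                 trial_index = trial_index, artifact = artifact,
                 sampling_rate_hz = config$sampling_rate_hz),
            class = "mw_epoch")
}

#' @export
print.mw_epoch <- function(x, ...) {
  cat(sprintf("<mw_epoch> %s tone, %d channels x %d samples @ %g Hz%s\n",
              x$tone_type, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              if (isTRUE(x$artifact)) " [artifact]" else ""))
  invisible(x)
}

#' Generate one simulated subject session
#'
#' Draws the subject's mind-wandering rate, builds the blocks (tone
#' sequence, inter-trial jitter, per-block thought-probe response drawn
#' Bernoulli at the subject rate, per-trial artifact flags, target-tone
#' reaction times), then synthesizes the epoch waveforms. Every trial
#' carries the probe label of its block.
#'
#' All session metadata are drawn before any waveform, so the two `render`
#' modes agree on labels, tone types, artifact flags and counts for a
#' given seed.
#'
#' @param config a `mw_generator_config`.
#' @param subject_id subject identifier string.
#' @param seed optional seed.
#' @param templates component templates.
#' @return an object of class `mw_session`.
#' @export
generate_subject <- function(config = generator_config(),
                             subject_id = "S01", seed = NULL,
                             templates = default_templates(config)) {
  with_seed(seed, {
    mw_rate <- rmw_rate(1, config)
    rt_offset <- stats::rnorm(1, 0, config$rt_subject_sd_ms)
    nb <- config$n_blocks

    if (config$tone_mode == "exact") {
      counts <- rep(config$total_tones %/% nb, nb)
      extra <- config$total_tones - sum(counts)
      if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
      seq_all <- generate_tone_sequence(config, mode = "exact")
      split_idx <- rep(seq_len(nb), counts)
    }

    blocks <- vector("list", nb)
    for (b in seq_len(nb)) {
      if (config$tone_mode == "exact") {
        types <- as.character(seq_all$tone_type[split_idx == b])
        k <- length(types)
        gaps <- config$tone_duration_ms / 1000 +
          stats::runif(k, config$iti_range_ms[1], config$iti_range_ms[2]) / 1000
        onsets <- cumsum(c(0, gaps[-k]))
        duration <- onsets[k] + gaps[k]
      } else {
        duration <- stats::runif(1, config$block_duration_range_s[1],
                                 config$block_duration_range_s[2])
        onsets <- c(); t_next <- 0
        while (t_next + config$tone_duration_ms / 1000 <= duration) {
          onsets <- c(onsets, t_next)
          t_next <- t_next + config$tone_duration_ms / 1000 +
            stats::runif(1, config$iti_range_ms[1], config$iti_range_ms[2]) / 1000
        }
        k <- length(onsets)
        types <- ifelse(stats::runif(k) < config$tone_probabilities[["target"]],
                        "target", "standard")
      }
      probe <- if (stats::runif(1) < mw_rate) "mind_wandering" else "on_task"
      artifact <- stats::runif(k) < config$artifact_probability
      rt <- rep(NA_real_, k)
      tgt <- which(types == "target")
      if (length(tgt))
        rt[tgt] <- config$rt_mean_ms[[probe]] + rt_offset +
          stats::rnorm(length(tgt), 0, config$rt_sd_ms)
      blocks[[b]] <- list(index = b, duration_s = duration,
                          probe_response = probe, onsets_s = onsets,
                          tone_type = types, artifact = artifact, rt_ms = rt,
                          trials = vector("list", k))
    }

    # waveform synthesis after all metadata draws, batched over the session
    idx_by_block <- lapply(blocks, function(blk) {
      if (config$render == "all") seq_along(blk$tone_type)
      else preprobe_indices(blk$artifact)
    })
    blk_of <- rep(seq_len(nb), lengths(idx_by_block))
    idx_all <- unlist(idx_by_block)
    if (length(idx_all)) {
      states <- vapply(blocks, `[[`, "", "probe_response")[blk_of]
      tones <- mapply(function(b, i) blocks[[b]]$tone_type[i], blk_of, idx_all)
      r <- render_epochs(states, tones, templates, config)
      nc <- length(config$channels)
      for (j in seq_along(idx_all)) {
        b <- blk_of[j]; i <- idx_all[j]
        cols <- ((j - 1) * nc + 1):(j * nc)
        blocks[[b]]$trials[[i]] <-
          new_epoch(t(r$data[, cols, drop = FALSE]), config,
                    blocks[[b]]$tone_type[i], block_index = b,
                    trial_index = i, artifact = blocks[[b]]$artifact[i])
      }
    }

    structure(list(subject_id = subject_id, blocks = blocks,
                   mw_rate = mw_rate, rt_offset_ms = rt_offset,
                   config = config, templates = templates,
                   channels = config$channels,
                   sampling_rate_hz = config$sampling_rate_hz,
                   time_ms = epoch_time_axis(config)),
              class = "mw_session")
  })
}

#' @export
print.mw_session <- function(x, ...) {
  nmw <- sum(vapply(x$blocks, function(b) b$probe_response == "mind_wandering",
                    logical(1)))
  cat(sprintf("<mw_session> %s: %d blocks (%d mind-wandering probes), mw_rate %.2f\n",
              x$subject_id, length(x$blocks), nmw, x$mw_rate))
  invisible(x)
}

#' Generate a cohort of simulated sessions
#'
#' @param config a `mw_generator_config`.
#' @param seed seed; each subject gets a derived child seed, so sessions
#'   are independent and individually reproducible.
#' @param templates component templates shared by all subjects.
#' @return list of `mw_session`, one per subject.
#' @export
generate_cohort <- function(config = generator_config(),
                            seed = config$seed,
                            templates = default_templates(config)) {
  assert_that(config$n_subjects >= 1, "generator", "n_subjects must be >= 1")
  seed <- seed %||% stats::runif(1, 0, 2^31 - 2)
  lapply(seq_len(config$n_subjects), function(i) {
    generate_subject(config, subject_id = sprintf("S%02d", i),
                     seed = derive_seed(seed, i), templates = templates)
  })
}
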