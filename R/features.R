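#' Feature-extraction specification
#'
#' Defines the ERP quantification used throughout: 1-15 Hz zero-phase
#' band-pass, -200..0 ms baseline, N1 = minimum amplitude 80-120 ms
#' post-stimulus averaged over FC1/FCz/FC2, P3 = maximum amplitude
#' 400-600 ms over P1/Pz/P2; per block, the mean and standard deviation of
#' the per-trial peaks over the up-to-10 pre-probe trials, restricted to
#' standard tones for the classifier features.
#'
#' @param filter_band_hz band-pass edges (Hz).
#' @param baseline_window_ms baseline window (ms).
#' @param n1_window_ms,n1_channels N1 search window and channels.
#' @param p3_window_ms,p3_channels P3 search window and channels.
#' @param trials_per_block number of pre-probe trials considered per block.
#' @param min_trials minimum usable standard trials per block; blocks below
#'   this are dropped (the sample SD needs at least 2).
#' @return an object of class `mw_feature_spec`.
#' @export
feature_spec <- function(filter_band_hz = c(1, 15),
                         baseline_window_ms = c(-200, 0),
                         n1_window_ms = c(80, 120),
                         n1_channels = c("FC1", "FCz", "FC2"),
                         p3_window_ms = c(400, 600),
                         p3_channels = c("P1", "Pz", "P2"),
                         trials_per_block = 10L,
                         min_trials = 2L) {
  assert_that(baseline_window_ms[2] <= 0, "features",
              "baseline must precede stimulus onset")
  structure(list(filter_band_hz = filter_band_hz,
                 baseline_window_ms = baseline_window_ms,
                 n1 = list(window_ms = n1_window_ms, channels = n1_channels,
                           polarity = "negative"),
                 p3 = list(window_ms = p3_window_ms, channels = p3_channels,
                           polarity = "positive"),
                 trials_per_block = as.integer(trials_per_block),
                 min_trials = as.integer(min_trials)),
            class = "mw_feature_spec")
}

#' Extract a peak amplitude from an epoch
#'
#' The named channels are averaged into one virtual trace first; the
#' minimum (negative polarity) or maximum (positive polarity) over the
#' window samples of that trace is returned. Window endpoints are
#' inclusive.
#'
#' @param epoch an `mw_epoch` (normally filtered and baseline-corrected).
#' @param channels channel names to average.
#' @param window_ms search window (ms).
#' @param polarity `"negative"` or `"positive"`.
#' @return peak amplitude in uV.
#' @export
extract_peak <- function(epoch, channels, window_ms, polarity) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  missing <- setdiff(channels, rownames(epoch$data))
  assert_that(length(missing) == 0, "features",
              paste("missing channel(s):", paste(missing, collapse = ", ")))
  idx <- window_sample_index(epoch$time_ms, window_ms, epoch$sampling_rate_hz)
  trace <- colMeans(epoch$data[channels, idx, drop = FALSE])
  if (polarity == "negative") min(trace) else max(trace)
}

# Indices of the last up-to-n non-artifact trials, in temporal order.
preprobe_indices <- function(artifact, n = 10L) {
  clean <- which(!artifact)
  if (length(clean) > n) clean <- clean[(length(clean) - n + 1):length(clean)]
  clean
}

#' Select the pre-probe trials of a block
#'
#' Returns the last up-to-n non-artifact trials before the thought probe,
#' in temporal order. May return fewer than `n` when the block does not
#' contain that many clean trials.
#'
#' @param block one block of an `mw_session`.
#' @param n maximum number of trials.
#' @return list of `mw_epoch`.
#' @export
select_preprobe_trials <- function(block, n = 10L) {
  assert_that(length(block$tone_type) > 0, "features", "block is empty")
  block$trials[preprobe_indices(block$artifact, n)]
}

# Peak measurement chain for a set of epochs, batched: channel averaging
# (linear, so it commutes with the filter), one vectorized zero-phase
# filter call over all virtual traces, baseline correction, then the
# window extremum. Returns a data.frame with one row per epoch.
peaks_for_epochs <- function(epochs, spec, fs, time_ms) {
  n <- length(epochs)
  if (n == 0) return(data.frame(n1 = numeric(0), p3 = numeric(0)))
  nt <- length(time_ms)
  V <- matrix(0, 2 * n, nt)
  for (i in seq_len(n)) {
    d <- epochs[[i]]$data
    V[2 * i - 1, ] <- colMeans(d[spec$n1$channels, , drop = FALSE])
    V[2 * i, ] <- colMeans(d[spec$p3$channels, , drop = FALSE])
  }
  co <- butter_coefs(spec$filter_band_hz, fs)
  V <- filtfilt_mat(co$b, co$a, V)
  bidx <- window_sample_index(time_ms, spec$baseline_window_ms, fs)
  V <- V - rowMeans(V[, bidx, drop = FALSE])
  i_n1 <- window_sample_index(time_ms, spec$n1$window_ms, fs)
  i_p3 <- window_sample_index(time_ms, spec$p3$window_ms, fs)
  odd <- seq(1, 2 * n, by = 2)
  data.frame(
    n1 = apply(V[odd, i_n1, drop = FALSE], 1, min),
    p3 = apply(V[odd + 1, i_p3, drop = FALSE], 1, max))
}

#' Block-level ERP features
#'
#' Computes the four classifier features of one block: mean and sample
#' standard deviation (n-1 denominator) of the per-trial N1 and P3 peak
#' amplitudes over the standard-tone trials among the selected pre-probe
#' trials. Trials are filtered and baseline-corrected before peak
#' extraction. Blocks with fewer than `spec$min_trials` usable trials are
#' dropped (returns `NULL` with a warning).
#'
#' @param block one block of an `mw_session`.
#' @param spec an `mw_feature_spec`.
#' @param fs sampling rate (Hz).
#' @param time_ms epoch time axis (ms).
#' @param subject_id subject identifier copied into the row.
#' @return one-row data.frame (`subject_id`, `block`, `label`, `n1_mean`,
#'   `n1_sd`, `p3_mean`, `p3_sd`, `n_trials_used`, `normalized`) or `NULL`.
#' @export
block_features <- function(block, spec = feature_spec(), fs = 512,
                           time_ms = NULL, subject_id = NA_character_) {
  sel <- select_preprobe_trials(block, spec$trials_per_block)
  sel <- Filter(function(e) identical(e$tone_type, "standard") ||
                  identical(as.character(e$tone_type), "standard"), sel)
  if (length(sel) < spec$min_trials) {
    warning(sprintf("block %s: only %d usable standard trial(s); dropped",
                    block$index, length(sel)), call. = FALSE)
    return(NULL)
  }
  if (is.null(time_ms)) time_ms <- sel[[1]]$time_ms
  pk <- peaks_for_epochs(sel, spec, fs, time_ms)
  data.frame(subject_id = subject_id, block = block$index,
             label = as.integer(block$probe_response == "mind_wandering"),
             n1_mean = mean(pk$n1), n1_sd = stats::sd(pk$n1),
             p3_mean = mean(pk$p3), p3_sd = stats::sd(pk$p3),
             n_trials_used = nrow(pk), normalized = 0L)
}

#' Feature table for one session
#'
#' Applies [block_features()] to every block; all selected trials of the
#' session are filtered in a single vectorized pass.
#'
#' @param session an `mw_session`.
#' @param spec an `mw_feature_spec`.
#' @return data.frame with up to one row per block.
#' @export
session_features <- function(session, spec = feature_spec()) {
  fs <- session$sampling_rate_hz
  time_ms <- session$time_ms
  sel_by_block <- lapply(session$blocks, function(blk) {
    sel <- select_preprobe_trials(blk, spec$trials_per_block)
    Filter(function(e) as.character(e$tone_type) == "standard", sel)
  })
  counts <- lengths(sel_by_block)
  keep <- counts >= spec$min_trials
  for (b in which(!keep))
    warning(sprintf("%s block %d: only %d usable standard trial(s); dropped",
                    session$subject_id, b, counts[b]), call. = FALSE)
  pk <- peaks_for_epochs(unlist(sel_by_block[keep], recursive = FALSE),
                         spec, fs, time_ms)
  grp <- rep(which(keep), counts[keep])
  rows <- lapply(which(keep), function(b) {
    p <- pk[grp == b, , drop = FALSE]
    data.frame(subject_id = session$subject_id, block = b,
               label = as.integer(session$blocks[[b]]$probe_response ==
                                    "mind_wandering"),
               n1_mean = mean(p$n1), n1_sd = stats::sd(p$n1),
               p3_mean = mean(p$p3), p3_sd = stats::sd(p$p3),
               n_trials_used = nrow(p), normalized = 0L)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Feature table for a cohort
#'
#' @param cohort list of `mw_session`.
#' @param spec an `mw_feature_spec`.
#' @return row-bound feature table over all subjects.
#' @export
cohort_features <- function(cohort, spec = feature_spec()) {
  do.call(rbind, c(lapply(cohort, session_features, spec = spec),
                   list(make.row.names = FALSE)))
}

#' Simulate a cohort and extract its feature table in one pass
#'
#' Streaming composition of [generate_subject()] and [session_features()]:
#' each subject's epochs are discarded as soon as their block features are
#' extracted, keeping memory flat for Monte-Carlo sweeps over many
#' cohorts. Produces exactly the same table as
#' `cohort_features(generate_cohort(config, seed), spec)`.
#'
#' @param config an `mw_generator_config`.
#' @param spec an `mw_feature_spec`.
#' @param seed cohort seed.
#' @param templates component templates shared by all subjects.
#' @return cohort feature table.
#' @export
simulate_features <- function(config = generator_config(), spec = feature_spec(),
                              seed = config$seed, templates = default_templates(config)) {
  seed <- seed %||% stats::runif(1, 0, 2^31 - 2)
  rows <- lapply(seq_len(config$n_subjects), function(i) {
    s <- generate_subject(config, subject_id = sprintf("S%02d", i),
                          seed = derive_seed(seed, i), templates = templates)
    session_features(s, spec)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-subject on-task-mean normalization
#'
#' For every subject and every feature, subtracts the mean of that
#' subject's on-task blocks from all of the subject's rows, so the on-task
#' mean is zero afterwards and mind-wandering rows are shifted by the same
#' per-feature constant. Idempotent.
#'
#' @param features a feature table (see [block_features()]).
#' @return the normalized table (`normalized` column set to 1).
#' @export
normalize_features <- function(features) {
  cols <- feature_names()
  for (sid in unique(features$subject_id)) {
    rows <- features$subject_id == sid
    on <- rows & features$label == 0
    assert_that(any(on), "features",
                sprintf("subject %s has no on-task blocks to normalize against", sid))
    for (f in cols)
      features[rows, f] <- features[rows, f] - mean(features[on, f])
  }
  features$normalized <- 1L
  features
}

#' The four classifier feature names
#' @return character vector.
#' @export
feature_names <- function() c("n1_mean", "n1_sd", "p3_mean", "p3_sd")

#' Feature table from a stored epochs container
#'
#' Applies the pre-probe selection and block-feature computation to an
#' epochs container read with [read_epochs()] (e.g. exported by another
#' toolchain), reproducing [session_features()] for stored data.
#'
#' @param container list from [read_epochs()].
#' @param spec an `mw_feature_spec`.
#' @return feature data.frame, one row per usable block.
#' @export
epochs_to_features <- function(container, spec = feature_spec()) {
  tr <- container$trials
  fs <- container$sampling_rate_hz
  time_ms <- container$time_ms
  rows <- list()
  for (b in sort(unique(tr$block))) {
    in_b <- which(tr$block == b)
    sel <- in_b[preprobe_indices(tr$artifact[in_b], spec$trials_per_block)]
    sel <- sel[tr$tone_type[sel] == "standard"]
    if (length(sel) < spec$min_trials) {
      warning(sprintf("%s block %d: only %d usable standard trial(s); dropped",
                      container$subject_id, b, length(sel)), call. = FALSE)
      next
    }
    epochs <- lapply(sel, function(i) {
      d <- container$data[i, , , drop = TRUE]
      rownames(d) <- container$channels
      list(data = d, time_ms = time_ms, tone_type = tr$tone_type[i],
           artifact = tr$artifact[i], sampling_rate_hz = fs)
    })
    pk <- peaks_for_epochs(epochs, spec, fs, time_ms)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = container$subject_id, block = b,
      label = tr$label[in_b][1],
      n1_mean = mean(pk$n1), n1_sd = stats::sd(pk$n1),
      p3_mean = mean(pk$p3), p3_sd = stats::sd(pk$p3),
      n_trials_used = nrow(pk), normalized = 0L)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
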