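# Readers and writers for the pipeline's table and array formats.

FEATURE_HEADER <- c("subject_id", "block", "label", "n1_mean", "n1_sd",
                    "p3_mean", "p3_sd", "n_trials_used", "normalized")

#' Write a feature table
#'
#' Comma-separated text with the fixed header `subject_id, block, label,
#' n1_mean, n1_sd, p3_mean, p3_sd, n_trials_used, normalized`. Floating
#' point values are written at full double precision so that
#' write-then-read is the identity.
#'
#' @param features feature table.
#' @param path output file.
#' @export
write_features <- function(features, path) {
  assert_that(all(FEATURE_HEADER %in% names(features)), "io",
              "feature table is missing required columns")
  out <- features[, FEATURE_HEADER]
  for (f in feature_names()) out[[f]] <- sprintf("%.17g", out[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table
#'
#' Validates the header, the label domain (0/1) and that the `normalized`
#' flag is not mixed within the file.
#'
#' @param path csv file written by [write_features()].
#' @return validated feature data.frame.
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(FEATURE_HEADER, names(tab))
  assert_that(length(missing) == 0, "io",
              paste("missing column(s):", paste(missing, collapse = ", ")))
  assert_that(all(tab$label %in% c(0L, 1L)), "io",
              "label values must be 0 (on task) or 1 (mind wandering)")
  assert_that(length(unique(tab$normalized)) <= 1, "io",
              "mixed normalized flags in one table")
  assert_that(all(tab$n1_sd >= 0) && all(tab$p3_sd >= 0), "io",
              "feature SDs must be non-negative")
  tab
}

#' Write a session's event table
#'
#' Tab-separated: `onset_s, duration_s, tone_type, block, probe_response`,
#' one row per tone, onsets relative to block start.
#'
#' @param session an `mw_session`.
#' @param path output file.
#' @export
write_events <- function(session, path) {
  rows <- lapply(session$blocks, function(b) {
    data.frame(onset_s = b$onsets_s,
               duration_s = session$config$tone_duration_ms / 1000,
               tone_type = b$tone_type, block = b$index,
               probe_response = b$probe_response)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a session's epochs as a binary array with a JSON sidecar
#'
#' The `.bin` file holds the rendered epochs as little-endian float64 in
#' trial-major order (trial, then channel, then sample); `.json` records
#' the shape, channel names, sampling rate, time-zero index (1-based) and
#' the per-trial tone/block/artifact/label columns. Unrendered trials
#' (render = "preprobe") are skipped and absent from the sidecar index.
#'
#' @param session an `mw_session`.
#' @param path_prefix output path without extension.
#' @return invisible list of the two file paths.
#' @export
write_epochs <- function(session, path_prefix) {
  eps <- list(); meta <- list()
  for (b in session$blocks) for (e in b$trials) if (!is.null(e)) {
    eps[[length(eps) + 1]] <- e
    meta[[length(meta) + 1]] <- data.frame(
      tone_type = as.character(e$tone_type), block = e$block_index,
      trial = e$trial_index, artifact = e$artifact,
      label = as.integer(b$probe_response == "mind_wandering"))
  }
  meta <- do.call(rbind, meta)
  bin <- paste0(path_prefix, ".bin"); js <- paste0(path_prefix, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  for (e in eps) writeBin(as.vector(t(e$data)), con, size = 8,
                          endian = "little")
  nt <- length(session$time_ms)
  jsonlite::write_json(list(
    subject_id = session$subject_id,
    shape = c(length(eps), length(session$channels), nt),
    order = "trial x channel x sample",
    channels = session$channels,
    sampling_rate_hz = session$sampling_rate_hz,
    time_zero_index = which.min(abs(session$time_ms)),
    trials = meta), js, auto_unbox = TRUE, digits = NA)
  invisible(list(bin = bin, json = js))
}

#' Read an epochs container
#'
#' @param path_prefix path without extension, as given to [write_epochs()].
#' @return list with `data` (trials x channels x samples array), `channels`,
#'   `sampling_rate_hz`, `time_ms` and the per-trial `trials` table.
#' @export
read_epochs <- function(path_prefix) {
  side <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  shp <- as.integer(side$shape)
  raw <- readBin(paste0(path_prefix, ".bin"), what = "double",
                 n = prod(shp), size = 8, endian = "little")
  data <- aperm(array(raw, dim = rev(shp)), 3:1)
  fs <- side$sampling_rate_hz
  time_ms <- (seq_len(shp[3]) - side$time_zero_index) / fs * 1000
  list(data = data, channels = side$channels, sampling_rate_hz = fs,
       time_ms = time_ms, trials = side$trials,
       subject_id = side$subject_id)
}

#' Write / read an evaluation results bundle as JSON
#'
#' @param results a list (config echo, per-subject metrics, aggregates).
#' @param path JSON file.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
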