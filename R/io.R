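## Plain-text serialization of recordings, trial tables and feature tables.

#' Write / read a respiration recording
#'
#' Two-column delimited table `time_s, value`; the sampling rate is recovered
#' from the time axis on read.
#'
#' @param recording a `resp_recording`.
#' @param path file path (.csv).
#' @param session_id session identifier to attach on read.
#' @return `read_recording()` returns a `resp_recording`.
#' @export
write_recording <- function(recording, path) {
  check_recording(recording)
  n <- length(recording$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / recording$sampling_rate,
                   value = recording$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, session_id = basename(path)) {
  if (!file.exists(path)) stopf("cannot read recording: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stopf("%s: expected columns time_s, value", path)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stopf("%s: time axis not strictly increasing", path)
  structure(list(samples = df$value, sampling_rate = 1 / median(dt),
                 session_id = session_id),
            class = "resp_recording")
}

#' Write / read a trial event table
#'
#' Delimited table with header `session_id, trial_index, trial_start_s,
#' fixation_onset_s, go_cue_s, outcome, difficulty`; `go_cue_s` may be empty
#' (false alarms have no go cue).
#'
#' @param trials trial event data.frame.
#' @param path file path (.csv).
#' @export
write_trial_table <- function(trials, path) {
  cols <- c("session_id", "trial_index", "trial_start_s", "fixation_onset_s",
            "go_cue_s", "outcome", "difficulty")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(trials[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stopf("cannot read trial table: %s", path)
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  cols <- c("session_id", "trial_index", "trial_start_s", "fixation_onset_s",
            "go_cue_s", "outcome", "difficulty")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s: missing columns %s", path, paste(missing, collapse = ", "))
  df
}

#' Write a per-session trial feature table
#'
#' Canonical feature names plus `valid`, `outcome`, `difficulty`,
#' `trial_index`, `session_id`, as a delimited table with header.
#'
#' @param features a `trial_features` table.
#' @param path file path (.csv).
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  structure(df, class = c("trial_features", "data.frame"))
}
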