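## Conditioning of the raw respiration trace: bandpass -> notch -> invert ->
## z-score, plus the session spectrogram and trial epoching.

#' Filter configuration for signal conditioning
#'
#' @param band_low,band_high Butterworth passband edges, Hz.
#' @param order Butterworth prototype order.
#' @param notch_freqs numeric vector of notch center frequencies, Hz
#'   (default none; the mains frequency can be supplied here).
#' @param notch_q notch quality factor (bandwidth = freq / q).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(band_low = 0.1, band_high = 0.5, order = 3L,
                          notch_freqs = numeric(0), notch_q = 30) {
  notch_freqs <- as.numeric(unlist(notch_freqs))  # YAML: [] reads as list()
  stopifnot(is_num1(band_low), is_num1(band_high), is_count(order),
            is.numeric(notch_freqs), is_num1(notch_q))
  if (!(band_low > 0 && band_low < band_high))
    stopf("need 0 < band_low < band_high")
  structure(list(band_low = band_low, band_high = band_high,
                 order = as.integer(order), notch_freqs = notch_freqs,
                 notch_q = notch_q),
            class = "filter_config")
}

check_recording <- function(recording) {
  if (!inherits(recording, "resp_recording"))
    stopf("expected a resp_recording")
  if (!all(is.finite(recording$samples)))
    stopf("recording contains non-finite samples")
  if (recording$sampling_rate <= 0) stopf("sampling_rate must be positive")
  invisible(recording)
}

## Reflect-padding length used for zero-phase filtering. The slowest filter
## mode decays with a time constant of a few periods of the low passband
## edge; six periods of padding lets startup transients decay below 1e-6.
bandpass_pad_samples <- function(band_low, fs) as.integer(round(6 * fs / band_low))

#' Zero-phase Butterworth bandpass of a recording
#'
#' Forward-backward filtering (no group delay), with odd-reflection padding at
#' the session boundaries. The effective attenuation is the squared
#' single-pass Butterworth magnitude response.
#'
#' @param recording a `resp_recording` (see [generate_session()] or
#'   [read_recording()]).
#' @param filt a [filter_config()].
#' @return numeric vector, filtered samples (same length as the input).
#' @export
bandpass <- function(recording, filt = filter_config()) {
  check_recording(recording)
  stopifnot(inherits(filt, "filter_config"))
  fs <- recording$sampling_rate
  if (filt$band_high >= fs / 2)
    stopf("band_high (%g Hz) must be below Nyquist (%g Hz)", filt$band_high, fs / 2)
  pad <- bandpass_pad_samples(filt$band_low, fs)
  n <- length(recording$samples)
  if (n < pad + 2L)
    stopf("signal too short for stable filtering: need at least %d samples (%.1f s at %g Hz)",
          pad + 2L, (pad + 2L) / fs, fs)
  sos <- butter_bandpass_sos(filt$order, filt$band_low, filt$band_high, fs)
  sos_filtfilt(recording$samples, sos, pad)
}

#' Apply notch filters to a series
#'
#' Zero-phase narrowband rejection at each listed frequency; identity when the
#' list is empty.
#'
#' @param x numeric series.
#' @param notch_freqs numeric vector of center frequencies, Hz.
#' @param notch_q quality factor.
#' @param fs sampling rate, Hz.
#' @return filtered numeric vector.
#' @export
apply_notch <- function(x, notch_freqs, notch_q, fs) {
  if (length(notch_freqs) == 0L) return(x)
  for (f0 in notch_freqs) {
    sos <- notch_sos(f0, notch_q, fs)
    pad <- as.integer(round(min(length(x) - 1, 20 * fs / f0)))
    x <- sos_filtfilt(x, sos, pad)
  }
  x
}

#' Condition a raw respiration recording
#'
#' Runs the full conditioning pipeline: zero-phase Butterworth bandpass,
#' optional notch filters, polarity inversion (the thermocouple records
#' exhalation as a voltage increase; after inversion rising phases correspond
#' to inhalation), and session-wide z-scoring (so uncalibrated probe placement
#' differences across sessions do not affect amplitude features).
#'
#' @param recording a `resp_recording`.
#' @param filt a [filter_config()].
#' @return object of class `clean_signal`: `samples` (dimensionless,
#'   zero-mean, unit-SD), `sampling_rate`, `session_id`, and `filter`
#'   (provenance).
#' @export
condition_signal <- function(recording, filt = filter_config()) {
  if (sd(recording$samples) < 1e-12)
    stopf("flat signal: recording has zero variance (session %s)",
          recording$session_id %||% "?")
  y <- bandpass(recording, filt)
  y <- apply_notch(y, filt$notch_freqs, filt$notch_q, recording$sampling_rate)
  y <- -y
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12)
    stopf("flat signal: post-filter variance is zero (session %s)",
          recording$session_id %||% "?")
  y <- (y - mean(y)) / s
  ## lightly filtered companion trace (wide band, same inversion/scale):
  ## the narrowband trace cannot track breath-to-breath period jitter at the
  ## sample level, so extremum times are refined on this trace downstream
  fs <- recording$sampling_rate
  wide_high <- min(2, 0.4 * fs)
  wide <- tryCatch({
    sosw <- butter_bandpass_sos(2L, 0.05, wide_high, fs)
    w <- -sos_filtfilt(recording$samples, sosw, bandpass_pad_samples(0.05, fs))
    (w - mean(w)) / s
  }, error = function(e) NULL)
  structure(list(samples = y, sampling_rate = recording$sampling_rate,
                 session_id = recording$session_id, filter = filt,
                 wide = wide),
            class = "clean_signal")
}

#' @export
print.clean_signal <- function(x, ...) {
  cat(sprintf("<clean_signal> %s: %d samples @ %g Hz, band %g-%g Hz (order %d)\n",
              x$session_id, length(x$samples), x$sampling_rate,
              x$filter$band_low, x$filter$band_high, x$filter$order))
  invisible(x)
}

#' Session spectrogram
#'
#' Short-time power estimate (Hann-windowed FFT segments) of a recording or
#' conditioned signal. With the defaults the frequency axis resolves 0.05 Hz
#' or finer.
#'
#' @param x a `resp_recording` or `clean_signal`.
#' @param window_s segment length, s.
#' @param overlap_frac fractional overlap of consecutive segments.
#' @return object of class `resp_spectrogram`: `time` (segment centers, s),
#'   `freq` (Hz), `power` (freq x time matrix).
#' @export
resp_spectrogram <- function(x, window_s = 30, overlap_frac = 0.5) {
  stopifnot(inherits(x, c("resp_recording", "clean_signal")))
  fs <- x$sampling_rate
  samples <- x$samples
  nwin <- as.integer(round(window_s * fs))
  if (nwin > length(samples))
    stopf("spectrogram window (%g s) longer than the recording (%.1f s)",
          window_s, length(samples) / fs)
  noverlap <- as.integer(round(nwin * overlap_frac))
  sg <- signal::specgram(samples, n = nwin, Fs = fs, overlap = noverlap)
  structure(list(time = as.numeric(sg$t), freq = as.numeric(sg$f),
                 power = Mod(sg$S)^2),
            class = "resp_spectrogram")
}

#' Epoch a conditioned signal into trial windows
#'
#' Extracts the half-open window `[trial_start - pre_s, trial_start + post_s)`
#' for each trial. Trials whose window falls outside the recording are flagged
#' excluded (their rows are NA), never silently dropped.
#'
#' @param signal a `clean_signal`.
#' @param trials trial event table with a `trial_start_s` column.
#' @param window numeric `c(pre_s, post_s)`, both >= 0.
#' @return list with `epochs` (trials x samples matrix), `time` (epoch time
#'   axis relative to trial start) and `excluded` (logical per trial).
#' @export
epoch_trials <- function(signal, trials, window = c(2, 6)) {
  stopifnot(inherits(signal, "clean_signal"), is.data.frame(trials),
            length(window) == 2L, all(window >= 0))
  starts <- trials$trial_start_s
  bad <- !is.finite(starts) | starts < 0
  if (any(bad))
    stopf("malformed trial start time at trial index %s",
          paste(trials$trial_index[bad], collapse = ", "))
  fs <- signal$sampling_rate
  n_samp <- as.integer(round(sum(window) * fs))
  n <- length(signal$samples)
  i0 <- as.integer(round((starts - window[1]) * fs)) + 1L
  excluded <- i0 < 1L | (i0 + n_samp - 1L) > n
  epochs <- matrix(NA_real_, nrow = length(starts), ncol = n_samp)
  for (j in which(!excluded))
    epochs[j, ] <- signal$samples[i0[j]:(i0[j] + n_samp - 1L)]
  time <- (seq_len(n_samp) - 1L) / fs - window[1]
  list(epochs = epochs, time = time, excluded = excluded)
}
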