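## Breath-cycle segmentation and trial-aligned feature extraction.
##
## Peaks of the conditioned (inverted) trace mark exhalation onsets, valleys
## mark inhalation onsets. Detection is a tailored peak finder: candidate
## local extrema -> strict peak/valley alternation -> iterative removal of
## low-prominence extrema -> minimum-separation pruning -> assembly into
## valley -> peak -> valley cycles.

#' Peak-detection configuration
#'
#' @param min_prominence minimum topographic prominence of a kept extremum, in
#'   z-units of the conditioned signal.
#' @param min_separation minimum time between consecutive same-type extrema,
#'   s. Values above the fastest in-band period (`1 / band_high`) would
#'   suppress legitimate fast breaths and are flagged with a warning.
#' @param refine_window half-width (s) of the window in which each extremum
#'   time is refined on the wide-band companion trace of the conditioned
#'   signal (the narrowband trace localizes extrema robustly but cannot track
#'   breath-to-breath period jitter at the sample level); 0 disables
#'   refinement.
#' @return object of class `peak_config`.
#' @export
peak_config <- function(min_prominence = 0.3, min_separation = 1.0,
                        refine_window = 0.4) {
  stopifnot(is_num1(min_prominence), min_prominence >= 0,
            is_num1(min_separation), min_separation > 0,
            is_num1(refine_window), refine_window >= 0)
  structure(list(min_prominence = min_prominence,
                 min_separation = min_separation,
                 refine_window = refine_window),
            class = "peak_config")
}

## Candidate strict local extrema of x; returns data.frame(idx, type)
## with type +1 = peak, -1 = valley.
local_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  s[s == 0] <- 1  # flat steps break ties toward continuation
  ds <- diff(s)
  peaks <- which(ds < 0) + 1L
  valleys <- which(ds > 0) + 1L
  ext <- data.frame(idx = c(peaks, valleys),
                    type = rep(c(1L, -1L), c(length(peaks), length(valleys))))
  ext[order(ext$idx), , drop = FALSE]
}

## Enforce strict alternation: among runs of same-type extrema keep the most
## extreme one.
enforce_alternation <- function(ext, x) {
  if (nrow(ext) == 0L) return(ext)
  keep <- integer(0)
  run_best <- 1L
  for (i in seq_len(nrow(ext))[-1]) {
    if (ext$type[i] == ext$type[run_best]) {
      better <- if (ext$type[i] > 0) x[ext$idx[i]] > x[ext$idx[run_best]]
                else x[ext$idx[i]] < x[ext$idx[run_best]]
      if (better) run_best <- i
    } else {
      keep <- c(keep, run_best)
      run_best <- i
    }
  }
  keep <- c(keep, run_best)
  ext[keep, , drop = FALSE]
}

## Topographic prominence of every extremum in an alternating sequence.
## For a peak: height minus the higher of the two minima separating it from
## the nearest higher peak (or the signal edge) on each side; valleys are
## measured on the negated trace.
alternating_prominences <- function(ext, x) {
  n <- nrow(ext)
  prom <- numeric(n)
  val <- x[ext$idx]
  for (i in seq_len(n)) {
    sgn <- ext$type[i]
    h <- sgn * val[i]
    ## walk left (work on sgn * x, where this extremum is a peak of height h)
    m_left <- Inf
    j <- i - 1L
    repeat {
      if (j < 1L) { m_left <- min(m_left, min(sgn * x[1:ext$idx[i]])); break }
      if (ext$type[j] == sgn) { if (sgn * val[j] > h) break }
      else m_left <- min(m_left, sgn * val[j])
      j <- j - 1L
    }
    m_right <- Inf
    j <- i + 1L
    repeat {
      if (j > n) { m_right <- min(m_right, min(sgn * x[ext$idx[i]:length(x)])); break }
      if (ext$type[j] == sgn) { if (sgn * val[j] > h) break }
      else m_right <- min(m_right, sgn * val[j])
      j <- j + 1L
    }
    prom[i] <- h - max(m_left, m_right)
  }
  prom
}

## Drop the weakest extremum below `thresh` (or closer than min_sep to its
## same-type neighbour), restore alternation, repeat.
prune_extrema <- function(ext, x, min_prom, min_sep_samples) {
  repeat {
    if (nrow(ext) < 2L) return(ext)
    prom <- alternating_prominences(ext, x)
    bad <- prom < min_prom
    sep_bad <- rep(FALSE, nrow(ext))
    idx <- ext$idx
    for (k in seq_len(nrow(ext) - 2L)) {
      if (ext$type[k] == ext$type[k + 2L] &&
          (idx[k + 2L] - idx[k]) < min_sep_samples) {
        weaker <- if (prom[k] <= prom[k + 2L]) k else k + 2L
        sep_bad[weaker] <- TRUE
      }
    }
    drop <- bad | sep_bad
    if (!any(drop)) return(ext)
    victim <- which(drop)[which.min(prom[drop])]
    ext <- ext[-victim, , drop = FALSE]
    ext <- enforce_alternation(ext, x)
  }
}

## Re-localize one extremum on the wide-band trace inside +-half samples,
## with a final 3-point parabolic sub-sample step.
refine_extremum <- function(wide, idx, half, type) {
  n <- length(wide)
  if (is.null(wide) || half < 1L) return(idx)
  lo <- max(1L, idx - half); hi <- min(n, idx + half)
  seg <- type * wide[lo:hi]
  idx <- lo + which.max(seg) - 1L
  if (idx <= 1L || idx >= n) return(idx)
  y0 <- type * wide[idx - 1L]; y1 <- type * wide[idx]; y2 <- type * wide[idx + 1L]
  den <- y0 - 2 * y1 + y2
  if (abs(den) < 1e-12) return(idx)
  idx + max(-1, min(1, 0.5 * (y0 - y2) / den))
}

#' Detect breath cycles in a conditioned signal
#'
#' @param signal a `clean_signal` from [condition_signal()].
#' @param cfg a [peak_config()].
#' @return object of class `breath_cycles`: a data.frame with one row per
#'   complete cycle (`inhalation_onset`, `exhalation_onset`,
#'   `next_inhalation_onset`, `peak_prominence`, `valley_prominence`, all
#'   times in session seconds), with attribute `qc_flag = TRUE` when no
#'   extrema were found. Unpaired leading/trailing extrema are discarded.
#' @export
detect_cycles <- function(signal, cfg = peak_config()) {
  stopifnot(inherits(signal, "clean_signal"), inherits(cfg, "peak_config"))
  x <- signal$samples
  fs <- signal$sampling_rate
  bh <- signal$filter$band_high %||% NA_real_
  if (is.finite(bh) && cfg$min_separation > 1 / bh)
    warning(sprintf("min_separation (%g s) exceeds the fastest in-band period (%g s); fast breaths would be suppressed",
                    cfg$min_separation, 1 / bh), call. = FALSE)
  empty <- data.frame(inhalation_onset = numeric(0),
                      exhalation_onset = numeric(0),
                      next_inhalation_onset = numeric(0),
                      peak_prominence = numeric(0),
                      valley_prominence = numeric(0))
  ext <- local_extrema(x)
  if (nrow(ext) == 0L)
    return(structure(empty, class = c("breath_cycles", "data.frame"),
                     qc_flag = TRUE))
  ext <- enforce_alternation(ext, x)
  ext <- prune_extrema(ext, x, cfg$min_prominence,
                       as.integer(round(cfg$min_separation * fs)))
  if (nrow(ext) < 3L)
    return(structure(empty, class = c("breath_cycles", "data.frame"),
                     qc_flag = nrow(ext) == 0L))
  prom <- alternating_prominences(ext, x)
  half <- as.integer(round(cfg$refine_window * fs))
  wide <- signal$wide
  tim <- vapply(seq_len(nrow(ext)), function(i)
    (refine_extremum(wide, ext$idx[i], half, ext$type[i]) - 1) / fs,
    numeric(1))
  ## assemble valley -> peak -> valley triplets
  v <- which(ext$type == -1L)
  rows <- v[v + 2L <= nrow(ext)]
  rows <- rows[ext$type[rows + 1L] == 1L & ext$type[rows + 2L] == -1L]
  out <- data.frame(inhalation_onset = tim[rows],
                    exhalation_onset = tim[rows + 1L],
                    next_inhalation_onset = tim[rows + 2L],
                    peak_prominence = prom[rows + 1L],
                    valley_prominence = prom[rows])
  structure(out, class = c("breath_cycles", "data.frame"), qc_flag = FALSE)
}

#' @export
print.breath_cycles <- function(x, ...) {
  cat(sprintf("<breath_cycles> %d complete cycles%s\n", nrow(x),
              if (isTRUE(attr(x, "qc_flag"))) " [QC FLAG: no extrema]" else ""))
  if (nrow(x) > 0)
    cat(sprintf("  cycle length %.2f +- %.2f s\n",
                mean(x$next_inhalation_onset - x$inhalation_onset),
                sd(x$next_inhalation_onset - x$inhalation_onset)))
  invisible(x)
}

#' First complete cycle at or after a trial start
#'
#' @param cycles a `breath_cycles` data.frame (sorted by onset).
#' @param trial_start time in session seconds.
#' @return the single-row cycle with the smallest `inhalation_onset >=
#'   trial_start`, or `NULL` when none exists.
#' @export
first_cycle_after <- function(cycles, trial_start) {
  stopifnot(is_num1(trial_start))
  i <- which(cycles$inhalation_onset >= trial_start)
  if (length(i) == 0L) return(NULL)
  cycles[i[1L], , drop = FALSE]
}

#' Instantaneous respiration phase of a session
#'
#' Angle of the analytic signal (Hilbert transform) of the whole-session
#' conditioned trace, in degrees wrapped to (-180, 180]. By construction the
#' phase is 0 deg at signal maxima (exhalation onset) and +-180 deg at minima
#' (inhalation onset), increasing through a cycle.
#'
#' @param signal a `clean_signal`.
#' @return numeric vector of phases, one per sample.
#' @export
phase_map <- function(signal) {
  stopifnot(inherits(signal, "clean_signal"))
  fs <- signal$sampling_rate
  bl <- signal$filter$band_low %||% 0.1
  if (length(signal$samples) < 3 * fs / bl)
    stopf("session shorter than 3 breath cycles at the passband floor; Hilbert edge effects would dominate")
  if (sd(signal$samples) < 1e-12)
    stopf("constant signal has no defined instantaneous phase")
  a <- analytic_signal(signal$samples)
  wrap_deg(Arg(a) * 180 / pi)
}

canonical_feature_names <- function() {
  c("inhalation_onset_latency", "exhalation_onset_latency",
    "inhalation_duration", "exhalation_duration", "respiration_length",
    "inhalation_depth", "exhalation_depth",
    "inhalation_volume", "exhalation_volume", "total_volume",
    "phase_at_trial_start", "phase_at_fixation_onset")
}

#' Canonical feature names and groups
#'
#' The fixed 12-dimensional per-trial feature vector: 5 timing features,
#' 5 amplitude features, 2 phase features.
#'
#' @return named list with `all`, `timing`, `amplitude`, `phase`.
#' @export
feature_groups <- function() {
  all <- canonical_feature_names()
  list(all = all, timing = all[1:5], amplitude = all[6:10], phase = all[11:12])
}

## Baseline-corrected magnitude of the trapezoidal integral over [t0, t1].
segment_volume <- function(x, fs, t0, t1) {
  i0 <- as.integer(round(t0 * fs)) + 1L
  i1 <- as.integer(round(t1 * fs)) + 1L
  i0 <- max(1L, i0); i1 <- min(length(x), i1)
  if (i1 - i0 < 1L) return(0)
  tt <- (seq(i0, i1) - 1L) / fs
  y <- x[i0:i1]
  chord <- y[1] + (y[length(y)] - y[1]) * (tt - tt[1]) / (tt[length(tt)] - tt[1])
  abs(trapz_int(tt, y - chord))
}

#' Extract the canonical features of one trial-aligned cycle
#'
#' Latencies are onsets relative to trial start; durations partition the
#' cycle; depths are the detected prominences; volumes are magnitudes of the
#' trapezoidal integral of the conditioned signal over the inhalation and
#' exhalation sub-intervals after subtracting each sub-interval's chord
#' baseline (robust to residual slow drift; the thermal sensor has no absolute
#' amplitude calibration, so only magnitudes are meaningful); phases are read
#' from the session-wide [phase_map()] at trial start and fixation onset.
#'
#' @param signal a `clean_signal`.
#' @param cycle one-row `breath_cycles` entry (see [first_cycle_after()]).
#' @param trial_start,fixation_onset event times, session s. A non-finite
#'   `fixation_onset` yields `NA` for its phase, other fields are computed.
#' @param phase optional precomputed [phase_map()] vector.
#' @return one-row data.frame with the 12 canonical features and `valid`.
#' @export
extract_cycle_features <- function(signal, cycle, trial_start, fixation_onset,
                                   phase = NULL) {
  stopifnot(inherits(signal, "clean_signal"))
  if (is.null(phase)) phase <- phase_map(signal)
  fs <- signal$sampling_rate
  x <- signal$samples
  if (is.null(cycle) || nrow(cycle) != 1L) return(invalid_features())
  o1 <- cycle$inhalation_onset
  pk <- cycle$exhalation_onset
  o2 <- cycle$next_inhalation_onset
  if (!(trial_start <= o1 && o1 < pk && pk < o2)) return(invalid_features())
  phase_at <- function(t) {
    if (!is.finite(t)) return(NA_real_)
    i <- as.integer(round(t * fs)) + 1L
    if (i < 1L || i > length(phase)) return(NA_real_)
    phase[i]
  }
  inh_vol <- segment_volume(x, fs, o1, pk)
  exh_vol <- segment_volume(x, fs, pk, o2)
  data.frame(
    inhalation_onset_latency = o1 - trial_start,
    exhalation_onset_latency = pk - trial_start,
    inhalation_duration = pk - o1,
    exhalation_duration = o2 - pk,
    respiration_length = (pk - o1) + (o2 - pk),
    inhalation_depth = cycle$valley_prominence,
    exhalation_depth = cycle$peak_prominence,
    inhalation_volume = inh_vol,
    exhalation_volume = exh_vol,
    total_volume = inh_vol + exh_vol,
    phase_at_trial_start = phase_at(trial_start),
    phase_at_fixation_onset = phase_at(fixation_onset),
    valid = TRUE)
}

invalid_features <- function() {
  out <- as.data.frame(as.list(setNames(rep(NA_real_, 12L),
                                        canonical_feature_names())))
  out$valid <- FALSE
  out
}

#' Build the per-session trial feature table
#'
#' Detects cycles once per session, then extracts the canonical 12 features
#' from the first complete cycle at or after each trial start. Trials with no
#' such cycle get `valid = FALSE` but keep their row. The session is flagged
#' (attribute `qc_flag`) when more than 20% of trials are invalid.
#'
#' @param signal a `clean_signal`.
#' @param trials trial event table for the same session.
#' @param cfg a [peak_config()].
#' @return data.frame of class `trial_features`: canonical features plus
#'   `valid`, `outcome`, `difficulty`, `trial_index`, `session_id`.
#' @export
build_trial_features <- function(signal, trials, cfg = peak_config()) {
  stopifnot(inherits(signal, "clean_signal"), is.data.frame(trials))
  if (!is.null(trials$session_id) && !is.null(signal$session_id) &&
      !all(trials$session_id == signal$session_id))
    stopf("trials and signal come from different sessions")
  cycles <- detect_cycles(signal, cfg)
  phase <- phase_map(signal)
  rows <- lapply(seq_len(nrow(trials)), function(j) {
    cyc <- if (nrow(cycles)) first_cycle_after(cycles, trials$trial_start_s[j]) else NULL
    extract_cycle_features(signal, cyc, trials$trial_start_s[j],
                           trials$fixation_onset_s[j] %||% NA_real_, phase)
  })
  out <- do.call(rbind, rows)
  out$outcome <- trials$outcome
  out$difficulty <- trials$difficulty
  out$trial_index <- trials$trial_index
  out$session_id <- trials$session_id %||% signal$session_id
  frac_bad <- mean(!out$valid)
  structure(out, class = c("trial_features", "data.frame"),
            qc_flag = frac_bad > 0.2, invalid_fraction = frac_bad)
}
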