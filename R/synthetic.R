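## Synthetic respiration sessions with planted outcome-dependent effects.
##
## The generator emulates a trial-paced detection task recorded with a nasal
## thermocouple: a ~15 breaths/min dominant rhythm, outcome proportions around
## 70/19/11 (correct / false alarm / miss), outcome-dependent inter-trial
## intervals, and raw thermocouple polarity (exhalation raises the voltage).
## Known effects - an inhalation-onset shift, a cycle-length delta and an
## amplitude delta on correct trials - are planted locally around each trial
## start so that downstream feature extraction and statistics can be validated
## by parameter recovery against the recorded ground truth.

#' Configuration for the synthetic respiration generator
#'
#' Defaults encode the emulated task: 1 kHz sampling, 4 s base breath period
#' (15 breaths/min), outcome probabilities 0.70/0.19/0.11, inter-trial
#' intervals of 0.99/1.62/2.00 s after correct/false-alarm/miss trials,
#' fixation hold of 400-600 ms, and a go-cue delay drawn from an exponential
#' rejection-truncated to [1.7, 3.0] s whose rate is solved so the truncated
#' mean equals `delay_mean`.
#'
#' Breath cycles are asymmetric raised-cosine half-waves (`inhalation_fraction`
#' of each cycle is inhalation), so inhalation and exhalation durations are
#' genuinely distinct features. Around every trial start the breath train is
#' locally re-timed so the next inhalation onset falls `trial_start +
#' U(latency_window)`; on correct trials that onset is additionally moved by
#' `effect_inhalation_onset_shift`, the cycle starting there is lengthened by
#' `effect_cycle_length_delta`, and its amplitude raised by
#' `effect_amplitude_delta`. When the next trial starts inside a trial's
#' feature cycle, its re-timing truncates that cycle; the onset shift is then
#' still planted exactly for every trial while the length delta survives only
#' on non-truncated trials (recorded per trial in the ground truth).
#'
#' @param n_sessions number of sessions for [generate_dataset()].
#' @param trials_per_session trials per session.
#' @param sampling_rate recording sampling rate, Hz.
#' @param base_breath_period mean breath period, s.
#' @param period_jitter_sd per-cycle period jitter SD, s.
#' @param inhalation_fraction fraction of each cycle spent inhaling.
#' @param amplitude_mean,amplitude_jitter_sd per-cycle amplitude mean/SD
#'   (arbitrary units; the thermal sensor is uncalibrated).
#' @param baseline_drift_amp amplitude of slow (< 0.03 Hz) baseline drift.
#' @param noise_sd SD of additive white measurement noise.
#' @param p_correct,p_false_alarm,p_miss outcome probabilities (sum to 1).
#' @param p_correct_by_difficulty optional length-4 vector of per-difficulty
#'   detection probabilities; when given, outcomes are false alarms with
#'   `p_false_alarm` and otherwise correct with the difficulty's probability
#'   (hit rate then recovers this vector exactly in expectation).
#' @param iti_correct,iti_false_alarm,iti_miss mean inter-trial interval after
#'   each outcome, s.
#' @param iti_jitter_sd SD of the inter-trial interval, s.
#' @param fixation_range fixation hold duration range, s.
#' @param fixation_acquisition_mean,fixation_acquisition_sd time from trial
#'   start to fixation acquisition (mean/SD of a truncated normal), s.
#' @param delay_mean,delay_min,delay_max target-to-go-cue delay: truncated
#'   exponential mean and range, s.
#' @param response_range saccade reaction-time range on correct trials, s.
#' @param latency_window range of the re-timed inhalation-onset latency after
#'   trial start, s.
#' @param effect_inhalation_onset_shift signed shift (s) of the first
#'   inhalation onset after trial start, applied to correct trials.
#' @param effect_cycle_length_delta signed length change (s) of the first
#'   complete cycle after trial start, applied to correct trials.
#' @param effect_amplitude_delta signed amplitude change of that cycle,
#'   applied to correct trials.
#' @param rng_seed integer master seed; per-session seeds derive from it via
#'   [child_seed()], so identical seeds give bit-identical output.
#' @param lead_in,tail breathing-only padding before the first and after the
#'   last trial, s (keeps filter and Hilbert edge effects away from trials).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_sessions = 1L,
                         trials_per_session = 300L,
                         sampling_rate = 1000,
                         base_breath_period = 4.0,
                         period_jitter_sd = 0.25,
                         inhalation_fraction = 0.45,
                         amplitude_mean = 1.0,
                         amplitude_jitter_sd = 0.1,
                         baseline_drift_amp = 0.3,
                         noise_sd = 0.1,
                         p_correct = 0.70,
                         p_false_alarm = 0.19,
                         p_miss = 0.11,
                         p_correct_by_difficulty = NULL,
                         iti_correct = 0.99,
                         iti_false_alarm = 1.62,
                         iti_miss = 2.00,
                         iti_jitter_sd = 0.06,
                         fixation_range = c(0.4, 0.6),
                         fixation_acquisition_mean = 0.321,
                         fixation_acquisition_sd = 0.057,
                         delay_mean = 2.0,
                         delay_min = 1.7,
                         delay_max = 3.0,
                         response_range = c(0.25, 0.45),
                         latency_window = c(1.0, 2.0),
                         effect_inhalation_onset_shift = 0,
                         effect_cycle_length_delta = 0,
                         effect_amplitude_delta = 0,
                         rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$lead_in <- 20
  cfg$tail <- 20
  validate_synth_config(structure(cfg, class = "synth_config"))
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_sessions) || !is_count(trials_per_session))
      stopf("n_sessions and trials_per_session must be positive integers")
    if (!is_num1(sampling_rate) || sampling_rate <= 0)
      stopf("sampling_rate must be a positive number")
    p <- p_correct + p_false_alarm + p_miss
    if (abs(p - 1) > 1e-9)
      stopf("outcome probabilities must sum to 1 (got %.12f)", p)
    if (!(delay_min <= delay_mean && delay_mean <= delay_max))
      stopf("need delay_min <= delay_mean <= delay_max")
    durs <- c(base_breath_period, iti_correct, iti_false_alarm, iti_miss,
              fixation_range, delay_min, delay_max, latency_window)
    if (any(durs <= 0)) stopf("all durations must be > 0")
    if (inhalation_fraction <= 0.1 || inhalation_fraction >= 0.9)
      stopf("inhalation_fraction must lie in (0.1, 0.9)")
    if (latency_window[1] >= latency_window[2])
      stopf("latency_window must be increasing")
    if (any(abs(c(effect_inhalation_onset_shift, effect_cycle_length_delta)) >
            base_breath_period / 2))
      stopf("planted effects larger than base_breath_period/2 would collapse cycles")
    if (latency_window[1] + min(0, effect_inhalation_onset_shift) <= 0.05)
      stopf("latency_window[1] plus a negative onset shift must stay above 0.05 s")
    if (!is.null(p_correct_by_difficulty) &&
        (length(p_correct_by_difficulty) != 4L ||
         any(p_correct_by_difficulty < 0 | p_correct_by_difficulty > 1)))
      stopf("p_correct_by_difficulty must be 4 probabilities")
  })
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d session(s) x %d trials @ %g Hz\n",
              x$n_sessions, x$trials_per_session, x$sampling_rate))
  cat(sprintf("  breath period %g s (jitter %g), amplitude %g (jitter %g), noise %g\n",
              x$base_breath_period, x$period_jitter_sd, x$amplitude_mean,
              x$amplitude_jitter_sd, x$noise_sd))
  cat(sprintf("  outcomes %.2f/%.2f/%.2f, planted effects: shift %+g s, length %+g s, amp %+g\n",
              x$p_correct, x$p_false_alarm, x$p_miss,
              x$effect_inhalation_onset_shift, x$effect_cycle_length_delta,
              x$effect_amplitude_delta))
  invisible(x)
}

## Rate of the underlying exponential such that delay_min + Exp(rate) rejected
## above delay_max has the configured mean.
delay_exp_mean <- function(delay_mean, delay_min, delay_max) {
  L <- delay_max - delay_min
  target <- delay_mean - delay_min
  if (target <= 1e-9) return(1e-6)
  if (target >= L / 2 - 1e-9) return(1e6)  # ~uniform limit
  f <- function(m) m - L / (exp(L / m) - 1) - target
  uniroot(f, c(1e-4, 1e4), tol = 1e-10)$root
}

draw_truncated_delay <- function(n, delay_mean, delay_min, delay_max) {
  m <- delay_exp_mean(delay_mean, delay_min, delay_max)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      d <- rexp(1, rate = 1 / m)
      if (d <= delay_max - delay_min) break
    }
    out[i] <- delay_min + d
  }
  out
}

## Trial schedule for one session; assumes the RNG is already seeded.
schedule_trials <- function(cfg) {
  n <- cfg$trials_per_session
  start <- fix_on <- go <- end <- numeric(n)
  outcome <- character(n)
  difficulty <- integer(n)
  t <- cfg$lead_in
  for (j in seq_len(n)) {
    start[j] <- t
    fix_on[j] <- start[j] + max(0.05, rnorm(1, cfg$fixation_acquisition_mean,
                                            cfg$fixation_acquisition_sd))
    fix_dur <- runif(1, cfg$fixation_range[1], cfg$fixation_range[2])
    target_on <- fix_on[j] + fix_dur
    delay <- draw_truncated_delay(1, cfg$delay_mean, cfg$delay_min, cfg$delay_max)
    go_cue <- target_on + delay
    difficulty[j] <- sample.int(4L, 1L)
    if (!is.null(cfg$p_correct_by_difficulty)) {
      if (runif(1) < cfg$p_false_alarm) outcome[j] <- "false_alarm"
      else if (runif(1) < cfg$p_correct_by_difficulty[difficulty[j]])
        outcome[j] <- "correct"
      else outcome[j] <- "miss"
    } else {
      outcome[j] <- sample(c("correct", "false_alarm", "miss"), 1L,
                           prob = c(cfg$p_correct, cfg$p_false_alarm, cfg$p_miss))
    }
    if (outcome[j] == "correct") {
      go[j] <- go_cue
      end[j] <- go_cue + runif(1, cfg$response_range[1], cfg$response_range[2])
      iti_mean <- cfg$iti_correct
    } else if (outcome[j] == "false_alarm") {
      go[j] <- NA_real_  # fixation broken before the go cue ever appeared
      end[j] <- fix_on[j] + runif(1, 0.4, 0.95) * (go_cue - fix_on[j])
      iti_mean <- cfg$iti_false_alarm
    } else {
      go[j] <- go_cue    # miss: cue shown, no saccade; timeout runs from it
      end[j] <- go_cue
      iti_mean <- cfg$iti_miss
    }
    t <- end[j] + max(0.3, rnorm(1, iti_mean, cfg$iti_jitter_sd))
  }
  data.frame(trial_index = seq_len(n), trial_start_s = start,
             fixation_onset_s = fix_on, go_cue_s = go, end_s = end,
             outcome = outcome, difficulty = difficulty,
             stringsAsFactors = FALSE)
}

#' Simulate a trial event table without rendering the respiration signal
#'
#' Useful for checking the task statistics (outcome proportions, inter-trial
#' gaps, delay distribution) at large trial counts cheaply.
#'
#' @param config a [synth_config()].
#' @param session_index session number (selects the deterministic child seed).
#' @return a data.frame of trial events.
#' @export
simulate_trial_schedule <- function(config, session_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$rng_seed, session_index))
  schedule_trials(config)
}

## Breath train with per-trial local re-timing and planted effects.
## Returns the cycle list plus per-trial planting bookkeeping.
plant_breath_train <- function(cfg, sched) {
  draw_period <- function() max(1.2, rnorm(1, cfg$base_breath_period,
                                           cfg$period_jitter_sd))
  draw_amp <- function() max(0.05, rnorm(1, cfg$amplitude_mean,
                                         cfg$amplitude_jitter_sd))
  n <- nrow(sched)
  onsets <- durs <- amps <- numeric(0)
  trial_cycle <- integer(n)
  latency <- numeric(n)
  shift_applied <- numeric(n)
  length_planted <- logical(n)
  session_end <- sched$end_s[n] + cfg$iti_miss + cfg$tail
  last_end <- 0
  add_cycle <- function(onset, dur, amp) {
    onsets[length(onsets) + 1L] <<- onset
    durs[length(durs) + 1L] <<- dur
    amps[length(amps) + 1L] <<- amp
  }
  for (j in seq_len(n)) {
    s_j <- sched$trial_start_s[j]
    correct <- sched$outcome[j] == "correct"
    repeat {
      T <- draw_period()
      if (last_end + T >= s_j) break
      add_cycle(last_end, T, draw_amp())
      last_end <- last_end + T
    }
    u <- runif(1, cfg$latency_window[1], cfg$latency_window[2])
    sh <- if (correct) cfg$effect_inhalation_onset_shift else 0
    o1 <- s_j + u + sh
    if (last_end < s_j) {
      ## cycle in progress started before this trial: close it at o1
      add_cycle(last_end, o1 - last_end, draw_amp())
    } else {
      ## the previous trial's feature cycle runs past this trial's start: its
      ## end is re-timed to o1. The previous trial's planted length delta is
      ## carried into the re-timed boundary so it survives truncation in
      ## expectation (the exact drawn period is lost; flagged below).
      k <- length(onsets)
      if (j > 1L && trial_cycle[j - 1L] == k) {
        o1 <- o1 + (if (sched$outcome[j - 1L] == "correct")
          cfg$effect_cycle_length_delta else 0)
        length_planted[j - 1L] <- FALSE
      }
      stopifnot(onsets[k] < s_j, o1 - onsets[k] > 0.2)
      durs[k] <- o1 - onsets[k]
    }
    Tf <- draw_period() + if (correct) cfg$effect_cycle_length_delta else 0
    Af <- draw_amp() + if (correct) cfg$effect_amplitude_delta else 0
    add_cycle(o1, Tf, Af)
    trial_cycle[j] <- length(onsets)
    latency[j] <- o1 - s_j
    shift_applied[j] <- sh
    length_planted[j] <- TRUE
    last_end <- o1 + Tf
  }
  while (last_end < session_end + cfg$base_breath_period) {
    T <- draw_period()
    add_cycle(last_end, T, draw_amp())
    last_end <- last_end + T
  }
  list(cycles = data.frame(onset = onsets, duration = durs, amplitude = amps),
       trial_cycle = trial_cycle, latency = latency,
       shift_applied = shift_applied, length_planted = length_planted,
       session_end = session_end)
}

## Render the breath train as a continuous waveform in "conditioned" polarity
## (inhalation rising): each cycle is an asymmetric pair of raised-cosine
## half-waves, with the inhalation rising from the previous cycle's trough so
## the trace is continuous across cycle boundaries.
render_breath_wave <- function(cycles, fi, t) {
  y <- numeric(length(t))
  fs <- 1 / (t[2] - t[1])
  n <- length(t)
  ## t is the regular grid k/fs, k = 0..n-1: index ranges are arithmetic
  idx_range <- function(t0, t1) {
    i0 <- max(1L, as.integer(ceiling(t0 * fs - 1e-9)) + 1L)
    i1 <- min(n, as.integer(ceiling(t1 * fs - 1e-9)))
    if (i0 > i1) integer(0) else i0:i1
  }
  nA <- nrow(cycles)
  prev_amp <- c(cycles$amplitude[1], cycles$amplitude[-nA])
  for (i in seq_len(nA)) {
    o <- cycles$onset[i]; Tc <- cycles$duration[i]; A <- cycles$amplitude[i]
    A0 <- prev_amp[i]
    i_in <- idx_range(o, o + fi * Tc)
    i_ex <- idx_range(o + fi * Tc, o + Tc)
    if (length(i_in)) {
      ph <- (t[i_in] - o) / (fi * Tc)   # rise from -A0 to +A
      y[i_in] <- -((A0 + A) / 2) * cos(pi * ph) + (A - A0) / 2
    }
    if (length(i_ex)) {
      ph <- (t[i_ex] - o - fi * Tc) / ((1 - fi) * Tc)
      y[i_ex] <- A * cos(pi * ph)
    }
  }
  y
}

#' Generate one synthetic session
#'
#' Builds the trial schedule, plants the configured outcome-dependent effects
#' into the breath train, and renders a raw thermocouple-polarity recording
#' (exhalation raises the value) with slow baseline drift and additive white
#' noise. Fully deterministic given `config$rng_seed` and `session_index`.
#'
#' @param config a [synth_config()].
#' @param session_index session number (>= 1).
#' @return a list of class `synthetic_session` with elements `recording`
#'   (class `resp_recording`), `trials` (the trial event table) and
#'   `ground_truth` (planted cycle boundaries and per-trial effect records).
#' @export
generate_session <- function(config, session_index = 1L) {
  stopifnot(inherits(config, "synth_config"), is_count(session_index))
  set.seed(child_seed(config$rng_seed, session_index))
  sched <- schedule_trials(config)
  train <- plant_breath_train(config, sched)
  fs <- config$sampling_rate
  t <- seq(0, train$session_end, by = 1 / fs)
  clean <- render_breath_wave(train$cycles, config$inhalation_fraction, t)
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  drift <- config$baseline_drift_amp *
    (sin(2 * pi * 0.011 * t + ph1) + 0.6 * sin(2 * pi * 0.027 * t + ph2))
  raw <- -clean + drift + rnorm(length(t), 0, config$noise_sd)
  session_id <- sprintf("S%03d", session_index)
  recording <- structure(list(samples = raw, sampling_rate = fs,
                              session_id = session_id),
                         class = "resp_recording")
  trials <- cbind(session_id = session_id,
                  sched[c("trial_index", "trial_start_s", "fixation_onset_s",
                          "go_cue_s", "outcome", "difficulty")])
  gt_trials <- data.frame(
    trial_index = sched$trial_index,
    outcome = sched$outcome,
    feature_onset_s = train$cycles$onset[train$trial_cycle],
    latency_s = train$latency,
    shift_applied_s = train$shift_applied,
    cycle_duration_s = train$cycles$duration[train$trial_cycle],
    length_planted = train$length_planted,
    amplitude = train$cycles$amplitude[train$trial_cycle],
    stringsAsFactors = FALSE)
  ground_truth <- structure(list(cycles = train$cycles, trials = gt_trials),
                            class = "ground_truth")
  structure(list(recording = recording, trials = trials,
                 ground_truth = ground_truth),
            class = "synthetic_session")
}

#' Generate a multi-session synthetic dataset
#'
#' Sessions are independent; each uses a child seed derived deterministically
#' from `config$rng_seed`, so session `i` regenerated alone via
#' [generate_session()] equals session `i` from the batch.
#'
#' @param config a [synth_config()].
#' @return list of `synthetic_session` objects, class `synthetic_dataset`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  structure(lapply(seq_len(config$n_sessions), function(i)
    generate_session(config, i)), class = "synthetic_dataset")
}

#' @export
print.resp_recording <- function(x, ...) {
  cat(sprintf("<resp_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$session_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
print.synthetic_session <- function(x, ...) {
  print(x$recording)
  tab <- table(x$trials$outcome)
  cat(sprintf("  %d trials (%s)\n", nrow(x$trials),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
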