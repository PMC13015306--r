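## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## A pure-tone "recording" (long enough for the 30 s filter padding).
tone_recording <- function(freq, dur_s = 240, fs = 200, amp = 1,
                           session_id = "tone") {
  t <- seq(0, dur_s, by = 1 / fs)
  structure(list(samples = amp * sin(2 * pi * freq * t), sampling_rate = fs,
                 session_id = session_id),
            class = "resp_recording")
}

## Wrap an arbitrary sample vector as an already-conditioned signal.
as_clean <- function(x, fs, wide = NULL) {
  structure(list(samples = x, sampling_rate = fs, session_id = "manual",
                 filter = filter_config(), wide = wide),
            class = "clean_signal")
}

## Analytic single-pass Butterworth bandpass magnitude (the zero-phase
## pipeline realizes its square). Independent of the package's SOS design.
butter_bp_mag <- function(f, f_lo, f_hi, order, fs) {
  warp <- function(fr) 2 * fs * tan(pi * fr / fs)
  w <- warp(f); wl <- warp(f_lo); wh <- warp(f_hi)
  B <- wh - wl; w0 <- sqrt(wl * wh)
  1 / sqrt(1 + ((w^2 - w0^2) / (B * w))^(2 * order))
}

## One small planted-effect session pipeline, cached across test files.
planted_session <- function() cached("planted_session", {
  cfg <- synth_config(trials_per_session = 80, rng_seed = 21,
                      effect_inhalation_onset_shift = -0.3,
                      effect_cycle_length_delta = 0.3)
  s <- generate_session(cfg, 1)
  clean <- condition_signal(s$recording)
  list(cfg = cfg, session = s, clean = clean,
       features = build_trial_features(clean, s$trials),
       cycles = detect_cycles(clean))
})

## A session_feature_summary with specified per-session outcome means
## (identical across features; enough for testing the paired comparisons).
fake_summary <- function(x, y) {
  df <- data.frame(session_id = paste0("S", seq_along(x)),
                   n_correct = 50L, n_incorrect = 20L,
                   stringsAsFactors = FALSE)
  for (fe in breathdecode::feature_groups()$all) {
    df[[paste0(fe, "_correct")]] <- x
    df[[paste0(fe, "_incorrect")]] <- y
  }
  structure(df, class = c("session_feature_summary", "data.frame"))
}

## Directly simulated feature tables (no signal processing) for decode tests:
## Gaussian features with an optional mean shift on correct trials in the
## named columns.
sim_feature_table <- function(n, session_id, seed, shift = c(),
                              p_correct = 0.5) {
  set.seed(seed)
  feats <- breathdecode::feature_groups()$all
  x <- matrix(rnorm(n * length(feats)), n, length(feats),
              dimnames = list(NULL, feats))
  outcome <- ifelse(runif(n) < p_correct, "correct",
                    sample(c("false_alarm", "miss"), n, replace = TRUE))
  for (f in names(shift)) x[outcome == "correct", f] <-
    x[outcome == "correct", f] + shift[[f]]
  out <- as.data.frame(x)
  out$valid <- TRUE
  out$outcome <- outcome
  out$difficulty <- sample(1:4, n, replace = TRUE)
  out$trial_index <- seq_len(n)
  out$session_id <- session_id
  structure(out, class = c("trial_features", "data.frame"))
}
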