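test_that("a pure 0.25 Hz tone segments into 4 s cycles", {
  fs <- 100
  rec <- tone_recording(0.25, dur_s = 120, fs = fs)
  clean <- condition_signal(rec)
  cyc <- detect_cycles(clean)
  expect_gte(nrow(cyc), 26)   # edge cycles may be discarded
  expect_lte(nrow(cyc), 30)
  len <- cyc$next_inhalation_onset - cyc$inhalation_onset
  expect_true(all(abs(len - 4.0) < 0.01))
  expect_true(all(cyc$peak_prominence > 0 & cyc$valley_prominence > 0))
  ## strict ordering within each cycle
  expect_true(all(cyc$inhalation_onset < cyc$exhalation_onset &
                  cyc$exhalation_onset < cyc$next_inhalation_onset))
})

test_that("a constant trace yields no cycles and a session flag", {
  flat <- as_clean(rep(0, 2000), 100)
  cyc <- detect_cycles(flat)
  expect_equal(nrow(cyc), 0L)
  expect_true(attr(cyc, "qc_flag"))
})

test_that("detected inhalation onsets recover the generator's ground truth", {
  fx <- planted_session()
  cyc <- fx$cycles
  gt <- fx$session$ground_truth$cycles
  interior <- gt$onset > 30 & gt$onset < max(gt$onset) - 30
  err <- vapply(gt$onset[interior], function(o)
    min(abs(cyc$inhalation_onset - o)), numeric(1))
  expect_lt(median(err), 0.05)
  expect_gt(mean(err < 0.5), 0.95)
})

test_that("first_cycle_after uses the smallest onset at or after trial start", {
  cyc <- data.frame(inhalation_onset = c(8, 12, 16),
                    exhalation_onset = c(10, 14, 18),
                    next_inhalation_onset = c(12, 16, 20),
                    peak_prominence = 1, valley_prominence = 1)
  expect_equal(first_cycle_after(cyc, 9.5)$inhalation_onset, 12)
  expect_equal(first_cycle_after(cyc, 12)$inhalation_onset, 12)  # >= convention
  expect_null(first_cycle_after(cyc, 16.5))
})

test_that("instantaneous phase is 0 deg at maxima and +-180 deg at minima", {
  fs <- 100
  t <- seq(0, 400, by = 1 / fs)
  clean <- as_clean(sin(2 * pi * 0.25 * t), fs)
  ph <- phase_map(clean)
  core <- t > 50 & t < 350
  peaks <- which(core & abs((t - 1) %% 4) < 1e-9)    # sin peaks at t = 1 mod 4
  troughs <- which(core & abs((t - 3) %% 4) < 1e-9)
  expect_true(all(abs(ph[peaks]) < 2))
  expect_true(all(abs(ph[troughs]) > 178))
  ## phase increases monotonically once unwrapped
  dph <- diff(ph[core]) %% 360
  expect_true(all(dph > 0 & dph < 5))
  expect_error(phase_map(as_clean(rep(1, 40000), fs)), "constant")
  expect_error(phase_map(as_clean(sin(1:100), 100)), "shorter")
})

test_that("cycle features obey the symmetry and closed-form volume oracles", {
  fs <- 1000
  t <- seq(0, 12, by = 1 / fs)
  clean <- as_clean(-cos(2 * pi * t / 4), fs)
  phase0 <- rep(0, length(t))
  cycle <- data.frame(inhalation_onset = 4, exhalation_onset = 6,
                      next_inhalation_onset = 8,
                      peak_prominence = 2, valley_prominence = 2)
  f <- extract_cycle_features(clean, cycle, 4, 4.3, phase = phase0)
  expect_true(f$valid)
  expect_equal(f$inhalation_duration, 2)
  expect_equal(f$exhalation_duration, 2)
  expect_equal(f$respiration_length, 4)
  expect_equal(f$inhalation_volume, f$exhalation_volume, tolerance = 1e-6)
  expect_equal(f$total_volume, 2 * f$inhalation_volume)
  expect_equal(f$inhalation_onset_latency, 0)   # trial start at the onset
  ## half-sine inhalation segment: closed-form integral 4 / pi
  clean2 <- as_clean(c(sin(pi * seq(0, 2, by = 1 / fs) / 2),
                       rep(0, 2 * fs)), fs)
  cycle2 <- data.frame(inhalation_onset = 0, exhalation_onset = 2,
                       next_inhalation_onset = 4,
                       peak_prominence = 1, valley_prominence = 1)
  f2 <- extract_cycle_features(clean2, cycle2, 0, NA_real_,
                               phase = rep(0, length(clean2$samples)))
  expect_equal(f2$inhalation_volume, 4 / pi, tolerance = 1e-3 * pi / 4)
  expect_true(is.na(f2$phase_at_fixation_onset))  # non-finite fixation time
})

test_that("volumes agree with a 10x-refined Riemann oracle within 0.5%", {
  waveform <- function(t) sin(pi * t / 2) + 0.3 * sin(pi * t) - 0.1 * t
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  clean <- as_clean(c(waveform(t), rep(0, fs)), fs)
  cycle <- data.frame(inhalation_onset = 0, exhalation_onset = 2,
                      next_inhalation_onset = 3,
                      peak_prominence = 1, valley_prominence = 1)
  f <- extract_cycle_features(clean, cycle, 0, NA_real_,
                              phase = rep(0, length(clean$samples)))
  ## independent oracle: midpoint Riemann sum at 10x finer steps, same
  ## chord-baseline definition
  tt <- seq(0, 2, by = 1 / (10 * fs))
  y <- waveform(tt)
  chord <- y[1] + (y[length(y)] - y[1]) * tt / 2
  mid <- (y[-1] + y[-length(y)]) / 2 - (chord[-1] + chord[-length(chord)]) / 2
  oracle <- abs(sum(mid) / (10 * fs))
  expect_lt(abs(f$inhalation_volume - oracle) / oracle, 0.005)
})

test_that("trial feature tables are complete, additive, and correctly ordered", {
  fx <- planted_session()
  tf <- fx$features
  expect_equal(nrow(tf), 80L)
  expect_true(all(tf$valid))
  expect_false(attr(tf, "qc_flag"))
  v <- tf[tf$valid, ]
  expect_true(all(abs(v$respiration_length -
                      v$inhalation_duration - v$exhalation_duration) < 1e-9))
  expect_true(all(abs(v$total_volume -
                      v$inhalation_volume - v$exhalation_volume) < 1e-9))
  expect_true(all(v$inhalation_onset_latency < v$exhalation_onset_latency))
  expect_true(all(v$inhalation_volume >= 0 & v$exhalation_volume >= 0))
  expect_true(all(v$phase_at_trial_start > -180 & v$phase_at_trial_start <= 180))
  ## phase/timing consistency: the closer the start phase is to the upcoming
  ## inhalation onset (+-180 deg), the shorter the onset latency
  to_go <- (180 - v$phase_at_trial_start) %% 360
  ct <- stats::cor.test(to_go, v$inhalation_onset_latency)
  expect_gt(unname(ct$estimate), 0.15)
  expect_lt(ct$p.value, 0.01)
  ## a trial starting after the last complete cycle keeps its row, invalid
  tr_late <- fx$session$trials[1, ]
  tr_late$trial_start_s <- max(fx$cycles$next_inhalation_onset) + 1
  tf2 <- build_trial_features(fx$clean, tr_late)
  expect_equal(nrow(tf2), 1L)
  expect_false(tf2$valid[1])
  expect_true(attr(tf2, "qc_flag"))
})

test_that("planted onset shift appears in the extracted features", {
  fx <- planted_session()
  tf <- fx$features[fx$features$valid, ]
  d <- mean(tf$inhalation_onset_latency[tf$outcome == "correct"]) -
    mean(tf$inhalation_onset_latency[tf$outcome != "correct"])
  ## small single-session check; the tight tolerance lives at larger n
  expect_lt(d, -0.1)
  gt <- fx$session$ground_truth$trials
  d_gt <- mean(gt$latency_s[gt$outcome == "correct"]) -
    mean(gt$latency_s[gt$outcome != "correct"])
  expect_lt(abs(d - d_gt), 0.06)
})
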