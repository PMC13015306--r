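## Session-level and within-session statistics of cycle features by trial
## outcome, plus behavioral psychometrics. "Incorrect" pools false alarms and
## misses; a three-way split is available via `pool_incorrect = FALSE` where
## it matters.

#' Hit rate
#'
#' Proportion of correct trials among correct plus miss trials; false alarms
#' are excluded by definition.
#'
#' @param n_correct,n_miss trial counts.
#' @return `n_correct / (n_correct + n_miss)`.
#' @export
hit_rate <- function(n_correct, n_miss) {
  stopifnot(is_num1(n_correct), is_num1(n_miss),
            n_correct >= 0, n_miss >= 0)
  if (n_correct + n_miss == 0)
    stopf("hit rate undefined: no correct or miss trials")
  n_correct / (n_correct + n_miss)
}

#' Psychometric curve: hit rate by difficulty rank
#'
#' Per-session hit rate at each difficulty rank (1 = easiest, 4 = hardest),
#' plus the across-session mean and SEM. Ranks with no correct-or-miss trials
#' in a session are `NA` for that session.
#'
#' @param trials trial table (possibly several sessions row-bound) with
#'   columns `session_id`, `outcome`, `difficulty`.
#' @return list with `per_session` (session x rank matrix of hit rates),
#'   `mean` and `sem` (length-4 vectors).
#' @export
psychometric_curve <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(trials$difficulty %in% 1:4))
  sessions <- unique(trials$session_id)
  per <- matrix(NA_real_, nrow = length(sessions), ncol = 4L,
                dimnames = list(sessions, paste0("rank", 1:4)))
  for (s in seq_along(sessions)) {
    tr <- trials[trials$session_id == sessions[s], ]
    for (d in 1:4) {
      nc <- sum(tr$outcome == "correct" & tr$difficulty == d)
      nm <- sum(tr$outcome == "miss" & tr$difficulty == d)
      if (nc + nm > 0) per[s, d] <- hit_rate(nc, nm)
    }
  }
  m <- colMeans(per, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  sem <- apply(per, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  })
  list(per_session = per, mean = m, sem = sem)
}

#' Per-session feature means by outcome
#'
#' Computes, for every canonical feature, the mean over correct trials and the
#' mean over incorrect (false alarm + miss) trials in each session. Sessions
#' with fewer than `min_incorrect` incorrect trials (or fewer than 2 correct)
#' are excluded with a reason, mirroring a quality-control threshold.
#'
#' @param features a `trial_features` table (one or more sessions row-bound).
#' @param min_incorrect minimum incorrect-trial count per session.
#' @return data.frame of class `session_feature_summary` with one row per
#'   kept session: `session_id`, `n_correct`, `n_incorrect`, then
#'   `<feature>_correct` and `<feature>_incorrect` columns. Excluded sessions
#'   are recorded in attribute `excluded` (data.frame session_id, reason).
#' @export
session_feature_summary <- function(features, min_incorrect = 10L) {
  stopifnot(is.data.frame(features))
  feats <- canonical_feature_names()
  sessions <- unique(features$session_id)
  rows <- list(); excl <- list()
  for (s in sessions) {
    f <- features[features$session_id == s & features$valid, ]
    cor <- f[f$outcome == "correct", ]
    inc <- f[f$outcome != "correct", ]
    if (nrow(inc) < min_incorrect) {
      excl[[s]] <- sprintf("only %d incorrect trials (min %d)", nrow(inc),
                           min_incorrect)
      next
    }
    if (nrow(cor) < 2L) { excl[[s]] <- "fewer than 2 correct trials"; next }
    row <- data.frame(session_id = s, n_correct = nrow(cor),
                      n_incorrect = nrow(inc), stringsAsFactors = FALSE)
    for (fe in feats) {
      row[[paste0(fe, "_correct")]] <- mean(cor[[fe]])
      row[[paste0(fe, "_incorrect")]] <- mean(inc[[fe]])
    }
    rows[[s]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(session_id = character(0))
  rownames(out) <- NULL
  structure(out, class = c("session_feature_summary", "data.frame"),
            excluded = data.frame(session_id = names(excl),
                                  reason = unlist(excl) %||% character(0),
                                  stringsAsFactors = FALSE))
}

#' Across-session paired comparison of one feature by outcome
#'
#' Two-sided Wilcoxon signed-rank test on the per-session (correct mean,
#' incorrect mean) pairs. The exact null distribution is used for n <= 25
#' sessions with no ties or zero differences; otherwise the normal
#' approximation with continuity and tie correction. If every pair is
#' identical the comparison is degenerate: p = 1 is reported and flagged.
#'
#' @param summaries a [session_feature_summary()].
#' @param feature one canonical feature name.
#' @return one-row data.frame (`outcome_comparison`): feature, test,
#'   statistic, p_value, direction (sign of correct - incorrect), n_sessions,
#'   degenerate flag.
#' @export
session_level_test <- function(summaries, feature) {
  stopifnot(inherits(summaries, "session_feature_summary"),
            feature %in% canonical_feature_names())
  x <- summaries[[paste0(feature, "_correct")]]
  y <- summaries[[paste0(feature, "_incorrect")]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6L)
    stopf("session_level_test needs >= 6 sessions (got %d): p < 0.05 is unattainable below that", n)
  d <- x - y
  if (all(d == 0)) {
    return(data.frame(feature = feature, test = "wilcoxon_signed_rank",
                      statistic = n * (n + 1) / 4, p_value = 1,
                      direction = 0, n = n, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                     exact = n <= 25L, correct = TRUE))
  data.frame(feature = feature, test = "wilcoxon_signed_rank",
             statistic = unname(wt$statistic), p_value = wt$p.value,
             direction = sign(mean(d)), n = n, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Within-session trial-level comparison of one feature by outcome
#'
#' Two-sided two-sample t-test (pooled variance by default, Welch optional)
#' on single-trial feature values, correct vs incorrect, within one session.
#'
#' @param features a `trial_features` table for one session.
#' @param feature one canonical feature name.
#' @param var_equal pooled-variance t-test when `TRUE` (default), Welch
#'   otherwise.
#' @return one-row `outcome_comparison` data.frame, with group means attached
#'   as columns `mean_correct`, `mean_incorrect`.
#' @export
within_session_test <- function(features, feature, var_equal = TRUE) {
  stopifnot(is.data.frame(features), feature %in% canonical_feature_names())
  f <- features[features$valid & is.finite(features[[feature]]), ]
  x <- f[[feature]][f$outcome == "correct"]
  y <- f[[feature]][f$outcome != "correct"]
  if (length(x) < 2L || length(y) < 2L)
    stopf("insufficient %s trials for a within-session test",
          if (length(y) < 2L) "incorrect" else "correct")
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    return(data.frame(feature = feature, test = "two_sample_t",
                      statistic = 0, p_value = 1,
                      direction = sign(mean(x) - mean(y)),
                      n = length(x) + length(y),
                      mean_correct = mean(x), mean_incorrect = mean(y),
                      stringsAsFactors = FALSE))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  data.frame(feature = feature, test = "two_sample_t",
             statistic = unname(tt$statistic), p_value = tt$p.value,
             direction = sign(mean(x) - mean(y)), n = length(x) + length(y),
             mean_correct = mean(x), mean_incorrect = mean(y),
             stringsAsFactors = FALSE)
}

circular_mean_deg <- function(deg) {
  r <- complex(modulus = 1, argument = deg * pi / 180)
  m <- mean(r)
  list(mean = Arg(m) * 180 / pi, resultant = Mod(m))
}

## smallest absolute angular difference, degrees in [0, 180]
ang_diff_deg <- function(a, b) abs(wrap_deg(a - b))

#' Circular comparison of a phase feature by outcome
#'
#' Circular means (atan2 of the mean sine/cosine) per outcome group and a
#' seeded label-permutation p-value on the absolute circular mean difference.
#' A distribution-free permutation null is used because phases need no
#' parametric assumption at these sample sizes.
#'
#' @param features a `trial_features` table.
#' @param phase_feature `"phase_at_trial_start"` or
#'   `"phase_at_fixation_onset"`.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list: `mean_correct`, `mean_incorrect` (degrees), `resultant_*`
#'   lengths, `observed_diff` (degrees), `p_value`, `degenerate` flag (TRUE
#'   when a resultant length underflows and the mean is undefined).
#' @export
circular_summary <- function(features, phase_feature = "phase_at_trial_start",
                             n_perm = 10000L, seed = 1L) {
  stopifnot(phase_feature %in% feature_groups()$phase)
  f <- features[features$valid & is.finite(features[[phase_feature]]), ]
  ph <- f[[phase_feature]]
  grp <- f$outcome == "correct"
  if (sum(grp) < 10L || sum(!grp) < 10L)
    stopf("circular_summary needs >= 10 trials per outcome group")
  mc <- circular_mean_deg(ph[grp])
  mi <- circular_mean_deg(ph[!grp])
  if (mc$resultant < 1e-12 || mi$resultant < 1e-12) {
    return(list(mean_correct = NA_real_, mean_incorrect = NA_real_,
                resultant_correct = mc$resultant,
                resultant_incorrect = mi$resultant,
                observed_diff = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  obs <- ang_diff_deg(mc$mean, mi$mean)
  set.seed(seed)
  perm <- replicate(n_perm, {
    g <- sample(grp)
    ang_diff_deg(circular_mean_deg(ph[g])$mean,
                 circular_mean_deg(ph[!g])$mean)
  })
  list(mean_correct = mc$mean, mean_incorrect = mi$mean,
       resultant_correct = mc$resultant, resultant_incorrect = mi$resultant,
       observed_diff = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       degenerate = FALSE)
}

#' Session-level comparison table over all features
#'
#' Runs [session_level_test()] for every canonical feature and returns the
#' tidy results table. No multiple-testing correction is applied by default
#' (per-feature p-values are reported); `p_adjust = "holm"` applies the Holm
#' step-down correction.
#'
#' @param summaries a [session_feature_summary()].
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return data.frame with one row per feature.
#' @export
compare_features <- function(summaries, p_adjust = "none") {
  out <- do.call(rbind, lapply(canonical_feature_names(),
                               function(f) session_level_test(summaries, f)))
  if (p_adjust != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
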