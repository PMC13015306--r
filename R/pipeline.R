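## Orchestration: one config object drives generation -> conditioning ->
## features -> statistics -> decoding, with an exclusion ledger and a
## machine-readable report. Identical config + seed => identical report.

#' Pipeline configuration
#'
#' Nests the per-stage configurations and the quality-control thresholds.
#' Round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]); unknown keys in a config file are rejected.
#'
#' @param synth a [synth_config()].
#' @param filter a [filter_config()].
#' @param peaks a [peak_config()].
#' @param qc list: `min_incorrect` (per-session minimum incorrect trials),
#'   `max_invalid_frac` (maximum invalid feature-row fraction),
#'   `flatline_sd` (below this raw-signal SD a session is corrupted).
#' @param decode list: `models` (names from [model_zoo()]), `schemes`
#'   (subset of `"5cv"`, `"loso"`), `balance`, `tune`.
#' @param seed global pipeline seed.
#' @param out_dir optional directory for per-stage artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            filter = filter_config(),
                            peaks = peak_config(),
                            qc = list(min_incorrect = 10L,
                                      max_invalid_frac = 0.2,
                                      flatline_sd = 1e-10),
                            decode = list(models = "gradient_boosting",
                                          schemes = "5cv",
                                          balance = TRUE, tune = FALSE),
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(synth, "synth_config"), inherits(filter, "filter_config"),
            inherits(peaks, "peak_config"))
  qc_def <- list(min_incorrect = 10L, max_invalid_frac = 0.2, flatline_sd = 1e-10)
  dec_def <- list(models = "gradient_boosting", schemes = "5cv",
                  balance = TRUE, tune = FALSE)
  check_keys <- function(given, def, where) {
    extra <- setdiff(names(given), names(def))
    if (length(extra)) stopf("unknown %s key(s): %s", where,
                             paste(extra, collapse = ", "))
    utils::modifyList(def, given)
  }
  qc <- check_keys(qc, qc_def, "qc")
  decode <- check_keys(decode, dec_def, "decode")
  bad <- setdiff(decode$models, names(model_zoo()))
  if (length(bad)) stopf("unknown model(s): %s", paste(bad, collapse = ", "))
  if (!all(decode$schemes %in% c("5cv", "loso")))
    stopf("schemes must be among '5cv', 'loso'")
  structure(list(synth = synth, filter = filter, peaks = peaks, qc = qc,
                 decode = decode, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a validated `pipeline_config`;
#'   unknown keys anywhere in the file are an error.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(synth = unclass(config$synth),
                filter = unclass(config$filter),
                peaks = unclass(config$peaks),
                qc = config$qc, decode = config$decode,
                seed = config$seed, out_dir = config$out_dir)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("cannot read config: %s", path)
  raw <- yaml::read_yaml(path)
  top_def <- c("synth", "filter", "peaks", "qc", "decode", "seed", "out_dir")
  extra <- setdiff(names(raw), top_def)
  if (length(extra)) stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  build <- function(fn, given, where) {
    def <- formals(fn)
    extra <- setdiff(names(given), names(def))
    if (length(extra)) stopf("unknown %s key(s): %s", where,
                             paste(extra, collapse = ", "))
    ## drop generator-managed fields not exposed as arguments
    do.call(fn, given[names(given) %in% names(def)])
  }
  synth_given <- raw$synth %||% list()
  synth_given$lead_in <- NULL; synth_given$tail <- NULL
  pipeline_config(
    synth = build(synth_config, synth_given, "synth"),
    filter = build(filter_config, raw$filter %||% list(), "filter"),
    peaks = build(peak_config, raw$peaks %||% list(), "peaks"),
    qc = raw$qc %||% list(),
    decode = raw$decode %||% list(),
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir)
}

#' Validate recordings and trial tables
#'
#' Structural checks before analysis: finite samples and a consistent
#' sampling rate per recording, monotone trial times, outcome labels in the
#' allowed set, and all trial events inside the recording span. Every
#' violation is reported with its location; an empty report means the inputs
#' are well-formed.
#'
#' @param recordings list of `resp_recording` objects.
#' @param trial_tables list of matching trial event data.frames.
#' @return data.frame with columns `session`, `where`, `message`.
#' @export
validate_inputs <- function(recordings, trial_tables) {
  stopifnot(length(recordings) == length(trial_tables))
  out <- list()
  add <- function(session, where, message)
    out[[length(out) + 1L]] <<- data.frame(session = session, where = where,
                                           message = message,
                                           stringsAsFactors = FALSE)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]; tr <- trial_tables[[i]]
    sid <- rec$session_id %||% sprintf("session %d", i)
    if (!all(is.finite(rec$samples)))
      add(sid, "recording", "non-finite samples")
    if (!is_num1(rec$sampling_rate) || rec$sampling_rate <= 0)
      add(sid, "recording", "invalid sampling rate")
    dur <- length(rec$samples) / rec$sampling_rate
    starts <- tr$trial_start_s
    if (any(!is.finite(starts)))
      add(sid, "trials", sprintf("non-finite trial_start at index %s",
                                 paste(tr$trial_index[!is.finite(starts)],
                                       collapse = ",")))
    else if (is.unsorted(starts, strictly = TRUE))
      add(sid, "trials", "trial start times not strictly increasing")
    bad_out <- !tr$outcome %in% c("correct", "false_alarm", "miss")
    if (any(bad_out))
      add(sid, "trials", sprintf("unknown outcome '%s' at index %s",
                                 tr$outcome[which(bad_out)[1]],
                                 paste(tr$trial_index[bad_out], collapse = ",")))
    over <- is.finite(starts) & starts > dur
    if (any(over))
      add(sid, "trials", sprintf("trial_start beyond recording end at index %s",
                                 paste(tr$trial_index[over], collapse = ",")))
    go_over <- is.finite(tr$go_cue_s) & tr$go_cue_s > dur
    if (any(go_over))
      add(sid, "trials", sprintf("go_cue beyond recording end at index %s",
                                 paste(tr$trial_index[go_over], collapse = ",")))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(session = character(0), where = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Generation (or supplied sessions) -> conditioning -> cycle features ->
#' quality control -> outcome statistics -> decoding, with an exclusion
#' ledger recording every dropped session/trial and why. The report is fully
#' determined by the config (which includes the seed); it carries no
#' timestamps, so two runs with the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @param sessions optional list of `list(recording =, trials =)` pairs to
#'   analyze instead of generating synthetic sessions.
#' @return object of class `pipeline_report`: `counts` (sessions/trials in,
#'   analyzed, excluded), `exclusions` (ledger data.frame), `features`
#'   (row-bound trial features of kept sessions), `stats` (comparison table,
#'   psychometrics), `decoding` (list of `decoding_result`), `config_digest`.
#' @export
run_pipeline <- function(config, sessions = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(sessions)) {
    dataset <- generate_dataset(config$synth)
    sessions <- lapply(dataset, function(s) list(recording = s$recording,
                                                 trials = s$trials))
  }
  exclusions <- list()
  note_excl <- function(session, unit, n, reason)
    exclusions[[length(exclusions) + 1L]] <<-
      data.frame(session = session, unit = unit, n = n, reason = reason,
                 stringsAsFactors = FALSE)
  feature_tables <- list()
  trials_in <- 0L
  for (s in sessions) {
    sid <- s$recording$session_id
    trials_in <- trials_in + nrow(s$trials)
    if (sd(s$recording$samples) < config$qc$flatline_sd) {
      note_excl(sid, "session", nrow(s$trials), "flatline recording")
      next
    }
    clean <- tryCatch(condition_signal(s$recording, config$filter),
                      error = function(e)
                        stopf("pipeline stage 'condition' (session %s): %s",
                              sid, conditionMessage(e)))
    feats <- tryCatch(build_trial_features(clean, s$trials, config$peaks),
                      error = function(e)
                        stopf("pipeline stage 'features' (session %s): %s",
                              sid, conditionMessage(e)))
    if (attr(feats, "invalid_fraction") > config$qc$max_invalid_frac) {
      note_excl(sid, "session", nrow(s$trials),
                sprintf("invalid feature fraction %.2f above %.2f",
                        attr(feats, "invalid_fraction"),
                        config$qc$max_invalid_frac))
      next
    }
    n_inc <- sum(feats$valid & feats$outcome != "correct")
    if (n_inc < config$qc$min_incorrect) {
      note_excl(sid, "session", nrow(s$trials),
                sprintf("only %d incorrect trials (min %d)", n_inc,
                        config$qc$min_incorrect))
      next
    }
    if (any(!feats$valid))
      note_excl(sid, "trial", sum(!feats$valid), "no complete cycle after trial start")
    feature_tables[[sid]] <- feats
  }
  if (length(feature_tables) == 0L)
    stopf("pipeline stage 'features': every session was excluded")
  all_feats <- do.call(rbind, lapply(feature_tables, as.data.frame))
  rownames(all_feats) <- NULL
  excl_df <- if (length(exclusions)) do.call(rbind, exclusions)
             else data.frame(session = character(0), unit = character(0),
                             n = integer(0), reason = character(0))
  trials_excluded <- sum(excl_df$n)
  trials_analyzed <- sum(all_feats$valid)
  ## statistics stage
  stats_out <- list(psychometric = psychometric_curve(all_feats))
  summaries <- session_feature_summary(all_feats, config$qc$min_incorrect)
  if (nrow(summaries) >= 6L)
    stats_out$session_comparisons <- compare_features(summaries)
  ## decoding stage
  decoding <- list()
  fm <- tryCatch(assemble_matrix(feature_tables, balance = config$decode$balance,
                                 seed = config$seed),
                 error = function(e) e)
  if (inherits(fm, "error")) {
    decoding$error <- conditionMessage(fm)
  } else {
    for (mod in config$decode$models)
      for (sch in config$decode$schemes) {
        if (sch == "loso" && length(unique(fm$session_id)) < 2L) next
        decoding[[paste(mod, sch, sep = "_")]] <-
          run_cv(fm, mod, sch, seed = config$seed, tune = config$decode$tune)
      }
  }
  report <- structure(list(
    counts = list(sessions_in = length(sessions),
                  sessions_analyzed = length(feature_tables),
                  trials_in = trials_in,
                  trials_analyzed = trials_analyzed,
                  trials_excluded = trials_excluded),
    exclusions = excl_df,
    features = all_feats,
    stats = stats_out,
    decoding = decoding,
    seed = config$seed),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(all_feats, file.path(config$out_dir, "trial_features.csv"))
    utils::write.csv(excl_df, file.path(config$out_dir, "exclusions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## Machine-readable summary (plain lists, JSON-stable ordering).
report_summary <- function(report) {
  dec <- lapply(report$decoding, function(d) {
    if (!inherits(d, "decoding_result")) return(d)
    list(model = d$model, scheme = d$scheme, accuracy = d$accuracy,
         auc = d$auc, fold_accuracy = d$fold_accuracy,
         confusion = as.vector(d$confusion), seed = d$seed)
  })
  list(counts = report$counts,
       exclusions = report$exclusions,
       psychometric_mean = unname(report$stats$psychometric$mean),
       session_comparisons = report$stats$session_comparisons,
       decoding = dec,
       seed = report$seed)
}

#' @export
print.pipeline_report <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("<pipeline_report> %d/%d sessions analyzed, %d/%d trials (%d excluded)\n",
              c0$sessions_analyzed, c0$sessions_in, c0$trials_analyzed,
              c0$trials_in, c0$trials_excluded))
  if (nrow(x$exclusions))
    cat(sprintf("  exclusions: %s\n",
                paste(sprintf("%s[%s: %s]", x$exclusions$session,
                              x$exclusions$unit, x$exclusions$reason),
                      collapse = "; ")))
  if (!is.null(x$stats$session_comparisons)) {
    sig <- x$stats$session_comparisons
    sig <- sig$feature[sig$p_value < 0.05]
    cat(sprintf("  features with session-level p < 0.05: %s\n",
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  for (d in x$decoding)
    if (inherits(d, "decoding_result"))
      cat(sprintf("  %s/%s accuracy %.1f%%, AUC %.3f\n",
                  d$model, d$scheme, 100 * d$accuracy, d$auc))
  invisible(x)
}
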