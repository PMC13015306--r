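## Single-trial outcome decoding from the canonical feature matrix.
##
## Normalization discipline: the assembled matrix stores raw feature values;
## per-feature z-scoring moments are computed on each training partition
## inside the cross-validation and applied to the held-out partition, so no
## information leaks from test to train.

#' Assemble the decoding feature matrix
#'
#' Row-binds per-session `trial_features` tables, drops invalid or non-finite
#' rows (count logged as an attribute), and optionally balances classes by
#' seeded subsampling of the majority class. Labels are binary:
#' correct = 1, incorrect (false alarm or miss) = 0.
#'
#' @param feature_tables a `trial_features` data.frame or list of them.
#' @param balance subsample the majority class to equalize class counts.
#' @param seed RNG seed for the balancing subsample.
#' @param subject_ids optional vector (recycled per table) identifying the
#'   subject each table belongs to.
#' @param drop_phase exclude the two phase features from the matrix.
#' @return object of class `feature_matrix`: `x` (trials x features, raw
#'   scale), `y` (0/1), `session_id`, `subject_id`, `prev_outcome`,
#'   `feature_names`; attribute `n_dropped`.
#' @export
assemble_matrix <- function(feature_tables, balance = FALSE, seed = 1L,
                            subject_ids = NULL, drop_phase = FALSE) {
  if (is.data.frame(feature_tables)) feature_tables <- list(feature_tables)
  if (is.null(subject_ids)) subject_ids <- rep("subject1", length(feature_tables))
  subject_ids <- rep_len(subject_ids, length(feature_tables))
  tabs <- list()
  for (i in seq_along(feature_tables)) {
    tb <- as.data.frame(feature_tables[[i]])
    tb$subject_id <- subject_ids[i]
    ## previous-trial outcome within each session, by trial order
    tb <- tb[order(tb$session_id, tb$trial_index), ]
    tb$prev_outcome <- ave(tb$outcome, tb$session_id,
                           FUN = function(o) c(NA, head(o, -1)))
    tabs[[i]] <- tb
  }
  all_tb <- do.call(rbind, tabs)
  feats <- canonical_feature_names()
  if (drop_phase) feats <- setdiff(feats, feature_groups()$phase)
  x <- as.matrix(all_tb[, feats, drop = FALSE])
  keep <- all_tb$valid & apply(is.finite(x), 1L, all)
  n_dropped <- sum(!keep)
  all_tb <- all_tb[keep, ]; x <- x[keep, , drop = FALSE]
  y <- as.integer(all_tb$outcome == "correct")
  if (balance) {
    set.seed(seed)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 != n0) {
      maj <- which(y == as.integer(n1 > n0))
      keep2 <- sort(c(which(y == as.integer(n1 <= n0)),
                      sample(maj, min(n1, n0))))
      x <- x[keep2, , drop = FALSE]; y <- y[keep2]; all_tb <- all_tb[keep2, ]
    }
  }
  if (length(y) < 50L)
    stopf("only %d trials after filtering; at least 50 are required", length(y))
  structure(list(x = unname(x), y = y,
                 session_id = all_tb$session_id,
                 subject_id = all_tb$subject_id,
                 prev_outcome = all_tb$prev_outcome,
                 feature_names = feats),
            class = "feature_matrix", n_dropped = n_dropped)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features, %d sessions, %d/%d correct/incorrect\n",
              nrow(x$x), ncol(x$x), length(unique(x$session_id)),
              sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

## z-scoring moments from a training partition; constant columns get SD 1
## so they pass through as zeros rather than NaN.
train_moments <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2L, sd)
  sig[!is.finite(sig) | sig < 1e-12] <- 1
  list(mu = mu, sig = sig)
}

apply_moments <- function(x, m) sweep(sweep(x, 2L, m$mu), 2L, m$sig, "/")

## Stratified k-fold assignment (seeded): shuffles within class then deals
## round-robin, so fold class proportions match the data.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- sample(which(y == cls))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

tune_params <- function(spec, x, y, seed, inner_k = 4L) {
  grid <- spec$grid
  if (nrow(grid) == 1L) return(as.list(grid[1L, , drop = FALSE]))
  fold <- stratified_folds(y, inner_k, child_seed(seed, 7L))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(inner_k)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2L) next
      m <- train_moments(x[tr, , drop = FALSE])
      model <- spec$fit(apply_moments(x[tr, , drop = FALSE], m), y[tr],
                        as.list(grid[g, , drop = FALSE]),
                        child_seed(seed, 100L + f))
      sc <- spec$score(model, apply_moments(x[te, , drop = FALSE], m))
      correct <- correct + sum((sc >= 0.5) == (y[te] == 1L))
      total <- total + sum(te)
    }
    acc[g] <- if (total > 0) correct / total else 0
  }
  as.list(grid[which.max(acc), , drop = FALSE])  # ties: first row in grid order
}

#' Cross-validated decoding
#'
#' Two schemes: `"5cv"` - stratified five-fold cross-validation over pooled
#' trials, with hyperparameters tuned by an inner stratified 4-fold search on
#' each training partition; `"loso"` - leave-one-session-out, one fold per
#' session, tuning on the remaining sessions. Feature z-scoring moments are
#' computed on each training partition only. Fully reproducible under a fixed
#' seed (per-fold child seeds are derived deterministically).
#'
#' @param matrix a [assemble_matrix()] result.
#' @param model a model name from [model_zoo()] or a spec.
#' @param scheme `"5cv"` or `"loso"`.
#' @param seed pipeline-level RNG seed.
#' @param tune run the inner hyperparameter search (`FALSE` uses the spec's
#'   default parameters).
#' @param grid optional replacement hyperparameter grid (e.g. reduced for
#'   large sweeps).
#' @param n_folds number of folds for `"5cv"`.
#' @return object of class `decoding_result`: model, scheme, `fold_accuracy`,
#'   `accuracy` (pooled trace / total), `auc` (pooled over held-out scores),
#'   `confusion` (2x2 counts, truth x prediction), `folds` (assignment),
#'   `params` (chosen per fold), `seed`.
#' @export
run_cv <- function(matrix, model = "gradient_boosting", scheme = c("5cv", "loso"),
                   seed = 1L, tune = TRUE, grid = NULL, n_folds = 5L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  scheme <- match.arg(scheme)
  spec <- if (is.character(model)) model_zoo(model) else model
  if (!is.null(grid)) spec$grid <- as.data.frame(grid)
  x <- matrix$x; y <- matrix$y
  if (scheme == "5cv") {
    fold <- stratified_folds(y, n_folds, seed)
    fold_ids <- seq_len(n_folds)
  } else {
    sess <- unique(matrix$session_id)
    if (length(sess) < 2L) stopf("LOSO needs >= 2 sessions")
    fold <- match(matrix$session_id, sess)
    fold_ids <- seq_along(sess)
  }
  n <- length(y)
  score <- pred <- rep(NA_real_, n)
  fold_acc <- numeric(length(fold_ids))
  params <- vector("list", length(fold_ids))
  for (f in fold_ids) {
    te <- fold == f; tr <- !te
    if (length(unique(y[tr])) < 2L)
      stopf("fold %d has a single class in training", f)
    p <- if (tune) tune_params(spec, x[tr, , drop = FALSE], y[tr],
                               child_seed(seed, f))
         else spec$default
    m <- train_moments(x[tr, , drop = FALSE])
    fitted <- spec$fit(apply_moments(x[tr, , drop = FALSE], m), y[tr],
                       p, child_seed(seed, 1000L + f))
    sc <- spec$score(fitted, apply_moments(x[te, , drop = FALSE], m))
    score[te] <- sc
    pred[te] <- as.integer(sc >= 0.5)
    fold_acc[f] <- mean(pred[te] == y[te])
    params[[f]] <- p
  }
  confusion <- table(truth = factor(y, levels = c(0, 1)),
                     prediction = factor(pred, levels = c(0, 1)))
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                        levels = c("0", "1"),
                                        direction = "<", quiet = TRUE)))
  structure(list(model = spec$name, scheme = scheme,
                 fold_accuracy = fold_acc,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 auc = auc, confusion = unclass(confusion),
                 folds = fold, params = params, seed = seed,
                 n_trials = n),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s / %s: accuracy %.1f%% (folds %s), AUC %.3f, n=%d\n",
              x$model, x$scheme, 100 * x$accuracy,
              paste(sprintf("%.0f%%", 100 * x$fold_accuracy), collapse = " "),
              x$auc, x$n_trials))
  print(x$confusion)
  invisible(x)
}

#' Gradient-boosting feature importance
#'
#' Fits the gradient-boosting model on the full (normalized) matrix and
#' returns per-feature gain importance, normalized to sum to 1. Features the
#' booster never used score 0. Ties keep canonical feature order.
#'
#' @param matrix a `feature_matrix` (balance it first for interpretability).
#' @param seed RNG seed.
#' @param params optional list overriding the spec's default parameters.
#' @return named numeric vector over `matrix$feature_names`, summing to 1.
#' @export
feature_importance <- function(matrix, seed = 1L, params = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  m <- train_moments(matrix$x)
  sig0 <- apply(matrix$x, 2L, sd)
  if (all(!is.finite(sig0) | sig0 < 1e-12))
    stopf("degenerate fit: all features are constant")
  spec <- model_zoo("gradient_boosting")
  x <- apply_moments(matrix$x, m)
  colnames(x) <- matrix$feature_names
  fitted <- spec$fit(x, matrix$y, params %||% spec$default, seed)
  imp <- xgboost::xgb.importance(model = fitted)
  out <- setNames(numeric(length(matrix$feature_names)), matrix$feature_names)
  out[imp$Feature] <- imp$Gain
  if (sum(out) <= 0) stopf("degenerate fit: no informative split found")
  out / sum(out)
}

#' Exhaustive feature-combination sweep
#'
#' For every feature count k, evaluates all `choose(p, k)` feature subsets
#' with cross-validated accuracy at a fixed seed (folds are fixed across
#' subsets so accuracies are comparable). Ties for the best subset keep the
#' lexicographically first combination in canonical order.
#'
#' @param matrix a `feature_matrix`.
#' @param model model name or spec (tuning is off by default here; pass
#'   `grid` via `...` of [run_cv()] through `cv_args` if needed).
#' @param seed RNG seed shared by every subset evaluation.
#' @param max_features combinatorial guard: errors above this count.
#' @param tune forwarded to [run_cv()] (default `FALSE`: the model's default
#'   hyperparameters, which keeps the sweep at desk scale).
#' @param ks feature counts to evaluate (default all of `1:p`).
#' @return list: `by_k` data.frame (k, n_subsets, mean_accuracy,
#'   best_accuracy), `best_sets` (named list of feature-name vectors per k).
#' @export
combination_sweep <- function(matrix, model = "gradient_boosting", seed = 1L,
                              max_features = 14L, tune = FALSE, ks = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  p <- ncol(matrix$x)
  if (p > max_features)
    stopf("%d features exceeds the exhaustive-sweep guard (%d); use a greedy search instead",
          p, max_features)
  spec <- if (is.character(model)) model_zoo(model) else model
  ks <- as.integer(ks %||% seq_len(p))
  stopifnot(all(ks >= 1L & ks <= p))
  by_k <- data.frame(k = ks, n_subsets = choose(p, ks),
                     mean_accuracy = NA_real_, best_accuracy = NA_real_)
  best_sets <- setNames(vector("list", length(ks)), paste0("k", ks))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    combs <- combn(p, k)
    accs <- numeric(ncol(combs))
    for (ci in seq_len(ncol(combs))) {
      sub <- matrix
      sub$x <- matrix$x[, combs[, ci], drop = FALSE]
      sub$feature_names <- matrix$feature_names[combs[, ci]]
      accs[ci] <- run_cv(sub, spec, scheme = "5cv", seed = seed,
                         tune = tune)$accuracy
    }
    best <- which.max(accs)  # first max = lexicographically first subset
    by_k$mean_accuracy[ki] <- mean(accs)
    by_k$best_accuracy[ki] <- accs[best]
    best_sets[[ki]] <- matrix$feature_names[combs[, best]]
  }
  list(by_k = by_k, best_sets = best_sets)
}

#' Decoding restricted to trials following a correct trial
#'
#' Holds recent-reward context constant: keeps only trials whose previous
#' trial (within session) was correct, drops each session's first trial (no
#' predecessor), rebalances, and reruns the cross-validation.
#'
#' @param matrix a `feature_matrix` built with `balance = FALSE` (the subset
#'   is rebalanced here).
#' @param model,scheme,seed,... forwarded to [run_cv()].
#' @return a `decoding_result` for the history-controlled subset.
#' @export
history_controlled <- function(matrix, model = "gradient_boosting",
                               scheme = "5cv", seed = 1L, ...) {
  stopifnot(inherits(matrix, "feature_matrix"))
  keep <- !is.na(matrix$prev_outcome) & matrix$prev_outcome == "correct"
  if (sum(keep) < 50L)
    stopf("only %d trials follow a correct trial; at least 50 are required",
          sum(keep))
  sub <- subset_matrix(matrix, keep)
  sub <- rebalance_matrix(sub, seed)
  run_cv(sub, model, scheme, seed = seed, ...)
}

subset_matrix <- function(matrix, keep) {
  structure(list(x = matrix$x[keep, , drop = FALSE], y = matrix$y[keep],
                 session_id = matrix$session_id[keep],
                 subject_id = matrix$subject_id[keep],
                 prev_outcome = matrix$prev_outcome[keep],
                 feature_names = matrix$feature_names),
            class = "feature_matrix")
}

rebalance_matrix <- function(matrix, seed) {
  y <- matrix$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) return(matrix)
  set.seed(seed)
  maj <- which(y == as.integer(n1 > n0))
  keep <- sort(c(which(y == as.integer(n1 <= n0)), sample(maj, min(n1, n0))))
  subset_matrix(matrix, seq_along(y) %in% keep)
}

#' Pool feature matrices across subjects
#'
#' Concatenates per-subject matrices (subject id retained for bookkeeping,
#' never as a model input) and reruns the cross-validation; normalization is
#' still computed per training partition inside [run_cv()].
#'
#' @param matrices list of `feature_matrix` objects with identical canonical
#'   feature order.
#' @param model,scheme,seed,... forwarded to [run_cv()].
#' @return a `decoding_result` on the pooled trials.
#' @export
pooled_subjects <- function(matrices, model = "gradient_boosting",
                            scheme = "5cv", seed = 1L, ...) {
  stopifnot(length(matrices) >= 2L,
            all(vapply(matrices, inherits, logical(1), "feature_matrix")))
  fn <- matrices[[1]]$feature_names
  for (m in matrices)
    if (!identical(m$feature_names, fn))
      stopf("feature order mismatch between pooled subjects")
  pooled <- structure(list(
    x = do.call(rbind, lapply(matrices, `[[`, "x")),
    y = unlist(lapply(matrices, `[[`, "y")),
    session_id = unlist(lapply(matrices, `[[`, "session_id")),
    subject_id = unlist(lapply(matrices, `[[`, "subject_id")),
    prev_outcome = unlist(lapply(matrices, `[[`, "prev_outcome")),
    feature_names = fn), class = "feature_matrix")
  run_cv(pooled, model, scheme, seed = seed, ...)
}
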