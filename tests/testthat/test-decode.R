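test_that("matrix assembly stacks sessions, drops invalid rows, and balances reproducibly", {
  tabs <- lapply(1:3, function(i) sim_feature_table(100, paste0("S", i), i))
  fm <- assemble_matrix(tabs)
  expect_equal(dim(fm$x), c(300L, 12L))
  expect_equal(fm$feature_names, feature_groups()$all)
  ## invalid rows dropped but logged
  tabs[[1]]$valid[1:7] <- FALSE
  fm2 <- assemble_matrix(tabs)
  expect_equal(nrow(fm2$x), 293L)
  expect_equal(attr(fm2, "n_dropped"), 7L)
  ## balancing: seeded subsample of the majority class
  tab <- sim_feature_table(300, "S1", 5, p_correct = 0.7)
  fmb1 <- assemble_matrix(tab, balance = TRUE, seed = 11)
  fmb2 <- assemble_matrix(tab, balance = TRUE, seed = 11)
  expect_identical(fmb1$x, fmb2$x)
  expect_equal(sum(fmb1$y == 1), sum(fmb1$y == 0))
  fmb3 <- assemble_matrix(tab, balance = TRUE, seed = 12)
  expect_false(identical(fmb1$x, fmb3$x))
  ## too few trials
  expect_error(assemble_matrix(sim_feature_table(49, "S1", 1)), "at least 50")
})

test_that("previous-trial outcome is tracked per session for the history control", {
  tab <- sim_feature_table(60, "S1", 3)
  fm <- assemble_matrix(tab)
  expect_true(is.na(fm$prev_outcome[1]))
  expect_equal(fm$prev_outcome[-1], tab$outcome[-nrow(tab)])
})

test_that("normalization moments come from the training partition only", {
  tabs <- lapply(1:2, function(i) sim_feature_table(100, paste0("S", i), i))
  ## shift session 2 far away: its columns are far from zero under session-1
  ## moments, which is exactly what no-leakage normalization implies
  tabs[[2]][, feature_groups()$all] <- tabs[[2]][, feature_groups()$all] + 5
  fm <- assemble_matrix(tabs)
  tr <- fm$session_id == "S1"
  m <- breathdecode:::train_moments(fm$x[tr, ])
  ztr <- breathdecode:::apply_moments(fm$x[tr, ], m)
  zte <- breathdecode:::apply_moments(fm$x[!tr, ], m)
  expect_true(all(abs(colMeans(ztr)) < 1e-8))
  expect_true(all(abs(apply(ztr, 2, sd) - 1) < 1e-6))
  expect_true(all(colMeans(zte) > 3))   # test fold keeps its shift
})

test_that("the registry holds five models whose specs serialize round-trip", {
  zoo <- model_zoo()
  expect_setequal(names(zoo),
                  c("gradient_boosting", "random_forest", "svm", "knn", "mlp"))
  expect_error(model_zoo("boosted_ferns"), "registry")
  for (spec in zoo) {
    cfgl <- breathdecode:::model_spec_config(spec)
    f <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfgl, f)
    back <- yaml::read_yaml(f)
    expect_equal(back$name, spec$name)
    expect_equal(as.data.frame(back$grid), spec$grid,
                 ignore_attr = TRUE)
  }
})

test_that("every model separates a perfectly informative feature and trains fast", {
  tab <- sim_feature_table(100, "S1", 2)
  tab[, feature_groups()$all] <- 0   # noiseless separable limit
  tab$inhalation_onset_latency <- ifelse(tab$outcome == "correct", 3, -3)
  fm <- assemble_matrix(tab)
  t0 <- Sys.time()
  for (m in names(model_zoo())) {
    res <- run_cv(fm, m, "5cv", seed = 4, tune = FALSE)
    expect_equal(res$accuracy, 1.0)
    expect_equal(res$auc, 1.0)
    expect_equal(sum(res$confusion), res$n_trials)
    expect_equal(sum(diag(res$confusion)) / sum(res$confusion), res$accuracy,
                 tolerance = 1e-12)
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
})

test_that("decoding is reproducible under a fixed seed and near chance on permuted labels", {
  tab <- sim_feature_table(300, "S1", 6, p_correct = 0.5)
  fm <- assemble_matrix(tab)
  set.seed(99); fm$y <- sample(fm$y)   # destroy any association
  for (m in c("gradient_boosting", "knn")) {
    r1 <- run_cv(fm, m, "5cv", seed = 21, tune = FALSE)
    r2 <- run_cv(fm, m, "5cv", seed = 21, tune = FALSE)
    expect_identical(r1$fold_accuracy, r2$fold_accuracy)
    expect_identical(r1$confusion, r2$confusion)
    expect_gt(r1$accuracy, 0.38); expect_lt(r1$accuracy, 0.62)
  }
})

test_that("LOSO holds one session out per fold and needs at least two sessions", {
  tabs <- lapply(1:3, function(i)
    sim_feature_table(80, paste0("S", i), 30 + i,
                      shift = list(respiration_length = 1.5)))
  fm <- assemble_matrix(tabs)
  res <- run_cv(fm, "knn", "loso", seed = 2, tune = FALSE)
  expect_length(res$fold_accuracy, 3L)
  for (f in 1:3)
    expect_true(all(fm$session_id[res$folds == f] == paste0("S", f)))
  expect_gt(res$accuracy, 0.6)
  one <- assemble_matrix(tabs[[1]])
  expect_error(run_cv(one, "knn", "loso", seed = 2), ">= 2 sessions")
})

test_that("feature importance concentrates on a planted feature and sums to one", {
  tab <- sim_feature_table(400, "S1", 8, p_correct = 0.5,
                           shift = list(exhalation_duration = 2.5))
  fm <- assemble_matrix(tab, balance = TRUE, seed = 2)
  imp <- feature_importance(fm, seed = 3)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_gt(imp[["exhalation_duration"]], 0.5)
  ## all-constant features cannot be fit
  fm0 <- fm; fm0$x[] <- 1
  expect_error(feature_importance(fm0, seed = 3), "degenerate")
})

test_that("the combination sweep enumerates subsets exactly and finds the planted feature", {
  tab <- sim_feature_table(120, "S1", 12, p_correct = 0.5,
                           shift = list(inhalation_onset_latency = 2.5))
  fm <- assemble_matrix(tab)
  sw <- combination_sweep(fm, "knn", seed = 5, ks = c(1, 2, 12))
  expect_equal(sw$by_k$n_subsets, choose(12, c(1, 2, 12)))
  expect_equal(sw$by_k$n_subsets[2], 66)
  expect_equal(sw$best_sets$k1, "inhalation_onset_latency")
  ## k = p has a single subset equal to the full model at the same seed
  full <- run_cv(fm, "knn", "5cv", seed = 5, tune = FALSE)
  expect_equal(sw$by_k$best_accuracy[3], full$accuracy)
  expect_equal(sw$by_k$mean_accuracy[3], full$accuracy)
  ## the guard refuses unreasonably wide sweeps
  expect_error(combination_sweep(fm, "knn", max_features = 10), "guard")
})

test_that("history control keeps only trials following a correct trial", {
  tab <- sim_feature_table(200, "S1", 14, p_correct = 0.6,
                           shift = list(respiration_length = 1.5))
  fm <- assemble_matrix(tab)
  res <- history_controlled(fm, "knn", "5cv", seed = 3, tune = FALSE)
  n_follow <- sum(tab$outcome[-nrow(tab)] == "correct")
  expect_lte(res$n_trials, n_follow)     # rebalancing may subsample further
  ## an all-correct session: every trial but the first survives the filter
  tab2 <- sim_feature_table(120, "S1", 15, p_correct = 0.5)
  tab2$outcome[] <- "correct"
  fm2 <- assemble_matrix(tab2)
  keep <- !is.na(fm2$prev_outcome) & fm2$prev_outcome == "correct"
  expect_equal(sum(keep), 119L)
  expect_error(history_controlled(assemble_matrix(
    sim_feature_table(60, "S1", 16, p_correct = 0.1)), "knn"),
    "at least 50")
})

test_that("subject pooling preserves trial counts and never feeds ids to the model", {
  fmA <- assemble_matrix(lapply(1:2, function(i)
    sim_feature_table(80, paste0("A", i), 50 + i,
                      shift = list(respiration_length = 1.5))),
    subject_ids = "monkeyA")
  fmB <- assemble_matrix(lapply(1:2, function(i)
    sim_feature_table(80, paste0("B", i), 60 + i,
                      shift = list(respiration_length = 1.5))),
    subject_ids = "monkeyB")
  res <- pooled_subjects(list(fmA, fmB), "knn", "5cv", seed = 9, tune = FALSE)
  expect_equal(res$n_trials, nrow(fmA$x) + nrow(fmB$x))
  expect_equal(ncol(fmA$x), 12L)   # subject id is bookkeeping, not a column
  indA <- run_cv(fmA, "knn", "5cv", seed = 9, tune = FALSE)
  expect_lt(abs(res$accuracy - indA$accuracy), 0.12)
  bad <- fmB; bad$feature_names <- rev(bad$feature_names)
  expect_error(pooled_subjects(list(fmA, bad), "knn"), "mismatch")
})

test_that("inner tuning selects from the declared grid", {
  tab <- sim_feature_table(150, "S1", 70, p_correct = 0.5,
                           shift = list(respiration_length = 1.2))
  fm <- assemble_matrix(tab)
  res <- run_cv(fm, "knn", "5cv", seed = 31, tune = TRUE)
  ks <- vapply(res$params, `[[`, numeric(1), "k")
  expect_true(all(ks %in% model_zoo("knn")$grid$k))
  ## a reduced grid override is honoured
  res2 <- run_cv(fm, "knn", "5cv", seed = 31, tune = TRUE,
                 grid = data.frame(k = 5L))
  expect_true(all(vapply(res2$params, `[[`, numeric(1), "k") == 5L))
})
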