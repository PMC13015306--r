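## Classifier registry. Each spec declares its hyperparameter grid, a default
## parameter row, a determinism class, and fit / score closures working on a
## plain numeric matrix and 0/1 labels. Scores are probabilities (or
## monotone decision values mapped through a logistic for the SVM) for the
## positive class (correct = 1), so AUC orientation is fixed, never inferred.

fit_gb <- function(x, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = params$max_depth,
                                   eta = params$eta, nthread = 1),
                     data = dtrain, nrounds = params$nrounds, verbose = 0)
}

fit_rf <- function(x, y, params, seed) {
  set.seed(seed)
  randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                             ntree = params$ntree, mtry = params$mtry)
}

fit_svm <- function(x, y, params, seed) {
  set.seed(seed)
  e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
             cost = params$cost, scale = FALSE)
}

fit_knn <- function(x, y, params, seed) {
  list(train_x = x, train_y = factor(y, levels = c(0, 1)), k = params$k)
}

fit_mlp <- function(x, y, params, seed) {
  set.seed(seed)
  nnet::nnet(x, y, size = params$size, decay = params$decay, maxit = 300,
             entropy = TRUE, trace = FALSE, MaxNWts = 5000)
}

score_gb <- function(model, x)
  as.numeric(predict(model, xgboost::xgb.DMatrix(x, nthread = 1)))
score_rf <- function(model, x) unname(predict(model, x, type = "prob")[, "1"])
score_svm <- function(model, x) {
  p <- predict(model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  d <- if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]  # orient toward "1"
  1 / (1 + exp(-unname(d)))
}
score_knn <- function(model, x) {
  pr <- class::knn(model$train_x, x, model$train_y, k = model$k, prob = TRUE)
  p <- attr(pr, "prob")
  ifelse(pr == "1", p, 1 - p)
}
score_mlp <- function(model, x) as.numeric(predict(model, x))

#' Registry of decoding models
#'
#' Five classifier families: gradient-boosted trees, random forest, RBF
#' support vector machine, k-nearest neighbours, and a single-hidden-layer
#' multi-layer perceptron. Each spec carries a small fixed hyperparameter
#' grid (tuned by inner cross-validation in [run_cv()]), a default parameter
#' row used when tuning is off, and its determinism class: `svm` and `knn`
#' are deterministic given the data; the tree ensembles and the MLP are
#' seeded-stochastic.
#'
#' @param name optional single model name to retrieve; errors with the list
#'   of known names when unknown.
#' @return a named list of model specs (or a single spec when `name` given).
#' @export
model_zoo <- function(name = NULL) {
  zoo <- list(
    gradient_boosting = list(
      name = "gradient_boosting", deterministic = FALSE,
      grid = expand.grid(nrounds = c(100L, 300L), max_depth = c(2L, 3L, 5L),
                         eta = c(0.05, 0.1)),
      default = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
      fit = fit_gb, score = score_gb),
    random_forest = list(
      name = "random_forest", deterministic = FALSE,
      grid = expand.grid(ntree = 300L, mtry = c(2L, 3L, 6L)),
      default = list(ntree = 300L, mtry = 3L),
      fit = fit_rf, score = score_rf),
    svm = list(
      name = "svm", deterministic = TRUE,
      grid = expand.grid(cost = c(0.1, 1, 10)),
      default = list(cost = 1),
      fit = fit_svm, score = score_svm),
    knn = list(
      name = "knn", deterministic = TRUE,
      grid = expand.grid(k = c(5L, 15L, 31L)),
      default = list(k = 15L),
      fit = fit_knn, score = score_knn),
    mlp = list(
      name = "mlp", deterministic = FALSE,
      grid = expand.grid(size = c(16L, 64L), decay = 0.01),
      default = list(size = 16L, decay = 0.01),
      fit = fit_mlp, score = score_mlp))
  if (is.null(name)) return(zoo)
  if (!name %in% names(zoo))
    stopf("unknown model '%s'; registry: %s", name,
          paste(names(zoo), collapse = ", "))
  zoo[[name]]
}

## Serializable summary of a spec (grids and scalars, no closures).
model_spec_config <- function(spec) {
  list(name = spec$name, deterministic = spec$deterministic,
       grid = as.list(spec$grid), default = spec$default)
}
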