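# The eleven-classifier benchmark: specs, fitting, probability prediction,
# and grid search under stratified cross-validation scored by weighted F1.
#
# Fixed configuration follows the study protocol: tree ensembles use
# 100-200 estimators with depth caps (15 for forests, 6 for boosting),
# boosting uses learning rate 0.1, the MLP is (100, 50) with ReLU, and the
# deep network is 128-64-32-16-1 with dropout 0.25 and batch normalization.
# Tuning grids are deliberately small and live here in the spec list, not
# in the fitting code.

MODEL_NAMES <- c("forest", "extra_random_trees", "gradient_boosting",
                 "xgboost_variant", "lightgbm_variant", "logistic", "knn",
                 "naive_bayes", "svm_rbf", "mlp", "deep_net")

#' Benchmark model specifications
#'
#' One spec per algorithm: fixed hyperparameters plus a (possibly
#' singleton) tuning grid. A singleton grid makes [tune_and_train()]
#' equivalent to plain training.
#'
#' @param seed seed recorded into every spec.
#' @return named list of specs (name, fixed, grid, seed).
#' @export
model_specs <- function(seed = 42) {
  grid1 <- list(list())  # singleton grid
  specs <- list(
    forest = list(fixed = list(max_depth = 15),
                  grid = list(list(num_trees = 100), list(num_trees = 200))),
    extra_random_trees = list(fixed = list(max_depth = 15),
                              grid = list(list(num_trees = 100), list(num_trees = 200))),
    gradient_boosting = list(fixed = list(max_depth = 3, eta = 0.1),
                             grid = list(list(nrounds = 100), list(nrounds = 200))),
    xgboost_variant = list(fixed = list(max_depth = 6, eta = 0.1),
                           grid = list(list(nrounds = 100), list(nrounds = 200))),
    lightgbm_variant = list(fixed = list(max_depth = 6, eta = 0.1, max_leaves = 31),
                            grid = list(list(nrounds = 100), list(nrounds = 200))),
    logistic = list(fixed = list(),
                    grid = list(list(C = 0.1), list(C = 1), list(C = 10))),
    knn = list(fixed = list(),
               grid = list(list(k = 5), list(k = 11), list(k = 21))),
    naive_bayes = list(fixed = list(), grid = grid1),
    svm_rbf = list(fixed = list(cost = 1), grid = grid1),
    mlp = list(fixed = list(hidden = c(100, 50), dropout = 0, batchnorm = FALSE),
               grid = grid1),
    deep_net = list(fixed = list(hidden = c(128, 64, 32, 16), dropout = 0.25,
                                 batchnorm = TRUE),
                    grid = grid1)
  )
  for (nm in names(specs)) {
    specs[[nm]]$name <- nm
    specs[[nm]]$seed <- seed
  }
  specs
}

#' Fit one benchmark model with explicit hyperparameters
#'
#' @param name one of `MODEL_NAMES`.
#' @param params named list of hyperparameters (fixed + grid point merged).
#' @param x,y training features (numeric data.frame/matrix) and 0/1 labels.
#' @param seed RNG seed for stochastic learners.
#' @return object of class `gdm_model` wrapping the fitted learner.
#' @export
fit_model <- function(name, params, x, y, seed = 42) {
  x <- as.data.frame(x)
  fit <- switch(
    name,
    forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees %||% 100, max.depth = params$max_depth %||% 15,
      seed = seed, num.threads = 1),
    extra_random_trees = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees %||% 100, max.depth = params$max_depth %||% 15,
      splitrule = "extratrees", num.random.splits = 1,
      seed = seed, num.threads = 1),
    gradient_boosting = xgb_fit(x, y, params, seed, tree_method = "exact"),
    xgboost_variant = xgb_fit(x, y, params, seed, tree_method = "exact"),
    lightgbm_variant = xgb_fit(x, y, params, seed, tree_method = "hist",
                               grow_policy = "lossguide",
                               max_leaves = params$max_leaves %||% 31),
    logistic = {
      lam <- 1 / ((params$C %||% 1) * nrow(x))
      glmnet::glmnet(as.matrix(x), y, family = "binomial", alpha = 0,
                     lambda = lam, standardize = FALSE)
    },
    knn = list(train = as.matrix(x), y = y, k = params$k %||% 5),
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    svm_rbf = {
      set.seed(seed)
      e1071::svm(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                 kernel = "radial", cost = params$cost %||% 1,
                 probability = TRUE)
    },
    mlp = ,
    deep_net = mlp_train(x, y, hidden = params$hidden,
                         dropout = params$dropout %||% 0,
                         batchnorm = isTRUE(params$batchnorm),
                         max_epochs = params$max_epochs %||% 120,
                         seed = seed),
    stop("unknown model: ", name)
  )
  structure(list(name = name, fit = fit, params = params,
                 features = colnames(x), seed = seed),
            class = "gdm_model")
}

xgb_fit <- function(x, y, params, seed, ...) {
  extra <- list(...)
  set.seed(seed)
  pars <- c(list(objective = "binary:logistic", max_depth = params$max_depth %||% 6,
                 eta = params$eta %||% 0.1, nthread = 1, seed = seed), extra)
  pars$max_leaves <- extra$max_leaves %||% 0
  xgboost::xgb.train(params = pars,
                     data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
                     nrounds = params$nrounds %||% 100, verbose = 0)
}

#' Positive-class probability predictions from any benchmark model
#'
#' @param model a `gdm_model`.
#' @param x feature matrix/data.frame on the training scale.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, x) {
  x <- as.data.frame(x)[, model$features, drop = FALSE]
  fit <- model$fit
  switch(
    model$name,
    forest = ,
    extra_random_trees = predict(fit, x, num.threads = 1)$predictions[, "1"],
    gradient_boosting = ,
    xgboost_variant = ,
    lightgbm_variant = predict(fit, xgboost::xgb.DMatrix(as.matrix(x))),
    logistic = as.numeric(predict(fit, as.matrix(x), type = "response")),
    knn = {
      pr <- class::knn(fit$train, as.matrix(x), factor(fit$y, levels = c(0, 1)),
                       k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    naive_bayes = predict(fit, x, type = "raw")[, "1"],
    svm_rbf = {
      pr <- predict(fit, as.matrix(x), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    mlp = ,
    deep_net = predict(fit, x),
    stop("unknown model: ", model$name)
  )
}

# stratified fold assignment for cross-validation
cv_folds_assign <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Grid search under stratified cross-validation, then refit
#'
#' Exhaustive search over the spec's grid, scored by support-weighted F1
#' under stratified k-fold cross-validation on the training partition only;
#' the winning grid point (ties: first listed) is refit on the full
#' training data. A singleton grid skips cross-validation entirely and is
#' identical to plain training.
#'
#' @param spec one element of [model_specs()].
#' @param x,y training features and 0/1 labels (balanced and scaled).
#' @param cv_folds number of stratified folds (default 10).
#' @param seed RNG seed for fold assignment and fitting.
#' @return list: `model` (refit `gdm_model`), `best_params`, `cv_results`
#'   (one row per grid point, NA score for singleton grids).
#' @export
tune_and_train <- function(spec, x, y, cv_folds = 10, seed = spec$seed %||% 42) {
  stopifnot(length(spec$grid) >= 1)
  scores <- rep(NA_real_, length(spec$grid))
  if (length(spec$grid) > 1) {
    fold <- cv_folds_assign(y, cv_folds, stage_seed(seed, paste0("cv_", spec$name)))
    if (min(table(fold, y)) < 1) {
      stop("degenerate fold with a single class; use fewer folds")
    }
    for (g in seq_along(spec$grid)) {
      params <- utils::modifyList(spec$fixed, spec$grid[[g]])
      f1s <- numeric(cv_folds)
      for (k in seq_len(cv_folds)) {
        tr <- fold != k
        m <- fit_model(spec$name, params, x[tr, , drop = FALSE], y[tr], seed)
        prob <- predict_prob(m, x[!tr, , drop = FALSE])
        cm <- confusion_matrix(y[!tr], as.integer(prob >= 0.5))
        f1s[k] <- confusion_metrics(cm)$weighted_f1
      }
      scores[g] <- mean(f1s)
    }
    best <- which.max(scores)   # ties: first grid point
  } else {
    best <- 1L
  }
  best_params <- utils::modifyList(spec$fixed, spec$grid[[best]])
  model <- fit_model(spec$name, best_params, x, y, seed)
  list(model = model, best_params = best_params,
       cv_results = data.frame(grid_point = seq_along(spec$grid),
                               weighted_f1 = scores))
}

#' Train and evaluate the full benchmark
#'
#' @param train_x,train_y SMOTE-balanced, scaled training partition.
#' @param test_x,test_y original-distribution test partition.
#' @param models character vector of model names (default: all eleven).
#' @param cv_folds stratified CV folds for grid search.
#' @param seed root seed.
#' @return list with `leaderboard` (data.frame ranked by weighted F1),
#'   `rows` (full metric rows), `fits` (tuning output per model).
#' @export
run_benchmark <- function(train_x, train_y, test_x, test_y,
                          models = MODEL_NAMES, cv_folds = 10, seed = 42) {
  specs <- model_specs(seed)[models]
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    tt <- tune_and_train(specs[[nm]], train_x, train_y, cv_folds, seed)
    fits[[nm]] <- tt
    rows[[nm]] <- evaluate(tt$model, test_x, test_y)
  }
  list(leaderboard = rank_models(rows), rows = rows, fits = fits)
}
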