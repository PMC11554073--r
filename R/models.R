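#' Neural-network classifier configuration
#'
#' Reference architecture: two hidden layers (64, 32 units), ReLU, dropout
#' 0.3, Adam, 300 epochs with minibatches of 16, and a two-neuron softmax
#' output head for the binary endpoint (KPS < 70 vs >= 70). All settings are
#' overridable per run.
#'
#' @param hidden_widths Integer vector of hidden-layer widths.
#' @param dropout Dropout rate applied after each hidden layer in training.
#' @param epochs,batch_size,learning_rate,seed Optimization settings.
#' @param class_weighting `"none"` or `"balanced"` (inverse-prevalence
#'   weights in the cross-entropy).
#' @return An `nn_config` list.
#' @export
nn_config <- function(hidden_widths = c(64L, 32L), dropout = 0.3,
                      epochs = 300L, batch_size = 16L, learning_rate = 1e-3,
                      seed = 1L, class_weighting = c("none", "balanced")) {
  class_weighting <- match.arg(class_weighting)
  structure(list(hidden_widths = as.integer(hidden_widths), dropout = dropout,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 class_weighting = class_weighting),
            class = "nn_config")
}

#' Train the neural-network classifier
#'
#' Softmax cross-entropy over the two output neurons, minimized by minibatch
#' Adam. Deterministic given the config seed (identical runs give identical
#' probabilities); training loss decreases from the first to the last epoch
#' on any learnable problem.
#'
#' @param X A `kps_feature_matrix`, or a numeric matrix (then `labels` is
#'   required).
#' @param labels Binary vector (1 = positive class, KPS < 70) when `X` is a
#'   plain matrix.
#' @param config An [nn_config()].
#' @return A `kps_nn` model with `loss_history`.
#' @export
train_nn <- function(X, labels = NULL, config = nn_config()) {
  if (inherits(X, "kps_feature_matrix")) {
    labels <- X$label
    X <- X$values
  }
  if (is.null(labels)) stop("`labels` required when `X` is a matrix")
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  n <- nrow(X); p <- ncol(X)

  cw <- c(1, 1)
  if (config$class_weighting == "balanced") {
    tab <- table(factor(y, levels = 0:1))
    cw <- as.numeric(n / (2 * tab))
  }
  w <- cw[y + 1L]

  sizes <- c(p, config$hidden_widths, 2L)
  set.seed(config$seed)
  params <- lapply(seq_len(length(sizes) - 1L),
                   function(i) dense_init(sizes[i], sizes[i + 1L]))
  opt <- adam_init(params)
  n_hidden <- length(config$hidden_widths)
  Y <- cbind(1 - y, y)                 # one-hot: column 2 = positive class
  history <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      A <- X[idx, , drop = FALSE]
      acts <- vector("list", n_hidden + 1L)
      masks <- vector("list", n_hidden)
      for (l in seq_len(n_hidden)) {
        A_in <- A
        A <- relu(dense_forward(A_in, params[[l]]))
        if (config$dropout > 0) {
          m <- matrix(stats::runif(length(A)) >= config$dropout, nrow(A)) /
            (1 - config$dropout)
          A <- A * m
          masks[[l]] <- m
        }
        acts[[l]] <- list(input = A_in, output = A)
      }
      Z <- dense_forward(A, params[[n_hidden + 1L]])
      P <- softmax_rows(Z)
      Yb <- Y[idx, , drop = FALSE]
      wb <- w[idx]
      ep_loss <- ep_loss - sum(wb * rowSums(Yb * log(pmax(P, 1e-12)))) /
        sum(wb)
      nb <- nb + 1L

      dZ <- (P - Yb) * wb / sum(wb)
      grads <- vector("list", n_hidden + 1L)
      grads[[n_hidden + 1L]] <- list(W = crossprod(A, dZ), b = colSums(dZ))
      dA <- dZ %*% t(params[[n_hidden + 1L]]$W)
      for (l in rev(seq_len(n_hidden))) {
        if (config$dropout > 0) dA <- dA * masks[[l]]
        # entries dropped by the mask already have zero gradient, so the
        # post-dropout output's sign is a valid ReLU indicator
        dA <- dA * (acts[[l]]$output > 0)
        grads[[l]] <- list(W = crossprod(acts[[l]]$input, dA),
                           b = colSums(dA))
        if (l > 1L) dA <- dA %*% t(params[[l]]$W)
      }
      stepped <- adam_step(params, grads, opt, config$learning_rate)
      params <- stepped$params
      opt <- stepped$state
    }
    history[ep] <- ep_loss / nb
  }
  structure(list(params = params, config = config,
                 feature_names = colnames(X), loss_history = history,
                 class_weights = cw),
            class = "kps_nn")
}

#' Predict positive-class probabilities
#'
#' Softmax probability that the 6-month postoperative KPS is below 70. The
#' feature columns must match the training columns by name and order; a
#' mismatch raises an error naming the offending columns.
#'
#' @param model A fitted model (`kps_nn` or `kps_baseline`).
#' @param X Numeric matrix or `kps_feature_matrix`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

check_feature_alignment <- function(model_names, X) {
  if (is.null(colnames(X)) || is.null(model_names)) return(invisible())
  if (!identical(colnames(X), model_names)) {
    off <- union(setdiff(colnames(X), model_names),
                 setdiff(model_names, colnames(X)))
    if (!length(off)) off <- "(same names, different order)"
    stop("feature columns do not match training columns: ",
         paste(off, collapse = ", "))
  }
  invisible()
}

#' @export
predict_proba.kps_nn <- function(model, X) {
  if (inherits(X, "kps_feature_matrix")) X <- X$values
  if (nrow(X) == 0L) return(numeric(0))
  check_feature_alignment(model$feature_names, X)
  n_hidden <- length(model$config$hidden_widths)
  A <- X
  for (l in seq_len(n_hidden)) A <- relu(dense_forward(A, model$params[[l]]))
  P <- softmax_rows(dense_forward(A, model$params[[n_hidden + 1L]]))
  as.numeric(P[, 2])
}

#' Baseline classifier specification
#'
#' Tree-ensemble baselines tuned by exhaustive grid search with inner
#' stratified cross-validation on AUC. Supported families: `random_forest`
#' and `xgboost`.
#'
#' @param family `"random_forest"` or `"xgboost"`.
#' @param grid Named list mapping hyperparameter to candidate values; `NULL`
#'   uses a small default grid per family.
#' @param inner_folds Folds of the tuning cross-validation.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(family = c("random_forest", "xgboost"),
                          grid = NULL, inner_folds = 3L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      random_forest = list(ntree = c(200L, 500L), mtry_frac = c(0.2, 0.5)),
      xgboost = list(nrounds = c(50L, 150L), max_depth = c(2L, 4L),
                     eta = c(0.1, 0.3)))
  }
  if (!length(grid) || any(!lengths(grid)))
    stop("hyperparameter grid must be nonempty")
  structure(list(family = family, grid = grid,
                 inner_folds = as.integer(inner_folds)),
            class = "baseline_spec")
}

fit_baseline_one <- function(X, y, family, pars, seed) {
  set.seed(seed)
  if (family == "random_forest") {
    mtry <- max(1L, round(pars$mtry_frac * ncol(X)))
    fit <- randomForest::randomForest(x = X, y = factor(y, levels = 0:1),
                                      ntree = pars$ntree, mtry = mtry)
    list(fit = fit, family = family)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = pars$max_depth,
                    eta = pars$eta, nthread = 1L, seed = seed),
      data = dtrain, nrounds = pars$nrounds, verbose = 0)
    list(fit = fit, family = family)
  }
}

predict_baseline_one <- function(model, X) {
  if (model$family == "random_forest")
    as.numeric(predict(model$fit, X, type = "prob")[, "1"])
  else
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X)))
}

#' Fit a tuned baseline classifier
#'
#' Exhaustive search over the configured hyperparameter grid, scored by mean AUC
#' of an inner stratified cross-validation, then refit of the best
#' configuration on the full input.
#'
#' @param X A `kps_feature_matrix` or numeric matrix.
#' @param labels Binary labels when `X` is a matrix.
#' @param spec A [baseline_spec()].
#' @param cv_seed Seed for the inner folds and the fits.
#' @return A `kps_baseline` with `best_params` and the tuning table.
#' @export
fit_baseline <- function(X, labels = NULL, spec = baseline_spec(),
                         cv_seed = 1L) {
  stopifnot(inherits(spec, "baseline_spec"))
  if (inherits(X, "kps_feature_matrix")) {
    labels <- X$label
    X <- X$values
  }
  y <- as.integer(labels)
  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  folds <- stratified_folds(y, spec$inner_folds, seed = cv_seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pars <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_len(spec$inner_folds), function(k) {
      tr <- folds != k
      m <- fit_baseline_one(X[tr, , drop = FALSE], y[tr], spec$family, pars,
                            seed = cv_seed + g)
      s <- predict_baseline_one(m, X[!tr, , drop = FALSE])
      roc_auc(y[!tr], s)
    }, 1)
    scores[g] <- mean(aucs)
  }
  best <- which.max(scores)
  pars <- as.list(grid[best, , drop = FALSE])
  model <- fit_baseline_one(X, y, spec$family, pars, seed = cv_seed)
  structure(list(fit = model$fit, family = spec$family,
                 best_params = pars,
                 tuning = cbind(grid, mean_auc = scores),
                 feature_names = colnames(X)),
            class = "kps_baseline")
}

#' @export
predict_proba.kps_baseline <- function(model, X) {
  if (inherits(X, "kps_feature_matrix")) X <- X$values
  if (nrow(X) == 0L) return(numeric(0))
  check_feature_alignment(model$feature_names, X)
  predict_baseline_one(model, X)
}

#' Model builders for cross-validation
#'
#' Thin closures binding a configuration, so [repeated_cv()] can retrain a
#' fresh model inside every fold.
#'
#' @param config An [nn_config()] or [baseline_spec()].
#' @return A function `(X, labels, seed) -> fitted model`.
#' @export
nn_builder <- function(config = nn_config()) {
  force(config)
  function(X, labels, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    train_nn(X, labels, config = cfg)
  }
}

#' @rdname nn_builder
#' @export
baseline_builder <- function(config = baseline_spec()) {
  force(config)
  function(X, labels, seed) fit_baseline(X, labels, spec = config,
                                         cv_seed = seed)
}
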