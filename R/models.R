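#' Specify a shallow classifier for the transfer harness
#'
#' Closed set of model families operating on encoded 7L-bit vectors:
#' \describe{
#'   \item{`logistic_regression`}{Ridge-penalized logistic regression
#'     (glmnet, `alpha = 0`); hyperparameter `lambda`.}
#'   \item{`random_forest`}{randomForest classifier; hyperparameters
#'     `ntree`, `mtry`, `nodesize`.}
#'   \item{`mlp1`}{One-hidden-layer perceptron (nnet); hyperparameters
#'     `size`, `decay`, `maxit`.}
#'   \item{`mlp2`}{Two-hidden-layer perceptron (package-internal
#'     Adam-trained network, logistic output, cross-entropy loss);
#'     hyperparameters `size1`, `size2`, `decay`, `epochs`,
#'     `learning_rate`.}
#'   \item{`plugin`}{Any user object honoring the fit/predict contract,
#'     supplied as `plugin = list(fit = function(x, y, hyperparameters,
#'     seed), predict_proba = function(fit, x))` — the extension point for
#'     deep architectures trained elsewhere.}
#' }
#' Omitted hyperparameters take the family defaults.
#'
#' @param family One of `"logistic_regression"`, `"random_forest"`,
#'   `"mlp1"`, `"mlp2"`, `"plugin"`.
#' @param hyperparameters Named list of hyperparameter values.
#' @param seed Integer seed used when fitting.
#' @param plugin For `family = "plugin"`, the fit/predict pair.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("logistic_regression", "random_forest",
                                  "mlp1", "mlp2", "plugin"),
                       hyperparameters = list(), seed = NULL, plugin = NULL) {
  family <- match.arg(family)
  if (family == "plugin") {
    if (!is.list(plugin) || !is.function(plugin$fit) ||
        !is.function(plugin$predict_proba)) {
      abort("`plugin` models need a list with `fit` and `predict_proba` functions.")
    }
  }
  if (!is.list(hyperparameters)) abort("`hyperparameters` must be a named list.")
  structure(
    list(family = family,
         hyperparameters = utils::modifyList(default_hyperparameters(family),
                                             hyperparameters),
         seed = seed, plugin = plugin),
    class = "model_spec"
  )
}

default_hyperparameters <- function(family) {
  switch(family,
    logistic_regression = list(lambda = 0.01),
    random_forest = list(ntree = 200, mtry = 12, nodesize = 1),
    mlp1 = list(size = 16, decay = 1e-3, maxit = 150),
    mlp2 = list(size1 = 32, size2 = 16, decay = 1e-4, epochs = 200,
                learning_rate = 0.01),
    plugin = list()
  )
}

#' Default random-search spaces per model family
#'
#' Grids of hyperparameter values sampled by [tune_model()]: regularization
#' strength for logistic regression, tree count/feature subsampling/leaf
#' size for random forests, and hidden-layer width plus weight decay for
#' the perceptrons.
#'
#' @param family A `model_spec` family name.
#' @return A named list of candidate value vectors.
#' @export
default_search_space <- function(family) {
  switch(family,
    logistic_regression = list(lambda = 10^seq(-4, 0, length.out = 9)),
    random_forest = list(ntree = c(100, 200, 400), mtry = c(6, 12, 24, 48),
                         nodesize = c(1, 5, 10)),
    mlp1 = list(size = c(8, 16, 32), decay = 10^seq(-4, -1, length.out = 4),
                maxit = c(100, 200)),
    mlp2 = list(size1 = c(16, 32), size2 = c(8, 16),
                decay = 10^seq(-4, -2, length.out = 3), epochs = c(150, 250),
                learning_rate = c(0.005, 0.01)),
    abort(sprintf("No default search space for family '%s'.", family))
  )
}

#' Fit a classifier on a pair dataset
#'
#' Encodes the training pairs ([encode_pairs()]) and fits the model
#' described by the spec on the resulting 0/1 feature matrix. Training
#' data must contain both classes.
#'
#' @param spec A [model_spec()].
#' @param train A pair dataset with both classes present.
#' @return An object of class `ot_model` wrapping the fitted engine.
#' @export
fit_model <- function(spec, train) {
  stopifnot(inherits(spec, "model_spec"))
  enc <- encode_pairs(train)
  x <- encoded_matrix(enc)
  y <- enc$label
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes.")
  }
  hp <- spec$hyperparameters
  fit_one <- function() {
    switch(spec$family,
      logistic_regression = glmnet::glmnet(
        x, y, family = "binomial", alpha = 0, lambda = hp$lambda,
        standardize = FALSE),
      random_forest = randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = hp$ntree,
        mtry = min(hp$mtry, ncol(x)), nodesize = hp$nodesize),
      mlp1 = nnet::nnet(
        x, y, size = hp$size, decay = hp$decay, maxit = hp$maxit,
        entropy = TRUE, trace = FALSE,
        MaxNWts = (ncol(x) + 2) * hp$size + hp$size + 10),
      mlp2 = mlp2_fit(x, y, size1 = hp$size1, size2 = hp$size2,
                      decay = hp$decay, epochs = hp$epochs,
                      learning_rate = hp$learning_rate),
      plugin = spec$plugin$fit(x, y, hyperparameters = hp, seed = spec$seed)
    )
  }
  engine <- if (is.null(spec$seed)) fit_one() else
    withr::with_seed(spec$seed, fit_one())
  structure(
    list(spec = spec, engine = engine, k = ncol(x), n = nrow(x),
         feature_names = colnames(x)),
    class = "ot_model"
  )
}

#' Predict off-target activity probabilities
#'
#' Encodes `pairs` and returns the fitted model's probability that each
#' record is an active off-target, together with the observed label.
#'
#' @param model An `ot_model` from [fit_model()].
#' @param pairs A pair dataset.
#' @return A tibble with columns `p` (probability in `[0, 1]`) and `o`
#'   (observed 0/1 label).
#' @export
predict_proba <- function(model, pairs) {
  stopifnot(inherits(model, "ot_model"))
  enc <- encode_pairs(pairs)
  x <- encoded_matrix(enc)
  if (ncol(x) != model$k) {
    abort(sprintf("Encoded dimension %d does not match the model's %d.",
                  ncol(x), model$k))
  }
  p <- switch(model$spec$family,
    logistic_regression = as.numeric(predict(model$engine, x, type = "response")),
    random_forest = as.numeric(predict(model$engine, x, type = "prob")[, "1"]),
    mlp1 = as.numeric(predict(model$engine, x)),
    mlp2 = mlp2_predict(model$engine, x),
    plugin = as.numeric(model$spec$plugin$predict_proba(model$engine, x))
  )
  p <- pmin(pmax(p, 0), 1)
  tibble(p = p, o = enc$label)
}

#' @export
print.ot_model <- function(x, ...) {
  cat(sprintf("<ot_model> %s fitted on %d records x %d encoded bits\n",
              x$spec$family, x$n, x$k))
  invisible(x)
}

# ---- two-hidden-layer perceptron engine --------------------------------
# Full-batch Adam on cross-entropy; tanh hidden units, logistic output.
# Kept deliberately small: dense inputs of a few thousand rows x 161 bits.

mlp2_fit <- function(x, y, size1 = 32, size2 = 16, decay = 1e-4,
                     epochs = 200, learning_rate = 0.01) {
  n <- nrow(x); k <- ncol(x)
  init <- function(r, c) matrix(stats::rnorm(r * c, sd = sqrt(1 / r)), r, c)
  W1 <- init(k, size1);  b1 <- numeric(size1)
  W2 <- init(size1, size2); b2 <- numeric(size2)
  W3 <- init(size2, 1);  b3 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    h1 <- tanh(sweep(x %*% params$W1, 2, params$b1, `+`))
    h2 <- tanh(sweep(h1 %*% params$W2, 2, params$b2, `+`))
    z <- as.numeric(h2 %*% params$W3) + params$b3
    p <- 1 / (1 + exp(-z))
    dz <- (p - y) / n
    g <- list(
      W3 = crossprod(h2, dz) + decay * params$W3,
      b3 = sum(dz),
      W2 = NULL, b2 = NULL, W1 = NULL, b1 = NULL
    )
    dh2 <- (dz %*% t(params$W3)) * (1 - h2^2)
    g$W2 <- crossprod(h1, dh2) + decay * params$W2
    g$b2 <- colSums(dh2)
    dh1 <- (dh2 %*% t(params$W2)) * (1 - h1^2)
    g$W1 <- crossprod(x, dh1) + decay * params$W1
    g$b1 <- colSums(dh1)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^t)
      vhat <- vel[[nm]] / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  params
}

mlp2_predict <- function(params, x) {
  h1 <- tanh(sweep(x %*% params$W1, 2, params$b1, `+`))
  h2 <- tanh(sweep(h1 %*% params$W2, 2, params$b2, `+`))
  as.numeric(1 / (1 + exp(-(as.numeric(h2 %*% params$W3) + params$b3))))
}

# ---- random-search tuning ----------------------------------------------

#' Tune a model spec by random search with stratified cross-validation
#'
#' Samples up to `max_trials` hyperparameter settings uniformly from the
#' search space (the full grid is enumerated when it is no larger than
#' `max_trials`), scores each by mean cross-validated AUC-ROC over
#' stratified folds of the training data, and returns the spec updated
#' with the best setting. Deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param train A pair dataset with at least `folds` records per class.
#' @param search_space Named list of candidate value vectors; defaults to
#'   [default_search_space()] for the spec's family.
#' @param max_trials Maximum settings evaluated (default 30).
#' @param folds Number of cross-validation folds (default 3).
#' @param seed Integer seed controlling the sampled settings, fold
#'   assignment and fit initialization.
#' @return The tuned `model_spec`, with the trial table in attribute
#'   `"trials"`.
#' @export
tune_model <- function(spec, train, search_space = NULL, max_trials = 30,
                       folds = 3, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(search_space)) search_space <- default_search_space(spec$family)
  if (!is.list(search_space) || length(search_space) == 0 ||
      is.null(names(search_space))) {
    abort("`search_space` must be a nonempty named list of value vectors.")
  }
  train <- validate_pairs(train)
  for (cl in c(0L, 1L)) {
    if (sum(train$label == cl) < folds) {
      abort(sprintf("Class %d has fewer records than folds = %d; cannot stratify.",
                    cl, folds))
    }
  }

  grid_size <- prod(vapply(search_space, length, numeric(1)))
  settings <- withr::with_seed(seed, {
    if (grid_size <= max_trials) {
      g <- expand.grid(search_space, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
    } else {
      lapply(seq_len(max_trials), function(i) {
        lapply(search_space, function(v) v[[sample.int(length(v), 1)]])
      })
    }
  })

  fold_id <- withr::with_seed(seed + 1L, stratified_fold_ids(train$label, folds))
  scores <- vapply(seq_along(settings), function(si) {
    hp <- settings[[si]]
    cv <- vapply(seq_len(folds), function(f) {
      tr <- train[fold_id != f, , drop = FALSE]
      te <- train[fold_id == f, , drop = FALSE]
      sp <- model_spec(spec$family, hyperparameters = hp,
                       seed = seed + 100L * si + f, plugin = spec$plugin)
      preds <- predict_proba(fit_model(sp, tr), te)
      auc_rank(preds$p, preds$o)
    }, numeric(1))
    mean(cv)
  }, numeric(1))

  best <- which.max(scores)
  trials <- tibble(
    trial = seq_along(settings),
    mean_cv_auc = scores,
    hyperparameters = settings
  )
  out <- model_spec(spec$family, hyperparameters = settings[[best]],
                    seed = spec$seed, plugin = spec$plugin)
  attr(out, "trials") <- trials
  out
}

# balanced fold labels within each class
stratified_fold_ids <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}
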