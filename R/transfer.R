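#' Run source-to-target transfer-learning experiments
#'
#' Phase 2 of the similarity-guided workflow. For every (source, model)
#' pair: the source is split 70/30 with equal class stratification
#' ([stratified_split()]), the model is optionally tuned by random search
#' with cross-validation on the 70% training part ([tune_model()]), fitted
#' on it, and scored on the full bootstrapped target with
#' [compute_metrics()]. A typical call compares the recommended source
#' against the alternatives on the same target.
#'
#' @param sources A named list of candidate source pair datasets (a single
#'   dataset is also accepted and treated as a one-element list).
#' @param target The evaluation pair dataset, usually a
#'   [stratified_bootstrap()] replicate.
#' @param models A list of [model_spec()] objects (optionally named). An
#'   empty list yields an empty result table.
#' @param threshold Decision threshold for the confusion-based metrics
#'   (default 0.5).
#' @param tune If `TRUE` (default), tune each model on the source's
#'   training part before the final fit.
#' @param search_spaces Optional named list (by model family) overriding
#'   [default_search_space()].
#' @param max_trials,folds Random-search budget and CV folds passed to
#'   [tune_model()].
#' @param test_fraction Held-out fraction of the source (default 0.3).
#' @param seed Master integer seed; per-cell sub-seeds are derived from it
#'   so each cell is independently reproducible.
#' @return A tibble with one row per (source, model): identifying columns
#'   `source`, `model`, the six metrics, confusion counts and `threshold`,
#'   plus `cell_seed`.
#' @export
run_transfer_experiment <- function(sources, target, models,
                                    threshold = 0.5, tune = TRUE,
                                    search_spaces = NULL, max_trials = 30,
                                    folds = 3, test_fraction = 0.3,
                                    seed = 1) {
  if (is.data.frame(sources)) sources <- list(source = sources)
  if (!is.list(sources) || length(sources) < 1 || is.null(names(sources))) {
    abort("`sources` must be a named list of pair datasets.")
  }
  if (inherits(models, "model_spec")) models <- list(models)
  if (length(models) == 0) {
    return(tibble(source = character(), model = character(),
                  auc_roc = numeric(), precision = numeric(),
                  recall = numeric(), f1 = numeric(), brier = numeric(),
                  accuracy = numeric(), tp = integer(), fp = integer(),
                  fn = integer(), tn = integer(), threshold = numeric(),
                  cell_seed = integer()))
  }
  model_names <- names(models)
  if (is.null(model_names)) model_names <- rep("", length(models))
  model_names <- ifelse(model_names == "",
                        vapply(models, function(m) m$family, character(1)),
                        model_names)

  cells <- tidyr::expand_grid(si = seq_along(sources), mi = seq_along(models))
  cells$cell_seed <- withr::with_seed(seed, sample.int(2^30, nrow(cells)))

  purrr::pmap_dfr(cells, function(si, mi, cell_seed) {
    src_name <- names(sources)[si]
    spec <- models[[mi]]
    res <- tryCatch({
      parts <- stratified_split(sources[[si]], test_fraction = test_fraction,
                                seed = cell_seed)
      if (tune && spec$family != "plugin") {
        space <- if (!is.null(search_spaces) && spec$family %in% names(search_spaces))
          search_spaces[[spec$family]] else NULL
        spec <- tune_model(spec, parts$train, search_space = space,
                           max_trials = max_trials, folds = folds,
                           seed = cell_seed + 1L)
      }
      spec$seed <- cell_seed + 2L
      fitted <- fit_model(spec, parts$train)
      compute_metrics(predict_proba(fitted, target), threshold = threshold)
    }, error = function(e) {
      abort(sprintf("Transfer cell (source '%s', model '%s'): %s",
                    src_name, model_names[mi], conditionMessage(e)))
    })
    dplyr::bind_cols(
      tibble(source = src_name, model = model_names[mi]),
      res,
      tibble(cell_seed = cell_seed)
    )
  })
}
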