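#' Run the full similarity-then-transfer pipeline
#'
#' Ties the workflow together: build a similarity matrix over the supplied
#' datasets ([build_similarity_matrix()]) for each requested metric,
#' recommend a source per target ([recommend_source()], excluding the
#' target itself as its own source candidate when `exclude_self = TRUE`),
#' and run transfer experiments of every candidate source onto each
#' target's bootstrap ([run_transfer_experiment()]). All tables are
#' written as CSV under `out_dir` together with a JSON run manifest
#' recording settings and derived seeds, so a run is re-executable from
#' its outputs.
#'
#' @param datasets Named list of pair datasets, or of CSV paths read via
#'   [read_pairs()].
#' @param targets Names of datasets to treat as targets (default: all).
#' @param metrics Distance metrics to evaluate (default `"cosine"`).
#' @param models List of [model_spec()]s (default: logistic regression,
#'   random forest, and both perceptrons).
#' @param out_dir Output directory; created if missing. `NULL` skips
#'   writing.
#' @param exclude_self Drop the target's own complete dataset from its
#'   source ranking and transfer runs (default `FALSE`, matching the
#'   benchmark design where the complete counterpart is a legitimate
#'   source).
#' @inheritParams build_similarity_matrix
#' @inheritParams run_transfer_experiment
#' @return (Invisibly) a list with `similarity` (per metric),
#'   `recommendations`, `transfer` and `manifest`.
#' @export
run_pipeline <- function(datasets, targets = NULL, metrics = "cosine",
                         models = NULL, n_itr = 5000, bootstrap_size = 250,
                         replicates = 5, threshold = 0.5, tune = TRUE,
                         max_trials = 30, folds = 3, seed = 1,
                         min_minority = 1, out_dir = NULL,
                         exclude_self = FALSE) {
  if (!is.list(datasets) || is.null(names(datasets))) {
    abort("`datasets` must be a named list of pair datasets or CSV paths.")
  }
  datasets <- purrr::imap(datasets, function(d, nm) {
    if (is.character(d)) read_pairs(d, name = nm) else validate_pairs(d)
  })
  for (m in metrics) check_metric(m)
  if (is.null(targets)) targets <- names(datasets)
  if (!all(targets %in% names(datasets))) {
    abort("All `targets` must name an entry of `datasets`.")
  }
  if (is.null(models)) {
    models <- list(
      lr = model_spec("logistic_regression"),
      rf = model_spec("random_forest"),
      mlp1 = model_spec("mlp1"),
      mlp2 = model_spec("mlp2")
    )
  }

  sims <- purrr::map(setNames(metrics, metrics), function(m) {
    build_similarity_matrix(datasets, metric = m, n_itr = n_itr,
                            bootstrap_size = bootstrap_size,
                            replicates = replicates, seed = seed,
                            min_minority = min_minority)
  })

  recommendations <- purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(targets, function(tg) {
      r <- recommend_source(sims[[m]], tg)
      if (exclude_self) r <- dplyr::filter(r, .data$source != tg)
      dplyr::mutate(dplyr::slice_head(r, n = 1), metric = m, target = tg,
                    .before = 1)
    })
  })

  transfer <- purrr::map_dfr(targets, function(tg) {
    sources <- datasets
    if (exclude_self) sources <- sources[setdiff(names(sources), tg)]
    boot <- stratified_bootstrap(datasets[[tg]], size = bootstrap_size,
                                 seed = seed + match(tg, targets),
                                 min_minority = min_minority)
    res <- run_transfer_experiment(sources, boot, models,
                                   threshold = threshold, tune = tune,
                                   max_trials = max_trials, folds = folds,
                                   seed = seed + 1000L + match(tg, targets))
    dplyr::mutate(res, target = tg, .before = 1)
  })

  manifest <- list(
    tool = "crisprtransfer",
    version = as.character(utils::packageVersion("crisprtransfer")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    datasets = purrr::imap(datasets, function(d, nm) {
      list(name = nm, n = nrow(d),
           imbalance_ratio = class_imbalance_ratio(d))
    }),
    settings = list(metrics = metrics, targets = targets, n_itr = n_itr,
                    bootstrap_size = bootstrap_size, replicates = replicates,
                    threshold = threshold, tune = tune,
                    max_trials = max_trials, folds = folds, seed = seed,
                    min_minority = min_minority, exclude_self = exclude_self)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in metrics) {
      write.csv(sims[[m]]$dist_av,
                file.path(out_dir, sprintf("dist_av_%s.csv", m)))
      write.csv(sims[[m]]$similarity,
                file.path(out_dir, sprintf("similarity_%s.csv", m)))
      for (r in seq_along(sims[[m]]$dist_replicates)) {
        write.csv(sims[[m]]$dist_replicates[[r]],
                  file.path(out_dir, sprintf("dist_%s_rep%d.csv", m, r)))
      }
    }
    readr::write_csv(recommendations, file.path(out_dir, "recommendations.csv"),
                     progress = FALSE)
    readr::write_csv(transfer, file.path(out_dir, "transfer_metrics.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(similarity = sims, recommendations = recommendations,
                 transfer = transfer, manifest = manifest))
}

#' @importFrom utils write.csv
NULL
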