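#' Tidy a similarity matrix into long form
#'
#' One row per (source, target) cell with the averaged distance and the
#' min-max similarity.
#'
#' @param x A `similarity_matrix` from [build_similarity_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `source`, `target`, `mean_distance`,
#'   `similarity`.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  nm <- dimnames(x$dist_av)
  tidyr::expand_grid(source = nm[[1]], target = nm[[2]]) |>
    dplyr::mutate(
      mean_distance = as.vector(t(x$dist_av)),
      similarity = as.vector(t(x$similarity))
    )
}

#' One-row summary of a similarity analysis
#'
#' @inheritParams tidy.similarity_matrix
#' @return A one-row tibble with the run settings and the distance range.
#' @method glance similarity_matrix
#' @export
glance.similarity_matrix <- function(x, ...) {
  tibble(
    metric = x$metric, n_datasets = nrow(x$dist_av),
    n_itr = x$n_itr, bootstrap_size = x$bootstrap_size,
    replicates = x$replicates, seed = x$seed,
    min_distance = min(x$dist_av), max_distance = max(x$dist_av)
  )
}

#' One-row summary of a fitted transfer model
#'
#' @param x An `ot_model` from [fit_model()].
#' @param ... Unused.
#' @return A one-row tibble with the family, hyperparameters and training
#'   dimensions.
#' @method glance ot_model
#' @export
glance.ot_model <- function(x, ...) {
  tibble(
    family = x$spec$family,
    n_train = x$n, n_features = x$k,
    hyperparameters = list(x$spec$hyperparameters),
    seed = x$spec$seed %||% NA_integer_
  )
}

#' @importFrom rlang %||%
NULL

#' Heatmap of a dataset similarity matrix
#'
#' Tiles of the min-max similarity with sources on the y axis and
#' bootstrapped targets on the x axis; cell labels show the similarity to
#' two decimals.
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$similarity)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = "bootstrapped target", y = "candidate source",
      fill = "similarity",
      title = sprintf("Dataset similarity (%s distance)", object$metric)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of transfer-experiment metrics
#'
#' Compares one evaluation metric across the (source, model) cells of a
#' [run_transfer_experiment()] result.
#'
#' @param results The tibble returned by [run_transfer_experiment()].
#' @param metric Column to plot (default `"auc_roc"`).
#' @return A ggplot object.
#' @export
plot_transfer_metrics <- function(results, metric = "auc_roc") {
  if (!metric %in% names(results)) {
    abort(sprintf("No metric column '%s' in the results.", metric))
  }
  ggplot2::ggplot(results, ggplot2::aes(x = .data$source,
                                        y = .data[[metric]],
                                        fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "source dataset", y = metric, fill = "model") +
    ggplot2::theme_minimal()
}
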