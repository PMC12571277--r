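#' Monte-Carlo minimum distance from one encoded pair to a source dataset
#'
#' Draws `n_itr` rows from the encoded source uniformly with replacement
#' and returns the smallest distance between `target_vec` and a drawn row.
#' The estimate upper-bounds the exhaustive minimum over the whole source
#' and converges to it as `n_itr` grows; once `n_itr` comfortably exceeds
#' the source size the exhaustive minimum is recovered with probability
#' near 1.
#'
#' @param target_vec A single encoded 0/1 vector (length `7L`).
#' @param source_mat An encoded source matrix, one encoded pair per row.
#' @param metric Distance metric name.
#' @param n_itr Number of Monte-Carlo draws (default 5000).
#' @return The minimum sampled distance (a nonnegative number).
#' @export
min_distance_to_source <- function(target_vec, source_mat,
                                   metric = c("cosine", "euclidean", "manhattan"),
                                   n_itr = 5000) {
  metric <- check_metric(match.arg(metric))
  if (!is.matrix(source_mat) || nrow(source_mat) == 0) {
    abort("`source_mat` must be a nonempty matrix of encoded pairs.")
  }
  if (n_itr < 1) abort("`n_itr` must be at least 1.")
  idx <- sample.int(nrow(source_mat), n_itr, replace = TRUE)
  u <- unique(idx)
  D <- cross_distance(matrix(target_vec, nrow = 1), source_mat[u, , drop = FALSE],
                      metric)
  min(D)
}

#' Monte-Carlo distance between a source dataset and a bootstrapped target
#'
#' For each record of the target, a fresh random subset of `n_itr` source
#' records (sampled uniformly with replacement) is scanned and the minimum
#' distance from the target record to the subset retained; the dataset
#' distance is the mean of these per-record minima. This is the sampling
#' estimator that makes source screening tractable when sources hold
#' hundreds of thousands of candidate sites: with `n_itr = 5000` it
#' typically agrees with the exhaustive one-way average to two decimal
#' places.
#'
#' @param source,target Pair datasets (tibbles with `sgrna_seq`, `dna_seq`,
#'   `label`); the target is usually a [stratified_bootstrap()] replicate.
#' @param metric Distance metric name.
#' @param n_itr Monte-Carlo draws per target record (default 5000).
#' @param seed Optional integer seed making the estimate reproducible.
#' @return An object of class `ot_distance`: a list with the per-record
#'   minima `d`, their `mean_distance`, and the `metric` and `n_itr` used.
#' @seealso [exhaustive_dataset_distance()] for the enumeration oracle.
#' @export
dataset_distance <- function(source, target,
                             metric = c("cosine", "euclidean", "manhattan"),
                             n_itr = 5000, seed = NULL) {
  metric <- check_metric(match.arg(metric))
  A <- encoded_matrix(encode_pairs(target))
  B <- encoded_matrix(encode_pairs(source))
  if (ncol(A) != ncol(B)) {
    abort("Source and target encode to different dimensions; alignment lengths differ.")
  }
  run <- function() mc_min_distances(A, B, metric, n_itr)
  d <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(d = d, mean_distance = mean(d), metric = metric,
         n_itr = as.integer(n_itr), seed = seed),
    class = "ot_distance"
  )
}

# per-target-row minima over fresh with-replacement subsets of B's rows
mc_min_distances <- function(A, B, metric, n_itr) {
  if (n_itr < 1) abort("`n_itr` must be at least 1.")
  m <- nrow(A)
  n <- nrow(B)
  # one subset per target row, drawn row-by-row so each row's subset is
  # an independent uniform sample
  idx <- matrix(sample.int(n, m * n_itr, replace = TRUE), nrow = m, byrow = TRUE)
  u <- sort(unique(as.vector(idx)))
  if (length(u) * m <= 5e7) {
    D <- cross_distance(A, B[u, , drop = FALSE], metric)
    col_of <- match(idx, u)
    dim(col_of) <- dim(idx)
    vapply(seq_len(m), function(i) min(D[i, col_of[i, ]]), numeric(1))
  } else {
    vapply(seq_len(m), function(i) {
      ui <- unique(idx[i, ])
      min(cross_distance(A[i, , drop = FALSE], B[ui, , drop = FALSE], metric))
    }, numeric(1))
  }
}

#' Exhaustive dataset distance (enumeration oracle)
#'
#' Enumerates every source-target record pair and averages per-record
#' minimum distances. The symmetric (`"two_way"`) form averages the minima
#' from both sides — for each source record its nearest target, for each
#' target record its nearest source — over all `|source| + |target|`
#' records. The one-way forms average a single side; `"target_to_source"`
#' is the exhaustive limit of [dataset_distance()]. Intended for small
#' datasets and as the convergence oracle for the Monte-Carlo estimator.
#'
#' @inheritParams dataset_distance
#' @param direction `"two_way"` (default), `"target_to_source"` or
#'   `"source_to_target"`.
#' @param max_pairs Guard on `|source| * |target|` (default 1e6); above it
#'   an error advises the Monte-Carlo path.
#' @return A single nonnegative number.
#' @export
exhaustive_dataset_distance <- function(source, target,
                                        metric = c("cosine", "euclidean", "manhattan"),
                                        direction = c("two_way", "target_to_source",
                                                      "source_to_target"),
                                        max_pairs = 1e6) {
  metric <- check_metric(match.arg(metric))
  direction <- match.arg(direction)
  A <- encoded_matrix(encode_pairs(target))
  B <- encoded_matrix(encode_pairs(source))
  if (as.double(nrow(A)) * nrow(B) > max_pairs) {
    abort(sprintf(
      "Exhaustive enumeration of %d x %d pairs exceeds max_pairs = %g; use dataset_distance().",
      nrow(B), nrow(A), max_pairs))
  }
  D <- cross_distance(A, B, metric) # targets x sources
  switch(direction,
    target_to_source = mean(apply(D, 1, min)),
    source_to_target = mean(apply(D, 2, min)),
    two_way = mean(c(apply(D, 1, min), apply(D, 2, min)))
  )
}

#' Build the dataset similarity matrix
#'
#' Phase 1 of the similarity-guided transfer workflow. For each of
#' `replicates` rounds, every dataset is freshly bootstrapped to
#' `bootstrap_size` records ([stratified_bootstrap()]) and a full
#' cross-distance matrix is computed with [dataset_distance()] — rows are
#' the complete candidate source datasets, columns the bootstrapped
#' targets. Replicate matrices are averaged entrywise into `dist_av`, which
#' is min-max normalized over the whole matrix into the similarity matrix
#' `S`: `s(i,j) = 1 - (dist_av(i,j) - min) / (max - min)`, so the closest
#' source-target pair scores 1 and the farthest 0. When `dist_av` is
#' constant the normalization is degenerate and `S` is set to all 1 with a
#' warning.
#'
#' @param datasets A named list of at least two pair datasets.
#' @param metric Distance metric name.
#' @param n_itr Monte-Carlo draws per target record (default 5000).
#' @param bootstrap_size Target bootstrap size (default 250).
#' @param replicates Number of bootstrap/distance replicates averaged
#'   (default 5).
#' @param seed Master integer seed; per-replicate bootstrap and distance
#'   sub-seeds are derived from it and logged in the result.
#' @param min_minority Minority floor passed to [stratified_bootstrap()].
#' @return An object of class `similarity_matrix` with elements
#'   `dist_replicates` (list of raw matrices), `dist_av`, `similarity`,
#'   `metric`, `n_itr`, `bootstrap_size`, `replicates`, `seed` and the
#'   derived `seeds` table. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
build_similarity_matrix <- function(datasets,
                                    metric = c("cosine", "euclidean", "manhattan"),
                                    n_itr = 5000, bootstrap_size = 250,
                                    replicates = 5, seed = 1,
                                    min_minority = 1) {
  metric <- check_metric(match.arg(metric))
  if (!is.list(datasets) || length(datasets) < 2) {
    abort("`datasets` must be a named list of at least two pair datasets.")
  }
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    abort("Every dataset must be named.")
  }
  if (replicates < 1) abort("`replicates` must be at least 1.")
  nm <- names(datasets)
  N <- length(datasets)

  seeds <- withr::with_seed(seed, {
    tibble(
      replicate = rep(seq_len(replicates), each = N),
      dataset = rep(nm, replicates),
      bootstrap_seed = sample.int(.Machine$integer.max, replicates * N),
      distance_seed = sample.int(.Machine$integer.max, replicates * N)
    )
  })

  dist_replicates <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    srow <- seeds[seeds$replicate == r, ]
    boots <- purrr::map(seq_len(N), function(j) {
      tryCatch(
        stratified_bootstrap(datasets[[j]], size = bootstrap_size,
                             seed = srow$bootstrap_seed[j],
                             min_minority = min_minority),
        error = function(e) abort(sprintf("Dataset '%s': %s", nm[j],
                                          conditionMessage(e)))
      )
    })
    M <- matrix(NA_real_, N, N, dimnames = list(source = nm, target = nm))
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        M[i, j] <- dataset_distance(
          datasets[[i]], boots[[j]], metric = metric, n_itr = n_itr,
          seed = (srow$distance_seed[j] + i) %% .Machine$integer.max
        )$mean_distance
      }
    }
    dist_replicates[[r]] <- M
  }

  dist_av <- Reduce(`+`, dist_replicates) / replicates
  S <- minmax_similarity(dist_av)

  structure(
    list(dist_replicates = dist_replicates, dist_av = dist_av,
         similarity = S, metric = metric, n_itr = as.integer(n_itr),
         bootstrap_size = as.integer(bootstrap_size),
         replicates = as.integer(replicates), seed = seed, seeds = seeds),
    class = "similarity_matrix"
  )
}

#' Min-max normalize a distance matrix into similarities
#'
#' `1 - (x - min) / (max - min)` entrywise over the whole matrix. A
#' constant matrix has no distance contrast to normalize; all similarities
#' are then set to 1 with a warning.
#'
#' @param dist_av A numeric distance matrix.
#' @return A matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_similarity <- function(dist_av) {
  lo <- min(dist_av)
  hi <- max(dist_av)
  if (hi == lo) {
    warn("Distance matrix is constant; min-max normalization is degenerate (all similarities set to 1).")
    return(array(1, dim = dim(dist_av), dimnames = dimnames(dist_av)))
  }
  1 - (dist_av - lo) / (hi - lo)
}

#' Rank candidate sources for a target
#'
#' Orders the sources of a similarity matrix by descending similarity to
#' the named bootstrapped target; the top row is the recommended source for
#' transfer learning. Exact ties are broken lexicographically by source
#' name and flagged.
#'
#' @param sim A `similarity_matrix` from [build_similarity_matrix()].
#' @param target Name of the target column.
#' @return A tibble with columns `rank`, `source`, `similarity`, `tied`.
#' @export
recommend_source <- function(sim, target) {
  stopifnot(inherits(sim, "similarity_matrix"))
  S <- sim$similarity
  if (!(target %in% colnames(S))) {
    abort(sprintf("Unknown target '%s'; available: %s.", target,
                  paste(colnames(S), collapse = ", ")))
  }
  s <- S[, target]
  ord <- order(-s, names(s))
  out <- tibble(
    rank = seq_along(ord),
    source = names(s)[ord],
    similarity = unname(s[ord])
  )
  out$tied <- duplicated(out$similarity) | duplicated(out$similarity, fromLast = TRUE)
  out
}

#' Rank candidate sources for one target by direct Monte-Carlo distance
#'
#' Convenience wrapper around [dataset_distance()] when only a single
#' target is of interest: computes the Monte-Carlo distance from each
#' candidate source to the bootstrapped target and ranks sources by
#' ascending distance (ties broken lexicographically).
#'
#' @param sources Named list of candidate source datasets.
#' @param target A (bootstrapped) target pair dataset.
#' @inheritParams dataset_distance
#' @return A tibble with columns `rank`, `source`, `mean_distance`.
#' @export
rank_sources <- function(sources, target,
                         metric = c("cosine", "euclidean", "manhattan"),
                         n_itr = 5000, seed = NULL) {
  metric <- check_metric(match.arg(metric))
  if (!is.list(sources) || length(sources) < 1 || is.null(names(sources))) {
    abort("`sources` must be a named list of pair datasets.")
  }
  seeds <- if (is.null(seed)) rep(list(NULL), length(sources)) else
    as.list(seed + seq_along(sources))
  d <- purrr::map2_dbl(sources, seeds, function(s, sd) {
    dataset_distance(s, target, metric = metric, n_itr = n_itr,
                     seed = sd)$mean_distance
  })
  ord <- order(d, names(sources))
  tibble(rank = seq_along(ord), source = names(sources)[ord],
         mean_distance = unname(d[ord]))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "Dataset similarity matrix (%s distance, n_itr = %d, bootstrap size = %d, %d replicate%s)\n",
    x$metric, x$n_itr, x$bootstrap_size, x$replicates,
    if (x$replicates == 1) "" else "s"))
  cat("Similarity (rows = complete sources, columns = bootstrapped targets):\n")
  print(round(x$similarity, 4))
  invisible(x)
}

#' @export
print.ot_distance <- function(x, ...) {
  cat(sprintf("Monte-Carlo dataset distance (%s, n_itr = %d): %.4f over %d target records\n",
              x$metric, x$n_itr, x$mean_distance, length(x$d)))
  invisible(x)
}
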