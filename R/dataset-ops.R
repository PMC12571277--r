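#' Class imbalance ratio of a labeled pair dataset
#'
#' The number of minority-class records (active off-targets, `label == 1`)
#' divided by the number of majority-class records (inactive candidates,
#' `label == 0`). Benchmark off-target datasets range from nearly balanced
#' (CD33-like, ~0.88) down to roughly 1:10,000 for GUIDE-seq screens.
#'
#' @param pairs A pair dataset (see [validate_pairs()]).
#' @return A number in `(0, Inf)`; for off-target data, in `(0, 1]`.
#' @examples
#' d <- generate_dataset(n_samples = 200, imbalance_ratio = 0.25, seed = 1)
#' class_imbalance_ratio(d)
#' @export
class_imbalance_ratio <- function(pairs) {
  pairs <- validate_pairs(pairs)
  n1 <- sum(pairs$label == 1L)
  n0 <- sum(pairs$label == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to form an imbalance ratio.")
  }
  n1 / n0
}

#' Stratified bootstrap allocation at a fixed resample size
#'
#' How many minority records a stratified size-`size` bootstrap draws:
#' `max(min_minority, round(size * minority / (minority + majority)))`,
#' with the remainder allocated to the majority class. Rounding to the
#' nearest integer preserves the parent imbalance ratio as closely as an
#' integer split allows; the floor guarantees at least one active
#' off-target even at extreme imbalance.
#'
#' @param minority,majority Parent per-class record counts.
#' @param size Bootstrap size (default 250).
#' @param min_minority Floor on the minority allocation (default 1).
#' @return A named list with integer `minority` and `majority` counts.
#' @examples
#' bootstrap_allocation(2273, 2580, size = 250)   # 117 / 133
#' bootstrap_allocation(7371, 577578, size = 250) # 3 / 247
#' @export
bootstrap_allocation <- function(minority, majority, size = 250,
                                 min_minority = 1) {
  if (size < 2) abort("`size` must be at least 2.")
  if (minority < 1 || majority < 1) {
    abort("Both classes must be nonempty for a stratified bootstrap.")
  }
  m <- max(min_minority, round(size * minority / (minority + majority)))
  m <- min(m, size - 1L)
  list(minority = as.integer(m), majority = as.integer(size - m))
}

#' Stratified bootstrap of a pair dataset
#'
#' Draws a fixed-size resample with replacement, independently within each
#' class, with per-class counts set by [bootstrap_allocation()] so the
#' bootstrapped dataset's imbalance ratio tracks the parent's. This is the
#' standing model of a "realistically small" target dataset: large
#' benchmark screens are shrunk to `size` records while keeping their class
#' geometry.
#'
#' @inheritParams class_imbalance_ratio
#' @param size Number of records to draw (default 250).
#' @param seed Integer seed; the draw is reproducible given the seed. The
#'   allocation itself depends only on the class counts and `size`.
#' @param min_minority Floor on the minority allocation (default 1).
#' @return A tibble of `size` records with attributes `parent` (if `pairs`
#'   carries a `name` attribute), `size` and `seed`.
#' @export
stratified_bootstrap <- function(pairs, size = 250, seed = NULL,
                                 min_minority = 1) {
  pairs <- validate_pairs(pairs)
  alloc <- bootstrap_allocation(sum(pairs$label == 1L),
                                sum(pairs$label == 0L),
                                size = size, min_minority = min_minority)
  draw <- function() {
    i1 <- which(pairs$label == 1L)
    i0 <- which(pairs$label == 0L)
    idx <- c(sample(i1, alloc$minority, replace = TRUE),
             sample(i0, alloc$majority, replace = TRUE))
    pairs[idx, , drop = FALSE]
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "parent") <- attr(pairs, "name", exact = TRUE)
  attr(out, "size") <- as.integer(size)
  attr(out, "seed") <- seed
  out
}

#' Stratified train/test split
#'
#' Shuffled partition of a pair dataset into train and test parts with
#' per-class proportions matching the parent's within integer rounding
#' (equal stratification). Used to hold out 30% of a source dataset before
#' model tuning and fitting.
#'
#' @inheritParams class_imbalance_ratio
#' @param test_fraction Fraction of each class assigned to the test part,
#'   strictly between 0 and 1 (default 0.3).
#' @param seed Integer seed for the shuffle; same seed, same partition.
#' @return A named list of two tibbles, `train` and `test`, disjoint and
#'   exhaustive over the input rows.
#' @export
stratified_split <- function(pairs, test_fraction = 0.3, seed = NULL) {
  pairs <- validate_pairs(pairs)
  if (!is.numeric(test_fraction) || length(test_fraction) != 1 ||
      test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1.")
  }
  split_one <- function() {
    test_idx <- integer(0)
    for (cl in c(0L, 1L)) {
      idx <- which(pairs$label == cl)
      if (length(idx) < 2) {
        abort(sprintf(
          "Class %d has %d record(s); at least 2 per class are needed to stratify.",
          cl, length(idx)))
      }
      n_test <- round(length(idx) * test_fraction)
      n_test <- min(max(n_test, 1L), length(idx) - 1L)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx
  }
  test_idx <- if (is.null(seed)) split_one() else withr::with_seed(seed, split_one())
  list(train = pairs[-sort(test_idx), , drop = FALSE],
       test = pairs[sort(test_idx), , drop = FALSE])
}

#' Read and write pair datasets as CSV
#'
#' Datasets are exchanged as UTF-8 CSV with header
#' `sgrna_seq,dna_seq,label`. `read_pairs()` validates on load and reports
#' malformed content with the offending data row; `write_pairs()` writes
#' the three canonical columns so that writing then reading is the
#' identity.
#'
#' @param path File path.
#' @param name Optional dataset name stored as a `name` attribute.
#' @return `read_pairs()` a validated tibble; `write_pairs()` the input,
#'   invisibly.
#' @export
read_pairs <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("sgrna_seq", "dna_seq", "label"), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s (header must include sgrna_seq,dna_seq,label).",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(sprintf("%s: no data rows (empty dataset).", path))
  out <- tryCatch(
    validate_pairs(raw),
    error = function(e) {
      # validate_pairs reports "Row <i>"; translate to a file line (header = line 1)
      msg <- conditionMessage(e)
      m <- regmatches(msg, regexec("^Row ([0-9]+)", msg))[[1]]
      if (length(m) == 2) {
        msg <- sub("^Row [0-9]+", sprintf("%s, line %d", path, as.integer(m[2]) + 1L), msg)
      }
      abort(msg)
    }
  )
  if (!is.null(name)) attr(out, "name") <- name
  out
}

#' @rdname read_pairs
#' @param pairs A pair dataset.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- validate_pairs(pairs)
  readr::write_csv(pairs[, c("sgrna_seq", "dna_seq", "label")], path,
                   progress = FALSE)
  invisible(pairs)
}
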