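#' Vector distances for encoded sgRNA-DNA pairs
#'
#' The three metrics used to compare encoded pairs: cosine distance
#' \eqn{1 - a \cdot b / (\|a\| \|b\|)}, Euclidean distance
#' \eqn{\sqrt{\sum_i (a_i - b_i)^2}} and Manhattan distance
#' \eqn{\sum_i |a_i - b_i|}. On the 0/1 vectors produced by
#' [encode_pairs()] the Euclidean distance equals the square root of the
#' Hamming distance and the Manhattan distance equals the Hamming distance
#' itself.
#'
#' @param a,b Numeric vectors of equal length. For `cosine_distance` both
#'   must be nonzero.
#' @return A single nonnegative number.
#' @name distances
NULL

#' @rdname distances
#' @export
cosine_distance <- function(a, b) {
  check_same_length(a, b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine_distance is undefined for a zero vector.")
  }
  1 - sum(a * b) / (na * nb)
}

#' @rdname distances
#' @export
euclidean_distance <- function(a, b) {
  check_same_length(a, b)
  sqrt(sum((a - b)^2))
}

#' @rdname distances
#' @export
manhattan_distance <- function(a, b) {
  check_same_length(a, b)
  sum(abs(a - b))
}

check_same_length <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("Vectors differ in length (%d vs %d).",
                  length(a), length(b)))
  }
  invisible(NULL)
}

ot_metrics <- c("cosine", "euclidean", "manhattan")

check_metric <- function(metric) {
  if (!(is.character(metric) && length(metric) == 1 && metric %in% ot_metrics)) {
    abort(paste0("`metric` must be one of: ",
                 paste(ot_metrics, collapse = ", "), "."))
  }
  metric
}

#' @rdname distances
#' @param metric One of `"cosine"`, `"euclidean"`, `"manhattan"`.
#' @export
pair_distance <- function(a, b, metric = c("cosine", "euclidean", "manhattan")) {
  metric <- check_metric(match.arg(metric))
  switch(metric,
    cosine = cosine_distance(a, b),
    euclidean = euclidean_distance(a, b),
    manhattan = manhattan_distance(a, b)
  )
}

# All pairwise distances between the rows of A (m x K) and B (n x K),
# returned as an m x n matrix. Uses inner-product identities: for 0/1 data
# ||a - b||_1 = ||a||^2 + ||b||^2 - 2 a.b, which also feeds the Euclidean
# and cosine forms; falls back to a row loop for non-binary input.
cross_distance <- function(A, B, metric) {
  metric <- check_metric(metric)
  if (ncol(A) != ncol(B)) {
    abort(sprintf("Encoded dimensions differ (%d vs %d).", ncol(A), ncol(B)))
  }
  binary <- all(A %in% c(0, 1)) && all(B %in% c(0, 1))
  if (!binary && metric == "manhattan") {
    return(t(apply(A, 1, function(a) apply(B, 1, manhattan_distance, a = a))))
  }
  AB <- tcrossprod(A, B)
  ra <- rowSums(A^2)
  rb <- rowSums(B^2)
  if (metric == "cosine") {
    if (any(ra == 0) || any(rb == 0)) {
      abort("cosine distance is undefined for a zero row.")
    }
    return(1 - AB / outer(sqrt(ra), sqrt(rb)))
  }
  sq <- pmax(outer(ra, rb, `+`) - 2 * AB, 0)
  if (metric == "euclidean") sqrt(sq) else sq
}
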