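#' Encode one aligned sgRNA-DNA pair as a 7L-bit binary vector
#'
#' Each alignment position is represented by a 7-bit block: five character
#' bits marking which symbols of `A, C, G, T, _` occur in the sgRNA and the
#' DNA at that position (their element-wise union), and a two-bit direction
#' channel locating mismatches and bulges. On a match both direction bits
#' are 0. On a mismatch or bulge the first direction bit is set when the
#' sgRNA symbol precedes the DNA symbol in alphabet order (`A < C < G < T <
#' _`), the second otherwise. Blocks are concatenated position-major, so a
#' length-23 pair becomes a 161-bit vector.
#'
#' The `_` symbol marks the gapped side of an aligned bulge: `_` in the DNA
#' string is an RNA bulge (extra base in the sgRNA), `_` in the sgRNA string
#' a DNA bulge. Inputs must be pre-aligned; no alignment is performed.
#'
#' @param sgrna_seq,dna_seq Character strings of equal length over
#'   `A, C, G, T, _` (lower case accepted). `_` may not occur at the same
#'   position in both.
#' @return An integer 0/1 vector of length `7 * nchar(sgrna_seq)`.
#' @examples
#' v <- encode_pair("GAGTCCGAGCAGAAGAAGAATGG", "GAGTCCGAGCAGAAGAAGAATGG")
#' sum(v) # one character bit per position, no direction bits
#' @export
encode_pair <- function(sgrna_seq, dna_seq) {
  m <- encode_pairs(tibble(
    sgrna_seq = sgrna_seq, dna_seq = dna_seq, label = 0L
  ))
  v <- as.integer(m[1, seq_len(ncol(m) - 1L), drop = TRUE])
  names(v) <- names(m)[seq_len(ncol(m) - 1L)]
  v
}

#' Encode a dataset of aligned sgRNA-DNA pairs
#'
#' Vectorized batch form of [encode_pair()]. Rows are encoded independently
#' and row order is preserved, so the result aligns with the input labels.
#'
#' @param pairs A data frame with columns `sgrna_seq`, `dna_seq` and a
#'   binary `label` (1 = active off-target, the minority class).
#' @return A tibble with `7 * L` integer 0/1 columns (one 7-bit block per
#'   position, named `p<position>_<bit>`) followed by a final `label`
#'   column.
#' @seealso [encode_pair()] for the bit layout.
#' @export
encode_pairs <- function(pairs) {
  pairs <- validate_pairs(pairs)
  n <- nrow(pairs)
  L <- nchar(pairs$sgrna_seq[1])
  K <- ot_bits_per_position * L

  sg <- char_index_matrix(pairs$sgrna_seq, L)
  dn <- char_index_matrix(pairs$dna_seq, L)

  bits <- matrix(0L, nrow = n, ncol = K)
  rows <- rep.int(seq_len(n), L)
  block0 <- rep(ot_bits_per_position * (seq_len(L) - 1L), each = n)

  # character channel: union of the two one-hot symbols
  bits[cbind(rows, block0 + as.vector(sg))] <- 1L
  bits[cbind(rows, block0 + as.vector(dn))] <- 1L

  # direction channel: (0,0) match, (1,0) sgRNA < DNA, (0,1) sgRNA > DNA
  lt <- as.vector(sg) < as.vector(dn)
  gt <- as.vector(sg) > as.vector(dn)
  if (any(lt)) bits[cbind(rows[lt], block0[lt] + 6L)] <- 1L
  if (any(gt)) bits[cbind(rows[gt], block0[gt] + 7L)] <- 1L

  colnames(bits) <- bit_column_names(L)
  out <- as_tibble(bits)
  out$label <- as.integer(pairs$label)
  out
}

bit_column_names <- function(L) {
  suffix <- c("A", "C", "G", "T", "gap", "d1", "d2")
  paste0("p", rep(seq_len(L), each = ot_bits_per_position), "_",
         rep(suffix, L))
}

# string vector -> n x L matrix of alphabet indices (1..5)
char_index_matrix <- function(seqs, L) {
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
  idx <- match(chars, ot_alphabet)
  dim(idx) <- dim(chars)
  idx
}

#' Validate an sgRNA-DNA pair dataset
#'
#' Checks the invariants every downstream operation assumes: the required
#' columns are present, sequences are same-length strings over
#' `A, C, G, T, _` (case-folded to upper), no position is gapped in both
#' strands, and labels are binary. Malformed rows are reported by row number
#' and, for alphabet violations, by position.
#'
#' @param pairs A data frame with columns `sgrna_seq`, `dna_seq`, `label`.
#' @return The validated tibble, sequences upper-cased, label integer.
#' @export
validate_pairs <- function(pairs) {
  if (!is.data.frame(pairs)) {
    abort("`pairs` must be a data frame of aligned sgRNA-DNA records.")
  }
  missing_cols <- setdiff(c("sgrna_seq", "dna_seq", "label"), names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("`pairs` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(pairs) == 0) {
    abort("`pairs` contains no records (empty dataset).")
  }
  pairs <- as_tibble(pairs)
  pairs$sgrna_seq <- toupper(as.character(pairs$sgrna_seq))
  pairs$dna_seq <- toupper(as.character(pairs$dna_seq))

  len_sg <- nchar(pairs$sgrna_seq)
  len_dn <- nchar(pairs$dna_seq)
  if (any(len_sg != len_dn)) {
    bad <- which(len_sg != len_dn)[1]
    abort(sprintf(
      "Row %d: sgRNA length (%d) and DNA length (%d) differ; pairs must be pre-aligned.",
      bad, len_sg[bad], len_dn[bad]))
  }
  if (length(unique(len_sg)) != 1) {
    abort(sprintf(
      "All pairs must share one alignment length; found lengths {%s}.",
      paste(sort(unique(len_sg)), collapse = ", ")))
  }
  L <- len_sg[1]
  if (L < 1) abort("Sequences must be non-empty.")

  for (col in c("sgrna_seq", "dna_seq")) {
    idx <- char_index_matrix(pairs[[col]], L)
    if (anyNA(idx)) {
      bad <- which(is.na(idx), arr.ind = TRUE)[1, ]
      ch <- substr(pairs[[col]][bad[1]], bad[2], bad[2])
      abort(sprintf(
        "Row %d: invalid character '%s' at position %d of %s (alphabet is A, C, G, T, _).",
        bad[1], ch, bad[2], col))
    }
  }

  sg <- char_index_matrix(pairs$sgrna_seq, L)
  dn <- char_index_matrix(pairs$dna_seq, L)
  both_gap <- sg == 5L & dn == 5L
  if (any(both_gap)) {
    bad <- which(both_gap, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Row %d: '_' aligned to '_' at position %d; a bulge gaps only one strand.",
      bad[1], bad[2]))
  }

  lab <- suppressWarnings(as.numeric(pairs$label))
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    bad <- which(is.na(lab) | !(lab %in% c(0, 1)))[1]
    abort(sprintf("Row %d: label '%s' is not binary (must be 0 or 1).",
                  bad, as.character(pairs$label[bad])))
  }
  pairs$label <- as.integer(lab)
  pairs
}

# encoded tibble (bits + label) -> plain numeric matrix of bits
encoded_matrix <- function(encoded) {
  as.matrix(encoded[, setdiff(names(encoded), "label"), drop = FALSE])
}
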