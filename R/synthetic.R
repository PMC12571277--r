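#' Generate a set of guide sequences
#'
#' Independent uniform-base L-mers over `A, C, G, T` (no gaps), standing in
#' for the protospacer+PAM guides of a benchmark screen. Benchmark
#' datasets carry between 5 and 65 guides; the default of 10 sits in that
#' range.
#'
#' @param n_guides Number of guides (default 10).
#' @param L Sequence length (default 23: 20-nt protospacer + 3-bp PAM).
#' @param seed Integer seed; same seed, same guides.
#' @return A character vector of `n_guides` L-mers.
#' @export
generate_guides <- function(n_guides = 10, L = 23, seed = NULL) {
  if (n_guides < 1) abort("`n_guides` must be at least 1.")
  if (L < 1) abort("`L` must be at least 1.")
  draw <- function() {
    vapply(seq_len(n_guides), function(i) {
      paste(sample(ot_alphabet[1:4], L, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a benchmark-like sgRNA-DNA off-target dataset
#'
#' Emulates the statistical shape of experimental off-target screens:
#' a small guide set, aligned sgRNA-DNA pairs whose DNA strand is a
#' mutated copy of a guide, class imbalance down to ~1:10,000, and a
#' learnable signal — active off-targets (`label = 1`, the minority class)
#' carry fewer mismatches than inactive candidates. Per record: a guide is
#' drawn uniformly; a Poisson number of substitutions (mean set by the
#' record's class) is placed at distinct positions — uniform over
#' `active_positions` for active records, uniform over the whole alignment
#' for inactive ones — with the replacement base uniform over the three
#' alternatives; with probability `indel_rate` one aligned single-position
#' bulge is added by gapping one strand (`_` in the DNA string for an RNA
#' bulge, in the sgRNA string for a DNA bulge). Class counts follow
#' `imbalance_ratio` through the [bootstrap_allocation()] rounding rule.
#'
#' Restricting active-class mismatches to a tolerated window mirrors the
#' position dependence of Cas9 cleavage (PAM-proximal seed mismatches
#' abolish activity far more often than PAM-distal ones), and gives each
#' dataset a position-specific mutation spectrum a classifier can exploit
#' — and lose when transferred to a dataset with a different spectrum.
#'
#' No cleavage biochemistry or genomic context is modeled; the generator
#' reproduces dataset shape (guide sharing, mismatch spectra, imbalance)
#' only.
#'
#' @param n_samples Number of records (default 2000).
#' @param imbalance_ratio Minority/majority ratio in `(0, 1]` (default
#'   0.05).
#' @param guides Optional character vector of guides; generated via
#'   [generate_guides()] when `NULL`.
#' @param n_guides Number of guides when `guides` is `NULL` (default 10).
#' @param mismatch_rate_active,mismatch_rate_inactive Expected substitution
#'   counts per pair by class (defaults 1.5 and 5.5); the active rate must
#'   be the smaller one — active sites resemble their guide more closely.
#' @param indel_rate Probability a record carries one bulge (default
#'   0.05).
#' @param active_positions Alignment positions where active-class
#'   mismatches may land (default `1:12`, the PAM-distal half of a 23-mer).
#' @param L Alignment length (default 23).
#' @param seed Integer seed.
#' @return A pair dataset tibble (`sgrna_seq`, `dna_seq`, `label`) with the
#'   generating settings in attribute `"config"`.
#' @export
generate_dataset <- function(n_samples = 2000, imbalance_ratio = 0.05,
                             guides = NULL, n_guides = 10,
                             mismatch_rate_active = 1.5,
                             mismatch_rate_inactive = 5.5,
                             indel_rate = 0.05, active_positions = 1:12,
                             L = 23, seed = NULL) {
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (imbalance_ratio <= 0 || imbalance_ratio > 1) {
    abort("`imbalance_ratio` must lie in (0, 1].")
  }
  if (mismatch_rate_active < 0 || mismatch_rate_inactive < 0 || indel_rate < 0) {
    abort("Rates must be nonnegative.")
  }
  if (mismatch_rate_active >= mismatch_rate_inactive) {
    abort("`mismatch_rate_active` must be smaller than `mismatch_rate_inactive` (active off-targets resemble guides more closely).")
  }
  active_positions <- as.integer(active_positions)
  if (length(active_positions) < 1 ||
      any(active_positions < 1 | active_positions > L)) {
    abort("`active_positions` must be a nonempty subset of 1:L.")
  }
  build <- function() {
    gset <- if (is.null(guides)) generate_guides(n_guides, L) else toupper(guides)
    if (any(nchar(gset) != L)) abort("All guides must have length L.")
    frac1 <- imbalance_ratio / (1 + imbalance_ratio)
    n1 <- max(1L, as.integer(round(n_samples * frac1)))
    n1 <- min(n1, n_samples - 1L)
    n0 <- n_samples - n1
    labels <- c(rep(1L, n1), rep(0L, n0))
    rates <- ifelse(labels == 1L, mismatch_rate_active, mismatch_rate_inactive)
    recs <- purrr::map(seq_len(n_samples), function(i) {
      g <- gset[[sample.int(length(gset), 1)]]
      sg <- strsplit(g, "", fixed = TRUE)[[1]]
      dn <- sg
      allowed <- if (labels[i] == 1L) active_positions else seq_len(L)
      n_sub <- min(rpois(1, rates[i]), length(allowed))
      if (n_sub > 0) {
        pos <- allowed[sample.int(length(allowed), n_sub)]
        for (p in pos) {
          dn[p] <- sample(setdiff(ot_alphabet[1:4], dn[p]), 1)
        }
      }
      if (runif(1) < indel_rate) {
        p <- sample.int(L, 1)
        if (runif(1) < 0.5) sg[p] <- "_" else dn[p] <- "_"
      }
      list(sg = paste(sg, collapse = ""), dn = paste(dn, collapse = ""))
    })
    out <- tibble(
      sgrna_seq = vapply(recs, `[[`, character(1), "sg"),
      dna_seq = vapply(recs, `[[`, character(1), "dn"),
      label = labels
    )
    attr(out, "guides") <- gset
    out
  }
  out <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  attr(out, "config") <- list(
    n_samples = n_samples, imbalance_ratio = imbalance_ratio,
    n_guides = if (is.null(guides)) n_guides else length(guides), L = L,
    mismatch_rate_active = mismatch_rate_active,
    mismatch_rate_inactive = mismatch_rate_inactive,
    indel_rate = indel_rate, active_positions = active_positions,
    seed = seed
  )
  out
}

#' Generate a pair of datasets at a controlled divergence
#'
#' Builds a base dataset and a partner whose generating process drifts
#' away from the base by `divergence` in `[0, 1]`: the partner reuses a
#' fraction `1 - divergence` of the base's guides (the rest are drawn
#' fresh), both class mismatch rates are shifted upward by
#' `divergence * rate_shift`, and the window of positions tolerating
#' active-class mismatches slides along the alignment in proportion to
#' `divergence`. At divergence 0 the two datasets are draws from the same
#' process; at divergence 1 they share no guides and the partner's
#' mismatch spectrum — both its count distribution and its positional
#' profile — is displaced, so a classifier fitted to the partner keys on
#' the wrong positions for the base. The Monte-Carlo cosine distance
#' between base and partner is non-decreasing in divergence (in
#' expectation over seeds), which is what makes these pairs useful
#' fixtures for testing that similarity ranking predicts transfer
#' success.
#'
#' @inheritParams generate_dataset
#' @param divergence Drift of the partner's generator in `[0, 1]`.
#' @param rate_shift Mismatch-rate displacement at divergence 1 (default
#'   4).
#' @param seed Integer seed; the base dataset depends only on the seed,
#'   not on `divergence`, so partners at several divergences can share one
#'   base.
#' @return A named list of two pair datasets, `base` and `partner`.
#' @export
generate_related_pair <- function(divergence, n_samples = 2000,
                                  imbalance_ratio = 0.05, n_guides = 10,
                                  mismatch_rate_active = 1.5,
                                  mismatch_rate_inactive = 5.5,
                                  indel_rate = 0.05, rate_shift = 4,
                                  L = 23, seed = 1) {
  if (!is.numeric(divergence) || length(divergence) != 1 ||
      divergence < 0 || divergence > 1) {
    abort("`divergence` must lie in [0, 1].")
  }
  base_guides <- generate_guides(n_guides, L, seed = seed)
  base <- generate_dataset(
    n_samples = n_samples, imbalance_ratio = imbalance_ratio,
    guides = base_guides, mismatch_rate_active = mismatch_rate_active,
    mismatch_rate_inactive = mismatch_rate_inactive,
    indel_rate = indel_rate, L = L, seed = seed + 1L
  )
  n_keep <- round((1 - divergence) * n_guides)
  partner_guides <- c(
    head(base_guides, n_keep),
    if (n_keep < n_guides) generate_guides(n_guides - n_keep, L, seed = seed + 2L)
  )
  base_window <- attr(base, "config")$active_positions
  w <- length(base_window)
  offset <- round(divergence * (L - w))
  partner <- generate_dataset(
    n_samples = n_samples, imbalance_ratio = imbalance_ratio,
    guides = partner_guides,
    mismatch_rate_active = mismatch_rate_active + divergence * rate_shift,
    mismatch_rate_inactive = mismatch_rate_inactive + divergence * rate_shift,
    indel_rate = indel_rate, active_positions = base_window + offset,
    L = L, seed = seed + 3L
  )
  list(base = base, partner = partner)
}
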