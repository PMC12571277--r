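# Independent oracles and small fixture builders shared across tests.
# Each oracle is written as a direct, position-by-position (or pair-by-pair)
# restatement of the definitions, deliberately avoiding the package's
# vectorized code paths.

alphabet <- c("A", "C", "G", "T", "_")

# brute-force single-pair encoder: explicit loop over positions
brute_encode <- function(sg, dn) {
  sg_ch <- strsplit(sg, "")[[1]]
  dn_ch <- strsplit(dn, "")[[1]]
  out <- integer(0)
  for (p in seq_along(sg_ch)) {
    block <- integer(7)
    i_sg <- match(sg_ch[p], alphabet)
    i_dn <- match(dn_ch[p], alphabet)
    block[i_sg] <- 1L
    block[i_dn] <- 1L
    if (i_sg < i_dn) block[6] <- 1L
    if (i_sg > i_dn) block[7] <- 1L
    out <- c(out, block)
  }
  out
}

# random valid aligned pair of length L with a given number of mismatches
# and optionally one bulge
random_pair <- function(L = 23, n_mismatch = 0, bulge = FALSE) {
  sg <- sample(alphabet[1:4], L, replace = TRUE)
  dn <- sg
  if (n_mismatch > 0) {
    for (p in sample(L, n_mismatch)) {
      dn[p] <- sample(setdiff(alphabet[1:4], dn[p]), 1)
    }
  }
  if (bulge) {
    p <- sample(L, 1)
    if (runif(1) < 0.5) sg[p] <- "_" else dn[p] <- "_"
  }
  list(sg = paste(sg, collapse = ""), dn = paste(dn, collapse = ""))
}

random_pairs_df <- function(n, L = 23, max_mismatch = 6, bulge_prob = 0.2) {
  recs <- lapply(seq_len(n), function(i) {
    random_pair(L, sample(0:max_mismatch, 1), runif(1) < bulge_prob)
  })
  tibble::tibble(
    sgrna_seq = vapply(recs, `[[`, character(1), "sg"),
    dna_seq = vapply(recs, `[[`, character(1), "dn"),
    label = sample(c(0L, 1L), n, replace = TRUE)
  )
}

# exhaustive pairwise-comparison AUC: every positive-negative pair, ties 1/2
auc_pairwise <- function(p, o) {
  pos <- p[o == 1]
  neg <- p[o == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# distance definitions restated directly from the formulas
oracle_distance <- function(a, b, metric) {
  switch(metric,
    cosine = 1 - sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b))),
    euclidean = sqrt(sum((a - b)^2)),
    manhattan = sum(abs(a - b))
  )
}

# steps A-C style exhaustive average of per-element minima, loop form
oracle_one_way_distance <- function(source_df, target_df, metric) {
  A <- as.matrix(encode_pairs(target_df)[, -ncol(encode_pairs(target_df))])
  B <- as.matrix(encode_pairs(source_df)[, -ncol(encode_pairs(source_df))])
  mins <- vapply(seq_len(nrow(A)), function(m) {
    min(vapply(seq_len(nrow(B)),
               function(n) oracle_distance(A[m, ], B[n, ], metric),
               numeric(1)))
  }, numeric(1))
  mean(mins)
}
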