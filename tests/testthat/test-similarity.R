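make_encoded <- function(df) as.matrix(encode_pairs(df)[, -162])

test_that("the Monte-Carlo minimum finds present targets and single-row sources exactly", {
  withr::with_seed(41, {
    df <- random_pairs_df(20)
    E <- make_encoded(df)
    # target present in source -> 0 once every row has been drawn
    expect_equal(min_distance_to_source(E[5, ], E, "cosine", n_itr = 2000), 0)
    # singleton source -> exact distance regardless of n_itr
    one <- E[1, , drop = FALSE]
    expect_equal(min_distance_to_source(E[2, ], one, "manhattan", n_itr = 3),
                 manhattan_distance(E[2, ], E[1, ]))
    expect_error(min_distance_to_source(E[1, ], E[0, , drop = FALSE], "cosine"),
                 "nonempty")
  })
})

test_that("with ample draws the Monte-Carlo minimum matches the exhaustive minimum", {
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      df <- random_pairs_df(20)
      E <- make_encoded(df)
      target <- make_encoded(random_pairs_df(1))[1, ]
      exact <- min(apply(E, 1, function(b) cosine_distance(target, b)))
      mc <- min_distance_to_source(target, E, "cosine", n_itr = 10000)
      if (isTRUE(all.equal(mc, exact))) hits <- hits + 1
    })
  }
  expect_gte(hits, 19) # >= 95% of seeds
})

test_that("dataset_distance converges to the exhaustive one-way oracle", {
  withr::with_seed(42, {
    src <- random_pairs_df(50)
    tgt <- random_pairs_df(10)
  })
  for (m in c("cosine", "euclidean", "manhattan")) {
    mc <- dataset_distance(src, tgt, m, n_itr = 5000, seed = 43)
    expect_length(mc$d, 10)
    expect_equal(mc$mean_distance, mean(mc$d))
    oracle <- oracle_one_way_distance(src, tgt, m)
    expect_equal(mc$mean_distance, oracle, tolerance = 1e-12)
    # also equals the package's own exhaustive variant
    expect_equal(exhaustive_dataset_distance(src, tgt, m,
                                             direction = "target_to_source"),
                 oracle)
  }
})

test_that("a bootstrap of the source itself sits at distance ~0, orthogonal data at 1", {
  d <- generate_dataset(n_samples = 300, imbalance_ratio = 0.3, seed = 44)
  b <- stratified_bootstrap(d, size = 100, seed = 45)
  mc <- dataset_distance(d, b, "cosine", n_itr = 4000, seed = 46)
  expect_lt(mc$mean_distance, 1e-8)
  # deterministic given the seed
  mc2 <- dataset_distance(d, b, "cosine", n_itr = 4000, seed = 46)
  expect_identical(mc$d, mc2$d)
  # fully mismatched single-position pairs: disjoint one-hot blocks
  a_df <- tibble::tibble(sgrna_seq = "A", dna_seq = "A", label = 0)
  b_df <- tibble::tibble(sgrna_seq = "C", dna_seq = "C", label = 0)
  expect_equal(dataset_distance(a_df, b_df, "cosine", n_itr = 5,
                                seed = 1)$mean_distance, 1)
})

test_that("the exhaustive distance is symmetric in two-way form and guarded on size", {
  withr::with_seed(47, {
    x <- random_pairs_df(12)
    y <- random_pairs_df(9)
  })
  expect_equal(exhaustive_dataset_distance(x, x, "euclidean"), 0)
  two_xy <- exhaustive_dataset_distance(x, y, "cosine")
  two_yx <- exhaustive_dataset_distance(y, x, "cosine")
  expect_equal(two_xy, two_yx)
  # single mismatch T/A: the mismatched block differs from the matched one
  # in the extra character bit and the direction bit -> Hamming distance 2
  one <- tibble::tibble(sgrna_seq = "ACGT", dna_seq = "ACGT", label = 0)
  other <- tibble::tibble(sgrna_seq = "ACGT", dna_seq = "ACGA", label = 0)
  expect_equal(exhaustive_dataset_distance(one, other, "manhattan"), 2)
  expect_error(exhaustive_dataset_distance(x, y, "cosine", max_pairs = 10),
               "max_pairs")
})

test_that("Monte-Carlo minima are non-increasing in n_itr on a fixed stream", {
  withr::with_seed(48, {
    src <- random_pairs_df(200)
    tgt <- random_pairs_df(20)
  })
  means <- vapply(c(10, 100, 1000), function(k) {
    dataset_distance(src, tgt, "cosine", n_itr = k, seed = 49)$mean_distance
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})

test_that("min-max normalization maps the closest pair to 1 and the farthest to 0", {
  dist_av <- matrix(c(0, 2, 4, 6), 2, byrow = TRUE,
                    dimnames = list(c("a", "b"), c("a", "b")))
  S <- minmax_similarity(dist_av)
  expect_equal(unname(S), matrix(c(1, 2/3, 1/3, 0), 2, byrow = TRUE))
  expect_warning(S1 <- minmax_similarity(matrix(3, 2, 2)), "degenerate")
  expect_true(all(S1 == 1))
})

test_that("build_similarity_matrix averages replicates and normalizes over the full matrix", {
  ds <- list(
    A = generate_dataset(400, 0.3, seed = 51),
    B = generate_dataset(400, 0.3, seed = 52),
    C = generate_dataset(400, 0.3, seed = 53)
  )
  sim <- build_similarity_matrix(ds, metric = "cosine", n_itr = 300,
                                 bootstrap_size = 100, replicates = 2, seed = 1)
  expect_equal(dim(sim$dist_av), c(3, 3))
  expect_length(sim$dist_replicates, 2)
  expect_equal(sim$dist_av,
               (sim$dist_replicates[[1]] + sim$dist_replicates[[2]]) / 2)
  expect_true(all(sim$similarity >= 0 & sim$similarity <= 1))
  expect_equal(sum(sim$similarity == 1), 1)
  expect_equal(sum(sim$similarity == 0), 1)
  # similarity ordering reverses distance ordering
  expect_equal(order(sim$dist_av), rev(order(sim$similarity)))
  # reproducible from the same master seed
  sim2 <- build_similarity_matrix(ds, metric = "cosine", n_itr = 300,
                                  bootstrap_size = 100, replicates = 2, seed = 1)
  expect_identical(sim$dist_av, sim2$dist_av)
  expect_error(build_similarity_matrix(ds[1], metric = "cosine"), "two")
})

test_that("each dataset's own complete version dominates its bootstrap under all metrics", {
  ds <- list(
    A = generate_dataset(500, 0.2, seed = 54, mismatch_rate_active = 1,
                         mismatch_rate_inactive = 4),
    B = generate_dataset(500, 0.2, seed = 55, mismatch_rate_active = 2,
                         mismatch_rate_inactive = 6),
    C = generate_dataset(500, 0.2, seed = 56, mismatch_rate_active = 1.5,
                         mismatch_rate_inactive = 5)
  )
  for (m in c("cosine", "euclidean", "manhattan")) {
    sim <- build_similarity_matrix(ds, metric = m, n_itr = 500,
                                   bootstrap_size = 100, replicates = 2,
                                   seed = 2)
    for (nm in names(ds)) {
      expect_equal(recommend_source(sim, nm)$source[1], nm)
    }
  }
})

test_that("recommend_source ranks by descending similarity with lexicographic ties", {
  sim <- structure(list(
    similarity = matrix(c(0.9, 0.2, 0.5, 0.5, 0.1, 0.5), 3,
                        dimnames = list(c("a", "b", "c"), c("t1", "t2"))),
    dist_av = matrix(0, 3, 2), metric = "cosine"
  ), class = "similarity_matrix")
  r1 <- recommend_source(sim, "t1")
  expect_equal(r1$source, c("a", "c", "b"))
  expect_false(any(r1$tied))
  r2 <- recommend_source(sim, "t2")
  expect_equal(r2$source[1:2], c("a", "c")) # tie at 0.5 -> lexicographic
  expect_true(all(r2$tied[1:2]))
  expect_false(r2$tied[3])
  expect_error(recommend_source(sim, "nope"), "Unknown target")
})

test_that("tidy, glance and autoplot summarize a similarity run", {
  ds <- list(A = generate_dataset(200, 0.5, seed = 57),
             B = generate_dataset(200, 0.5, seed = 58))
  sim <- build_similarity_matrix(ds, metric = "manhattan", n_itr = 100,
                                 bootstrap_size = 50, replicates = 1, seed = 3)
  td <- tidy(sim)
  expect_equal(nrow(td), 4)
  expect_equal(td$mean_distance[td$source == "A" & td$target == "B"],
               sim$dist_av["A", "B"])
  gl <- glance(sim)
  expect_equal(gl$metric, "manhattan")
  expect_equal(gl$replicates, 1L)
  expect_s3_class(autoplot(sim), "ggplot")
})
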