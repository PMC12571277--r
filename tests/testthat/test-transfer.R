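test_that("transfer onto a bootstrap of the training source scores high AUC", {
  src <- generate_dataset(n_samples = 600, imbalance_ratio = 0.3,
                          mismatch_rate_active = 1, mismatch_rate_inactive = 6,
                          seed = 101)
  tgt <- stratified_bootstrap(src, size = 250, seed = 102)
  res <- run_transfer_experiment(
    list(src = src), tgt,
    list(lr = model_spec("logistic_regression")),
    tune = FALSE, seed = 103)
  expect_equal(nrow(res), 1)
  expect_gt(res$auc_roc, 0.9)
})

test_that("a source with labels independent of features transfers at chance level", {
  withr::with_seed(104, {
    src <- generate_dataset(n_samples = 600, imbalance_ratio = 1, seed = 105)
    src$label <- sample(src$label)
    tgt <- generate_dataset(n_samples = 250, imbalance_ratio = 1, seed = 106)
    res <- run_transfer_experiment(
      list(noise = src), tgt, list(model_spec("logistic_regression")),
      tune = FALSE, seed = 107)
    expect_lt(abs(res$auc_roc - 0.5), 0.15)
  })
})

test_that("an empty model list yields an empty result table, not an error", {
  src <- generate_dataset(n_samples = 100, imbalance_ratio = 1, seed = 108)
  res <- run_transfer_experiment(list(s = src), src, list())
  expect_equal(nrow(res), 0)
  expect_true(all(c("source", "model", "auc_roc", "f1", "brier") %in% names(res)))
})

test_that("experiment cells are keyed, contextualized on failure, and reproducible", {
  src <- generate_dataset(n_samples = 300, imbalance_ratio = 0.5, seed = 109)
  tgt <- stratified_bootstrap(src, size = 100, seed = 110)
  models <- list(lr = model_spec("logistic_regression"),
                 rf = model_spec("random_forest", list(ntree = 50)))
  res <- run_transfer_experiment(list(a = src, b = src), tgt, models,
                                 tune = FALSE, seed = 111)
  expect_equal(nrow(res), 4)
  expect_setequal(paste(res$source, res$model),
                  c("a lr", "a rf", "b lr", "b rf"))
  res2 <- run_transfer_experiment(list(a = src, b = src), tgt, models,
                                  tune = FALSE, seed = 111)
  expect_equal(res$auc_roc, res2$auc_roc)
  # failures carry the (source, model) context
  bad <- src; bad$label <- 1L
  expect_error(
    run_transfer_experiment(list(allpos = bad), tgt,
                            list(lr = model_spec("logistic_regression")),
                            tune = FALSE),
    "source 'allpos', model 'lr'")
})

test_that("tuned transfer uses the source's stratified train part", {
  src <- generate_dataset(n_samples = 240, imbalance_ratio = 0.5,
                          mismatch_rate_active = 1, mismatch_rate_inactive = 6,
                          seed = 112)
  tgt <- stratified_bootstrap(src, size = 100, seed = 113)
  res <- run_transfer_experiment(
    list(src = src), tgt, list(lr = model_spec("logistic_regression")),
    tune = TRUE, search_spaces = list(logistic_regression =
                                        list(lambda = c(1e-3, 10))),
    max_trials = 2, folds = 3, seed = 114)
  expect_gt(res$auc_roc, 0.85)
})

test_that("the full pipeline writes matrices, recommendations and a manifest", {
  ds <- list(A = generate_dataset(300, 0.3, seed = 115),
             B = generate_dataset(300, 0.3, seed = 116))
  out <- withr::local_tempdir()
  res <- run_pipeline(ds, metrics = "cosine", n_itr = 200,
                      bootstrap_size = 80, replicates = 1,
                      models = list(lr = model_spec("logistic_regression")),
                      tune = FALSE, seed = 5, out_dir = out)
  expect_true(file.exists(file.path(out, "similarity_cosine.csv")))
  expect_true(file.exists(file.path(out, "recommendations.csv")))
  expect_true(file.exists(file.path(out, "transfer_metrics.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(nrow(res$recommendations), 2)
  # each dataset recommends itself as its own bootstrap's source
  expect_equal(res$recommendations$source, res$recommendations$target)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$settings$seed, 5)
  # rerun with identical config reproduces the similarity matrix bytes
  out2 <- withr::local_tempdir()
  run_pipeline(ds, metrics = "cosine", n_itr = 200, bootstrap_size = 80,
               replicates = 1, models = list(lr = model_spec("logistic_regression")),
               tune = FALSE, seed = 5, out_dir = out2)
  expect_identical(readLines(file.path(out, "similarity_cosine.csv")),
                   readLines(file.path(out2, "similarity_cosine.csv")))
})
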