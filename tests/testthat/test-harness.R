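test_that("stratified folds partition, balance to +/-1, and reproduce", {
  # exact divisibility: 100 + 100 binary
  labels <- rep(1:2, each = 100)
  fa <- stratified_folds(labels, k = 10, seed = 3)
  expect_identical(sort(unique(fa$fold)), 1:10)
  for (f in 1:10) {
    expect_identical(sum(fa$fold == f & labels == 1), 10L)
    expect_identical(sum(fa$fold == f & labels == 2), 10L)
  }

  # 400 + 100 imbalanced geometry: folds of 40 + 10
  labels8 <- rep(1:2, c(400, 100))
  fa8 <- stratified_folds(labels8, k = 10, seed = 3)
  for (f in 1:10) {
    expect_identical(sum(fa8$fold == f & labels8 == 1), 40L)
    expect_identical(sum(fa8$fold == f & labels8 == 2), 10L)
  }

  # non-divisible counts: per-class fold sizes differ by at most 1
  labels3 <- rep(1:3, c(23, 17, 31))
  fa3 <- stratified_folds(labels3, k = 5, seed = 1)
  for (cl in 1:3) {
    per <- table(fa3$fold[labels3 == cl])
    expect_lte(max(per) - min(per), 1)
  }

  # determinism and seed sensitivity
  expect_identical(stratified_folds(labels, 10, seed = 42)$fold,
                   stratified_folds(labels, 10, seed = 42)$fold)
  expect_false(identical(stratified_folds(labels, 10, seed = 1)$fold,
                         stratified_folds(labels, 10, seed = 2)$fold))

  # class smaller than k
  expect_error(stratified_folds(rep(1:2, c(5, 100)), k = 10, seed = 1),
               "fewer than k")
})

test_that("leave-one-out degenerate limit reduces to a simple proportion", {
  labels <- rep(1:2, each = 4)
  fa <- stratified_folds(labels, k = 4, seed = 2)
  # k = per-class n: every fold holds exactly one record of each class
  for (f in 1:4) expect_identical(sum(fa$fold == f), 2L)
})

# One cheap shared-network run reused by the bookkeeping tests: paper-mode
# training (one network for the dataset) with fold-fitted projectors.
cheap_case_result <- function() {
  fixture("cheap_case_result", function() {
    ds <- tiny_binary_dataset(n = 15L, len = 1024L)
    config <- pipeline_config(
      training = training_config(learning_rate = 1e-3, batch_size = 30L,
                                 epochs = 2L, seed = 4),
      k = 5L, fold_seed = 8L, classifier_seed = 21L,
      dnn_scope = "dataset", pca_scope = "fold",
      short_epoch_policy = "compact")
    run_case(ds, case = NULL, config = config)
  })
}

test_that("a case run produces k x 7 metric sets with coherent aggregates", {
  res <- cheap_case_result()
  expect_s3_class(res, "case_result")
  expect_length(res$per_fold, 5L)
  sets <- unlist(lapply(res$per_fold, function(pf)
    lapply(pf, `[[`, "metrics")), recursive = FALSE)
  expect_length(sets, 5L * 7L)
  expect_true(all(vapply(sets, inherits, TRUE, "metric_set")))

  for (nm in classifier_names()) {
    pooled <- res$pooled[[nm]]
    # micro-aggregation identity: pooled confusion = sum of fold confusions
    expect_identical(pooled$confmat,
                     Reduce(`+`, lapply(res$per_fold, function(pf)
                       pf[[nm]]$confmat)))
    total_correct <- sum(diag(pooled$confmat))
    expect_equal(pooled$metrics$values[["ACC"]],
                 100 * total_correct / sum(pooled$confmat),
                 tolerance = 1e-12)
    # aggregated metrics lie within the fold range where defined
    fold_acc <- vapply(res$per_fold, function(pf)
      pf[[nm]]$metrics$values[["ACC"]], 1)
    expect_gte(pooled$fold_mean[["ACC"]], min(fold_acc) - 1e-9)
    expect_lte(pooled$fold_mean[["ACC"]], max(fold_acc) + 1e-9)
  }
})

test_that("fold details prove projector fitting never saw the test fold", {
  res <- cheap_case_result()
  n <- 30L
  for (f in seq_along(res$fold_details)) {
    det <- res$fold_details[[f]]
    expect_length(intersect(det$train_idx, det$test_idx), 0L)
    expect_identical(sort(c(det$train_idx, det$test_idx)), seq_len(n))
    expect_identical(det$n_projector_rows, length(det$train_idx))
  }

  # fingerprint check: recompute the shared feature maps deterministically
  # and verify each stored fingerprint matches the train-fold slice exactly
  ds <- tiny_binary_dataset(n = 15L, len = 1024L)
  arch <- build_compact_architecture(1024L, 2L)
  net <- train_network(arch, ds, training_config(
    learning_rate = 1e-3, batch_size = 30L, epochs = 2L, seed = 4))$network
  maps <- extract_feature_maps(net, ds)
  fp <- asNamespace("deepeeg")$data_fingerprint
  for (f in seq_along(res$fold_details)) {
    det <- res$fold_details[[f]]
    expect_identical(det$projector_fingerprint,
                     fp(maps[det$train_idx, , , drop = FALSE]))
    expect_false(isTRUE(all.equal(det$projector_fingerprint, fp(maps))))
  }
})

test_that("reports use the published column order and re-run identically", {
  res <- cheap_case_result()
  wide <- report_results(res)
  expect_identical(colnames(wide),
                   c("case", "classifier", "ACC", "SPF", "SEN", "PPV",
                     "NPV", "MCC", "F1", "AUC"))
  expect_identical(wide$classifier, classifier_names())

  long <- write_report(list(res))
  expect_identical(colnames(long), c("case", "classifier", "metric",
                                     "value"))
  expect_identical(nrow(long), 7L * 8L)

  md <- write_report(list(res), format = "markdown")
  expect_match(md[1], "ACC \\| SPF \\| SEN \\| PPV \\| NPV \\| MCC \\| F1")

  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.csv"); f2 <- file.path(dir, "r2.csv")
  write_report(list(res), f1)
  ds <- tiny_binary_dataset(n = 15L, len = 1024L)
  res2 <- run_case(ds, config = res$config)
  write_report(list(res2), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical re-run

  json <- file.path(dir, "case.json")
  write_case_json(res, json)
  obj <- jsonlite::read_json(json)
  expect_length(obj$per_fold, 5L)
  expect_length(obj$pooled, 7L)
})

test_that("run_all_cases assembles and evaluates multiple cases", {
  sets <- synthetic_records_by_set(c("F", "G", "H"), n_per_set = 10L,
                                   len = 1024L)
  cases <- builtin_cases()[c(13L, 17L)]  # one binary, one ternary
  config <- pipeline_config(
    training = training_config(learning_rate = 1e-3, batch_size = 30L,
                               epochs = 2L, seed = 4),
    k = 5L, fold_seed = 8L, dnn_scope = "dataset",
    short_epoch_policy = "compact", classifiers = c("SVC", "GNB"))
  results <- run_all_cases(sets, cases, config)
  expect_length(results, 2L)
  expect_identical(results[[1]]$case_id, "I")
  expect_identical(results[[2]]$case_id, "V")
  expect_length(results[[2]]$class_names, 3L)
  wide <- report_results(results)
  expect_identical(nrow(wide), 4L)
  # ternary case carries a macro-averaged one-vs-rest AUC
  expect_true(all(is.finite(wide$AUC)))
})

test_that("pipeline misconfiguration and missing sets fail loudly", {
  expect_error(pipeline_config(k = 10, classifiers = "LDA"))
  sets <- synthetic_records_by_set(c("F", "G"), n_per_set = 6L, len = 1024L)
  expect_error(run_all_cases(sets, builtin_cases()[17],
                             pipeline_config(k = 2L)),
               "H")
  # pca_scope = "full" requires a shared network
  ds <- tiny_binary_dataset(n = 6L, len = 1024L)
  bad <- pipeline_config(training = training_config(epochs = 1L),
                         k = 2L, dnn_scope = "fold", pca_scope = "full",
                         short_epoch_policy = "compact")
  expect_error(run_case(ds, config = bad), "requires dnn_scope")
})
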