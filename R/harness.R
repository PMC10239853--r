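#' Stratified k-fold assignment
#'
#' Within each class, record indices are shuffled (seeded) and dealt
#' round-robin to the k folds, so per-class counts across folds differ by
#' at most one and the partition is reproducible from the seed.
#'
#' @param labels Vector of class labels (any type).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: list with `fold` (integer
#'   fold index per record, in 1..k), `k` and `seed`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[counts < k][1L]
    stop(sprintf(
      "stratified_folds: class '%s' has %d members, fewer than k = %d",
      small, counts[[small]], k), call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(fold = fold, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Pipeline configuration for the experimental harness
#'
#' @param training A [training_config()] for the feature-extraction
#'   network. The reduced-epoch profile used throughout the test suite
#'   sets `epochs` low (the full replication profile is 300).
#' @param k Number of cross-validation folds (default 10).
#' @param fold_seed Seed for the stratified split. Independent of the
#'   classifier seed so all classifiers see identical folds (paired
#'   comparison).
#' @param classifier_seed Seed applied to each stochastic classifier fit.
#' @param classifiers Character vector of classifiers to run (default all
#'   seven).
#' @param dnn_scope `"fold"` (strict: the network is retrained inside every
#'   training fold; leakage-safe, the default) or `"dataset"`
#'   ("paper mode": one network is trained on the full dataset and its
#'   features reused for every fold).
#' @param pca_scope `"fold"` (projectors fitted on the training fold only,
#'   default) or `"full"` (fitted once on all records; only meaningful
#'   together with `dnn_scope = "dataset"`).
#' @param short_epoch_policy How to handle epochs too short for the
#'   reference architecture: `"pad"` (symmetric zero-padding to
#'   `pad_length`, preserving the published 23 x 128 feature geometry) or
#'   `"compact"` (use [build_compact_architecture()] at the native
#'   length).
#' @param pad_length Target length for the `"pad"` policy.
#' @param classifier_params Optional per-classifier hyperparameter
#'   overrides.
#' @param verbose Emit per-stage log lines (stage, fold, seed, input
#'   fingerprint, duration).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(training = training_config(epochs = 30L),
                            k = 10L, fold_seed = 1L, classifier_seed = 42L,
                            classifiers = classifier_names(),
                            dnn_scope = c("fold", "dataset"),
                            pca_scope = c("fold", "full"),
                            short_epoch_policy = c("pad", "compact"),
                            pad_length = 4097L,
                            classifier_params = list(),
                            verbose = FALSE) {
  stopifnot(inherits(training, "training_config"),
            all(classifiers %in% classifier_names()))
  structure(list(training = training, k = as.integer(k),
                 fold_seed = as.integer(fold_seed),
                 classifier_seed = as.integer(classifier_seed),
                 classifiers = classifiers,
                 dnn_scope = match.arg(dnn_scope),
                 pca_scope = match.arg(pca_scope),
                 short_epoch_policy = match.arg(short_epoch_policy),
                 pad_length = as.integer(pad_length),
                 classifier_params = classifier_params,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

log_stage <- function(config, stage, fold, t0, fingerprint = NA) {
  if (!config$verbose) return(invisible())
  message(sprintf(
    "[deepeeg] stage=%s fold=%s seed=%d fingerprint=%s elapsed=%.2fs",
    stage, fold, config$fold_seed, format(fingerprint),
    as.numeric(Sys.time() - t0, units = "secs")))
}

# Cheap order-sensitive fingerprint of a numeric object, used to assert
# that per-fold stages saw exactly the intended records.
data_fingerprint <- function(x) {
  v <- as.numeric(x)
  n <- length(v)
  round(sum(v * (seq_len(n) %% 97 + 1)) + n, 6)
}

resolve_architecture <- function(dataset, config) {
  L <- epoch_length(dataset)
  k_classes <- length(dataset$class_names)
  ref_ok <- tryCatch({
    build_architecture(L, k_classes)
  }, error = function(e) NULL)
  if (!is.null(ref_ok)) return(list(arch = ref_ok, dataset = dataset))
  if (config$short_epoch_policy == "pad") {
    padded <- pad_dataset(dataset, config$pad_length)
    list(arch = build_architecture(config$pad_length, k_classes),
         dataset = padded)
  } else {
    list(arch = build_compact_architecture(L, k_classes), dataset = dataset)
  }
}

fit_fold_classifiers <- function(config, tr_scores, tr_labels, te_scores,
                                 te_labels, n_classes) {
  out <- list()
  for (nm in config$classifiers) {
    handle <- make_classifier(nm, seed = config$classifier_seed,
                              params = c(config$classifier_params[[nm]]))
    fit <- handle$fit(tr_scores, tr_labels)
    pred <- handle$predict(fit, te_scores)
    confmat <- table(factor(te_labels, levels = seq_len(n_classes)),
                     factor(pred$class, levels = seq_len(n_classes)))
    out[[nm]] <- list(
      metrics = case_metric_row(confmat),
      confmat = unclass(confmat),
      truth = te_labels,
      predicted = pred$class,
      scores = pred$scores)
  }
  out
}

#' Run the full pipeline for one case
#'
#' For each of the k stratified folds: train (or reuse, depending on
#' `dnn_scope`) the convolutional feature extractor on the training
#' records, export the tap-layer feature maps, fit the per-channel PCA
#' projectors on the training maps, project both splits, fit every shallow
#' classifier on the projected training features and score the held-out
#' fold. Results are aggregated both by pooling the fold confusion
#' matrices (micro) and by averaging per-fold metrics (macro over folds).
#'
#' @param dataset A [labeled_dataset()] assembled for the case (e.g. by
#'   [assemble_case()] or [generate_dataset()]).
#' @param case Optional [case_definition()]; used for the result's
#'   `case_id`.
#' @param config A [pipeline_config()].
#' @return Object of class `case_result` with elements `case_id`,
#'   `class_names`, `folds` (the `fold_assignment`), `per_fold` (per fold,
#'   per classifier: `metric_set`, confusion matrix, truth, predictions,
#'   score matrix), `pooled` (per classifier: pooled confusion matrix and
#'   `metric_set`, fold-mean metrics, ROC/AUC), `fold_details` (per fold:
#'   train/test indices and the fingerprint of the maps the projectors were
#'   fitted on), and the `config` snapshot.
#' @export
run_case <- function(dataset, case = NULL, config = pipeline_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  res <- resolve_architecture(dataset, config)
  arch <- res$arch
  dataset <- res$dataset
  n_classes <- length(dataset$class_names)
  n <- n_epochs(dataset)

  folds <- stratified_folds(dataset$labels, config$k, config$fold_seed)
  log_stage(config, "folds", NA, t0, data_fingerprint(folds$fold))

  shared_net <- NULL
  shared_maps <- NULL
  if (config$dnn_scope == "dataset") {
    t1 <- Sys.time()
    shared_net <- train_network(arch, dataset, config$training)$network
    shared_maps <- extract_feature_maps(shared_net, dataset)
    log_stage(config, "train-shared", NA, t1, data_fingerprint(shared_maps))
  }

  per_fold <- vector("list", config$k)
  fold_details <- vector("list", config$k)
  for (f in seq_len(config$k)) {
    t1 <- Sys.time()
    te_idx <- which(folds$fold == f)
    tr_idx <- which(folds$fold != f)
    fold_res <- tryCatch({
      if (config$dnn_scope == "fold") {
        net <- train_network(arch, subset_dataset(dataset, tr_idx),
                             config$training)$network
        tr_maps <- extract_feature_maps(net, subset_dataset(dataset, tr_idx))
        te_maps <- extract_feature_maps(net, subset_dataset(dataset, te_idx))
      } else {
        tr_maps <- structure(shared_maps[tr_idx, , , drop = FALSE],
                             class = "feature_map_batch")
        te_maps <- structure(shared_maps[te_idx, , , drop = FALSE],
                             class = "feature_map_batch")
      }
      fit_maps <- if (config$pca_scope == "fold") tr_maps else shared_maps
      if (is.null(fit_maps)) {
        stop("pca_scope = 'full' requires dnn_scope = 'dataset'",
             call. = FALSE)
      }
      projectors <- fit_channel_projectors(fit_maps)
      tr_scores <- project_features(tr_maps, projectors)
      te_scores <- project_features(te_maps, projectors)
      list(
        classifiers = fit_fold_classifiers(
          config, tr_scores, dataset$labels[tr_idx], te_scores,
          dataset$labels[te_idx], n_classes),
        details = list(train_idx = tr_idx, test_idx = te_idx,
                       n_projector_rows = dim(fit_maps)[1L],
                       projector_fingerprint = data_fingerprint(fit_maps)))
    }, error = function(e) {
      stop(sprintf("run_case: fold %d failed: %s", f, conditionMessage(e)),
           call. = FALSE)
    })
    per_fold[[f]] <- fold_res$classifiers
    fold_details[[f]] <- fold_res$details
    log_stage(config, "fold", f, t1,
              fold_res$details$projector_fingerprint)
  }

  pooled <- list()
  for (nm in config$classifiers) {
    confmat <- Reduce(`+`, lapply(per_fold, function(pf) pf[[nm]]$confmat))
    fold_vals <- do.call(rbind, lapply(per_fold, function(pf)
      pf[[nm]]$metrics$values))
    truth <- unlist(lapply(per_fold, function(pf) pf[[nm]]$truth))
    scores <- do.call(rbind, lapply(per_fold, function(pf) pf[[nm]]$scores))
    if (n_classes == 2L) {
      roc <- roc_curve_auc(truth, scores[, 2L], positive_class = 2L)
      auc <- roc$auc
    } else {
      rocs <- lapply(seq_len(n_classes), function(j)
        roc_curve_auc(truth == j, scores[, j], positive_class = TRUE))
      auc <- mean(vapply(rocs, function(r) r$auc, 1))
      roc <- rocs
    }
    pooled[[nm]] <- list(
      confmat = confmat,
      metrics = case_metric_row(confmat),
      fold_mean = colMeans(fold_vals, na.rm = TRUE),
      roc = roc, auc = auc)
  }

  structure(list(case_id = if (!is.null(case)) case$case_id else
                   dataset$dataset_id,
                 class_names = dataset$class_names,
                 folds = folds, per_fold = per_fold, pooled = pooled,
                 fold_details = fold_details, config = config),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result %s> %d classes, %d folds x %d classifiers\n",
              x$case_id, length(x$class_names), x$folds$k,
              length(x$config$classifiers)))
  print(report_results(list(x)), row.names = FALSE)
  invisible(x)
}

#' Run every case of an experiment
#'
#' Assembles each case from the per-set record lists and runs the full
#' pipeline on it.
#'
#' @param records_by_set Named list mapping set id to record lists
#'   ([load_set()] output or synthetic equivalents).
#' @param cases List of [case_definition()] objects (default
#'   [builtin_cases()]).
#' @param config A [pipeline_config()].
#' @return List of `case_result` objects, one per case.
#' @export
run_all_cases <- function(records_by_set, cases = builtin_cases(),
                          config = pipeline_config()) {
  lapply(cases, function(cs) {
    run_case(assemble_case(records_by_set, cs), cs, config)
  })
}

#' Tabulate case results
#'
#' One row per (case, classifier) with the seven pooled metrics in the
#' reporting column order ACC, SPF, SEN, PPV, NPV, MCC, F1 (percent, 2
#' decimals in formatted output). `aggregate = "fold_mean"` reports the
#' fold-averaged metrics instead of the pooled (micro) ones.
#'
#' @param results List of `case_result` objects (or a single one).
#' @param aggregate `"pooled"` (default) or `"fold_mean"`.
#' @return A `data.frame` with columns `case`, `classifier`, `ACC`, `SPF`,
#'   `SEN`, `PPV`, `NPV`, `MCC`, `F1`, `AUC`.
#' @export
report_results <- function(results, aggregate = c("pooled", "fold_mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(results, "case_result")) results <- list(results)
  rows <- list()
  for (res in results) {
    for (nm in names(res$pooled)) {
      p <- res$pooled[[nm]]
      vals <- if (aggregate == "pooled") p$metrics$values else p$fold_mean
      rows[[length(rows) + 1L]] <- data.frame(
        case = res$case_id, classifier = nm,
        ACC = vals[["ACC"]], SPF = vals[["SPF"]], SEN = vals[["SEN"]],
        PPV = vals[["PPV"]], NPV = vals[["NPV"]], MCC = vals[["MCC"]],
        F1 = vals[["F1"]], AUC = p$auc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write results in long CSV or markdown form
#'
#' The long CSV has one row per (case, classifier, metric, value); the
#' markdown table mirrors [report_results()] with values printed to two
#' decimals.
#'
#' @param results List of `case_result` objects.
#' @param path Output file path (CSV format only; ignored for markdown,
#'   which is returned as a character vector).
#' @param format `"csv"` or `"markdown"`.
#' @param aggregate Passed to [report_results()].
#' @return For `"csv"`, the long-format `data.frame` (invisibly, after
#'   writing if `path` is given); for `"markdown"`, a character vector of
#'   table lines.
#' @export
write_report <- function(results, path = NULL,
                         format = c("csv", "markdown"),
                         aggregate = c("pooled", "fold_mean")) {
  format <- match.arg(format)
  wide <- report_results(results, aggregate = match.arg(aggregate))
  if (format == "csv") {
    long <- stats::reshape(
      wide, direction = "long",
      varying = c("ACC", "SPF", "SEN", "PPV", "NPV", "MCC", "F1", "AUC"),
      v.names = "value", timevar = "metric",
      times = c("ACC", "SPF", "SEN", "PPV", "NPV", "MCC", "F1", "AUC"))
    long <- long[order(long$case, long$classifier), c("case", "classifier",
                                                      "metric", "value")]
    rownames(long) <- NULL
    if (!is.null(path)) utils::write.csv(long, path, row.names = FALSE)
    return(invisible(long))
  }
  num <- vapply(wide[, -(1:2)], function(col) sprintf("%.2f", col),
                character(nrow(wide)))
  num <- matrix(num, nrow = nrow(wide))
  header <- c("case", "classifier", "ACC", "SPF", "SEN", "PPV", "NPV",
              "MCC", "F1", "AUC")
  lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(header)), collapse = "|"),
                    "|"),
             apply(cbind(wide$case, wide$classifier, num), 1L, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")))
  lines
}

#' Save per-case results as JSON
#'
#' All folds, confusion matrices and pooled metrics of one case, as a
#' machine-readable record of the run.
#'
#' @param result A `case_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_json <- function(result, path) {
  stopifnot(inherits(result, "case_result"))
  obj <- list(
    case_id = result$case_id, class_names = result$class_names,
    k = result$folds$k, fold = result$folds$fold,
    pooled = lapply(result$pooled, function(p) list(
      confmat = p$confmat, metrics = as.list(p$metrics$values),
      fold_mean = as.list(p$fold_mean), auc = p$auc)),
    per_fold = lapply(result$per_fold, function(pf) lapply(pf, function(e)
      list(metrics = as.list(e$metrics$values), confmat = e$confmat))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
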