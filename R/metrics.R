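#' Binary confusion counts
#'
#' Tabulates true/false positives and negatives of a prediction vector
#' against truth, relative to a designated positive class.
#'
#' @param y_true,y_pred Equal-length vectors of class labels.
#' @param positive_class The label counted as positive.
#' @return Object of class `confusion_counts`: list with integer `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion_counts: y_true and y_pred differ in length",
         call. = FALSE)
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

metric_set <- function(values, undefined) {
  structure(list(values = values, undefined = undefined),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- x$values
  s <- vapply(names(v), function(nm) {
    if (x$undefined[nm]) "undef" else sprintf("%.2f", v[nm])
  }, "")
  cat(paste(sprintf("%s=%s", names(v), s), collapse = "  "), "\n")
  invisible(x)
}

#' The seven binary classification metrics
#'
#' Evaluates, in percent: sensitivity SEN = TP/(TP+FN), specificity
#' SPF = TN/(TN+FP), accuracy ACC = (TP+TN)/total, positive predictive
#' value PPV = TP/(TP+FP), negative predictive value NPV = TN/(TN+FN),
#' the Matthews correlation coefficient
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)), and
#' F1 = 2*TP/(2*TP+FN+FP). Any metric whose denominator is zero is flagged
#' undefined (`NA` value plus an explicit flag) rather than silently
#' zeroed, so fold averages are never corrupted.
#'
#' @param counts A [confusion_counts()].
#' @return A `metric_set`: `$values` is a named numeric vector (percent,
#'   `NA` where undefined), `$undefined` the matching logical flags.
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (tp + fp + tn + fn < 1) {
    stop("binary_metrics: empty confusion counts", call. = FALSE)
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  mcc_den <- as.double(tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  vals <- c(
    SEN = ratio(tp, tp + fn),
    SPF = ratio(tn, tn + fp),
    ACC = ratio(tp + tn, tp + tn + fn + fp),
    PPV = ratio(tp, tp + fp),
    NPV = ratio(tn, tn + fn),
    MCC = if (mcc_den == 0) NA_real_ else
      100 * (as.double(tp) * tn - as.double(fn) * fp) / sqrt(mcc_den),
    F1 = ratio(2 * tp, 2 * tp + fn + fp))
  metric_set(vals, is.na(vals))
}

#' Multi-class metrics from a confusion matrix
#'
#' `macro_ovr` collapses each class one-vs-rest, evaluates
#' [binary_metrics()] per class, and averages each metric over the classes
#' where it is defined. `micro` pools: ACC = trace/total and the remaining
#' metrics are computed from the pooled one-vs-rest counts (for which SEN,
#' PPV and F1 all equal the micro accuracy). The default reporting
#' convention of the package is macro one-vs-rest for SEN/SPF/PPV/NPV/
#' MCC/F1 with micro (overall) ACC; see [case_metric_row()].
#'
#' @param confmat K x K matrix of counts, rows = truth, columns =
#'   prediction.
#' @param scheme `"macro_ovr"` or `"micro"`.
#' @return A `metric_set` with attribute `scheme`.
#' @export
multiclass_metrics <- function(confmat, scheme = c("macro_ovr", "micro")) {
  scheme <- match.arg(scheme)
  confmat <- as.matrix(confmat)
  if (nrow(confmat) != ncol(confmat) || nrow(confmat) < 2L) {
    stop("multiclass_metrics: confusion matrix must be square, K >= 2",
         call. = FALSE)
  }
  total <- sum(confmat)
  k <- nrow(confmat)
  ovr <- function(j) {
    tp <- confmat[j, j]
    fn <- sum(confmat[j, ]) - tp
    fp <- sum(confmat[, j]) - tp
    structure(list(TP = tp, FP = fp, TN = total - tp - fn - fp, FN = fn),
              class = "confusion_counts")
  }
  if (scheme == "macro_ovr") {
    per_class <- lapply(seq_len(k), function(j) binary_metrics(ovr(j))$values)
    m <- do.call(rbind, per_class)
    vals <- colMeans(m, na.rm = TRUE)
    vals[colSums(!is.na(m)) == 0L] <- NA_real_
  } else {
    pooled <- Reduce(function(a, b) list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                                         TN = a$TN + b$TN, FN = a$FN + b$FN),
                     lapply(seq_len(k), ovr))
    class(pooled) <- "confusion_counts"
    vals <- binary_metrics(pooled)$values
    vals["ACC"] <- 100 * sum(diag(confmat)) / total
  }
  out <- metric_set(vals, is.na(vals))
  attr(out, "scheme") <- scheme
  out
}

#' Per-case metric row in the reporting convention
#'
#' For binary confusion matrices this is exactly [binary_metrics()] with
#' the second class taken as positive (the built-in cases list the
#' abnormal/seizure group second); for K >= 3 classes, overall accuracy
#' (trace/total) is combined with macro one-vs-rest values for the other
#' six metrics.
#'
#' @param confmat K x K confusion matrix (rows = truth).
#' @return A `metric_set` in column order SEN, SPF, ACC, PPV, NPV, MCC, F1.
#' @export
case_metric_row <- function(confmat) {
  confmat <- as.matrix(confmat)
  if (nrow(confmat) == 2L) {
    counts <- structure(list(TP = confmat[2L, 2L], FP = confmat[1L, 2L],
                             TN = confmat[1L, 1L], FN = confmat[2L, 1L]),
                        class = "confusion_counts")
    return(binary_metrics(counts))
  }
  macro <- multiclass_metrics(confmat, "macro_ovr")
  vals <- macro$values
  vals["ACC"] <- 100 * sum(diag(confmat)) / sum(confmat)
  metric_set(vals, is.na(vals))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties grouped
#' into a single step), tracing (FPR, TPR) from (0,0) to (1,1); AUC is the
#' trapezoid-rule area, which equals the Mann-Whitney concordance
#' probability (ties counted 1/2).
#'
#' @param y_true Vector of labels.
#' @param scores Real-valued scores, higher = more confidently positive.
#' @param positive_class Label treated as positive.
#' @return Object of class `roc_curve`: list with `fpr`, `tpr`,
#'   `thresholds` and `auc` (`NA` with an `undefined` flag when `y_true`
#'   contains a single class).
#' @export
roc_curve_auc <- function(y_true, scores, positive_class) {
  if (length(y_true) != length(scores)) {
    stop("roc_curve_auc: y_true and scores differ in length", call. = FALSE)
  }
  pos <- y_true == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    return(structure(list(fpr = c(0, 1), tpr = c(0, 1),
                          thresholds = c(Inf, -Inf), auc = NA_real_,
                          undefined = TRUE),
                     class = "roc_curve"))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into one threshold step
  grp_end <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[grp_end]), auc = auc,
                 undefined = FALSE),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("<roc_curve> undefined (single-class truth)\n")
  else cat(sprintf("<roc_curve> %d points, AUC = %.4f\n",
                   length(x$fpr), x$auc))
  invisible(x)
}

#' Write ROC coordinates to a two-column CSV
#'
#' @param roc A `roc_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr), path,
                   row.names = FALSE)
  invisible(path)
}
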