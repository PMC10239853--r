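# Independent oracle: direct evaluation of the seven ratio formulas,
# kept separate from the package implementation.
oracle_metrics <- function(tp, fn, tn, fp) {
  c(SEN = 100 * tp / (tp + fn),
    SPF = 100 * tn / (tn + fp),
    ACC = 100 * (tp + tn) / (tp + tn + fn + fp),
    PPV = 100 * tp / (tp + fp),
    NPV = 100 * tn / (tn + fn),
    MCC = 100 * (tp * tn - fn * fp) /
      sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)),
    F1 = 100 * 2 * tp / (2 * tp + fn + fp))
}

test_that("confusion counts tabulate correctly, including boundaries", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1), positive_class = 1)
  expect_identical(unclass(cc)[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))

  perfect <- confusion_counts(rep(c("a", "b"), each = 50),
                              rep(c("a", "b"), each = 50), "a")
  expect_identical(c(perfect$TP, perfect$FP, perfect$TN, perfect$FN),
                   c(50L, 0L, 50L, 0L))

  all_pos <- confusion_counts(c(1, 1, 0), c(1, 1, 1), 1)
  expect_identical(c(all_pos$FN, all_pos$TN), c(0L, 0L))

  expect_error(confusion_counts(1:3, 1:4, 1), "differ in length")
})

test_that("the seven metrics match direct formula evaluation", {
  # perfect classifier
  perfect <- binary_metrics(confusion_counts(rep(1:2, 50), rep(1:2, 50), 2))
  expect_equal(unname(perfect$values),
               rep(100, 7), tolerance = 1e-12)

  # total inversion: ACC = 0, MCC = -100
  inv <- binary_metrics(confusion_counts(rep(c(1, 0), each = 50),
                                         rep(c(0, 1), each = 50), 1))
  expect_equal(inv$values[["ACC"]], 0)
  expect_equal(inv$values[["MCC"]], -100)

  # general counts against the oracle, including the canonical example
  cases <- list(c(45, 5, 48, 2), c(10, 0, 5, 5), c(7, 3, 9, 1),
                c(400, 0, 99, 1))
  for (cs in cases) {
    counts <- structure(list(TP = cs[1], FN = cs[2], TN = cs[3],
                             FP = cs[4]),
                        class = "confusion_counts")
    got <- binary_metrics(counts)$values
    expect_equal(got, oracle_metrics(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10)
  }
  # spot-check printed-precision values of the canonical example
  got <- binary_metrics(structure(list(TP = 45, FN = 5, TN = 48, FP = 2),
                                  class = "confusion_counts"))$values
  expect_equal(round(got[c("SEN", "SPF", "ACC")], 2),
               c(SEN = 90, SPF = 96, ACC = 93))
})

test_that("undefined metrics are flagged, never silently zeroed", {
  # no predicted positives: PPV undefined, F1 = 0 (TP = 0, FN + FP > 0)
  m <- binary_metrics(structure(list(TP = 0, FN = 10, TN = 90, FP = 0),
                                class = "confusion_counts"))
  expect_true(m$undefined[["PPV"]])
  expect_true(is.na(m$values[["PPV"]]))
  expect_false(m$undefined[["F1"]])
  expect_equal(m$values[["F1"]], 0)
  expect_true(m$undefined[["MCC"]])  # a zero factor in the denominator
})

test_that("metrics are ratio-homogeneous and flip correctly under inversion", {
  base <- c(tp = 12, fn = 4, tn = 20, fp = 6)
  m1 <- binary_metrics(structure(as.list(setNames(base, c("TP", "FN", "TN",
                                                          "FP"))),
                                 class = "confusion_counts"))
  m3 <- binary_metrics(structure(as.list(setNames(3 * base,
                                                  c("TP", "FN", "TN",
                                                    "FP"))),
                                 class = "confusion_counts"))
  expect_equal(m1$values, m3$values, tolerance = 1e-12)

  # inverting predictions swaps TP<->FP and TN<->FN
  inv <- binary_metrics(structure(list(TP = 6, FN = 20, TN = 4, FP = 12),
                                  class = "confusion_counts"))
  expect_equal(inv$values[["MCC"]], -m1$values[["MCC"]], tolerance = 1e-12)
  expect_equal(inv$values[["ACC"]], 100 - m1$values[["ACC"]],
               tolerance = 1e-12)
})

test_that("multi-class schemes satisfy their closed forms", {
  # perfect 3-class
  perfect <- multiclass_metrics(diag(3) * 50, "macro_ovr")
  expect_equal(unname(perfect$values), rep(100, 7), tolerance = 1e-12)
  expect_equal(unname(multiclass_metrics(diag(3) * 50, "micro")$values[["ACC"]]),
               100)

  # uniform confusion: macro SEN = 100 / K
  for (K in c(2, 3, 5)) {
    conf <- matrix(10, K, K)
    m <- multiclass_metrics(conf, "macro_ovr")
    expect_equal(m$values[["SEN"]], 100 / K, tolerance = 1e-12)
    expect_equal(multiclass_metrics(conf, "micro")$values[["ACC"]],
                 100 / K, tolerance = 1e-12)
  }

  # K = 2 macro on a symmetric matrix: SEN equals (SEN + SPF)/2 of the
  # direct binary computation (each class is the other's "rest")
  conf <- matrix(c(40, 10, 10, 40), 2, byrow = TRUE)
  macro <- multiclass_metrics(conf, "macro_ovr")
  bin <- binary_metrics(structure(list(TP = 40, FN = 10, TN = 40, FP = 10),
                                  class = "confusion_counts"))
  expect_equal(macro$values[["SEN"]],
               (bin$values[["SEN"]] + bin$values[["SPF"]]) / 2,
               tolerance = 1e-12)

  expect_error(multiclass_metrics(matrix(1, 2, 3)), "square")
})

test_that("ROC sweep is a valid curve and AUC equals pairwise concordance", {
  # perfectly separating scores
  expect_equal(roc_curve_auc(c(0, 0, 1, 1), c(.1, .2, .8, .9), 1)$auc, 1)
  expect_equal(roc_curve_auc(c(0, 0, 1, 1), c(.9, .8, .2, .1), 1)$auc, 0)

  set.seed(77)
  for (rep in 1:3) {
    n <- 200L
    y <- rep(c(0, 1), each = n / 2)
    scores <- rnorm(n) + 0.5 * y
    scores[sample(n, 20)] <- round(scores[sample(n, 20)], 1)  # force ties
    roc <- roc_curve_auc(y, scores, 1)

    # curve validity
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[length(roc$fpr)], 1)
    expect_equal(roc$tpr[length(roc$tpr)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))

    # brute-force Mann-Whitney concordance oracle (ties count 1/2)
    pos <- scores[y == 1]; neg <- scores[y == 0]
    conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc$auc, mean(conc), tolerance = 1e-12)
  }

  # near-chance AUC for unrelated scores
  set.seed(5)
  y <- rep(c(0, 1), 1000)
  auc <- roc_curve_auc(y, rnorm(2000), 1)$auc
  expect_lt(abs(auc - 0.5), 0.05)

  # single-class truth flags undefined
  und <- roc_curve_auc(rep(1, 5), rnorm(5), 1)
  expect_true(und$undefined)
  expect_true(is.na(und$auc))
})

test_that("ROC/AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  y <- rep(c(0, 1), each = 60)
  s <- rnorm(120) + y
  ours <- roc_curve_auc(y, s, 1)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
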