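#' The seven shallow classifiers
#'
#' @return Character vector of the supported classifier names: support
#'   vector classifier (SVC), k-nearest neighbors (KNN), random forest
#'   (RF), Gaussian naive Bayes (GNB), gradient boosting (GB), decision
#'   tree (DT) and multi-layer perceptron (MLP).
#' @export
classifier_names <- function() {
  c("SVC", "KNN", "RF", "GNB", "GB", "DT", "MLP")
}

#' Default shallow-classifier hyperparameters
#'
#' The study states no classifier hyperparameters, so these library
#' defaults are frozen here (and echoed in run logs) for reproducibility:
#' SVC radial kernel with `cost = 1`; KNN with `k = 5` votes; RF with 300
#' trees; GB with 100 rounds of depth-3 trees at learning rate 0.3; DT
#' with standard CART pruning settings; MLP with one 16-unit hidden layer,
#' weight decay 1e-4, 200 iterations. GNB has none.
#'
#' @return Named list of hyperparameter lists.
#' @export
default_classifier_params <- function() {
  list(
    SVC = list(kernel = "radial", cost = 1),
    KNN = list(k = 5L),
    RF  = list(ntree = 300L),
    GNB = list(),
    GB  = list(nrounds = 100L, max_depth = 3L, eta = 0.3),
    DT  = list(cp = 0.01, minsplit = 20L),
    MLP = list(size = 16L, decay = 1e-4, maxit = 200L)
  )
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Ensure an n x K score matrix with one column per class level, in order.
full_score_matrix <- function(partial, levels) {
  out <- matrix(0, nrow(partial), length(levels),
                dimnames = list(NULL, levels))
  keep <- intersect(colnames(partial), levels)
  out[, keep] <- partial[, keep]
  out
}

#' Construct a shallow classifier handle
#'
#' Returns a uniform fit/predict handle around the established R
#' implementations: [e1071::svm()] (SVC), [class::knn()] (KNN),
#' [randomForest::randomForest()] (RF), [e1071::naiveBayes()] (GNB),
#' [xgboost::xgb.train()] (GB), [rpart::rpart()] (DT) and [nnet::nnet()]
#' (MLP). Stochastic learners (RF, GB, MLP, SVC's internal shrinking is
#' deterministic) are seeded at fit time; GNB and KNN are deterministic,
#' so the seed is irrelevant for them.
#'
#' @param name One of [classifier_names()].
#' @param seed Integer seed applied before each stochastic fit.
#' @param params Optional hyperparameter overrides, merged over
#'   [default_classifier_params()].
#' @return A `classifier_handle` with elements `name`, `params`,
#'   `fit(x, y)` and `predict(model, x)`. `fit` takes a numeric feature
#'   matrix and an integer label vector (1..K); `predict` returns
#'   `list(class = integer predictions, scores = n x K score matrix)`
#'   whose scores feed ROC analysis.
#' @export
make_classifier <- function(name, seed = 1L,
                            params = default_classifier_params()[[name]]) {
  if (!name %in% classifier_names()) {
    stop(sprintf("make_classifier: unknown classifier '%s'", name),
         call. = FALSE)
  }
  p <- utils::modifyList(default_classifier_params()[[name]],
                         as.list(params))
  fit_fun <- switch(name,
    SVC = function(x, y) {
      lev <- sort(unique(y))
      m <- with_seed(seed, suppressWarnings(e1071::svm(
        x, factor(y, levels = lev), kernel = p$kernel, cost = p$cost,
        probability = TRUE)))  # warns (harmlessly) on constant columns
      list(model = m, levels = lev)
    },
    KNN = function(x, y) list(x = x, y = y, levels = sort(unique(y))),
    RF = function(x, y) {
      lev <- sort(unique(y))
      m <- with_seed(seed, randomForest::randomForest(
        x, factor(y, levels = lev), ntree = p$ntree))
      list(model = m, levels = lev)
    },
    GNB = function(x, y) {
      lev <- sort(unique(y))
      df <- as.data.frame(x)
      m <- e1071::naiveBayes(df, factor(y, levels = lev))
      # variance floor: zero within-class variances (constant features)
      # would produce NaN posteriors; lift them to a tiny fraction of the
      # largest observed spread, as Gaussian NB implementations usually do
      sds <- unlist(lapply(m$tables, function(tb) tb[, 2L]))
      floor_sd <- max(max(sds, na.rm = TRUE), 1) * 1e-6
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2L] <- pmax(tb[, 2L], floor_sd)
        tb
      })
      list(model = m, levels = lev, cols = colnames(df))
    },
    GB = function(x, y) {
      lev <- sort(unique(y))
      k <- length(lev)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = match(y, lev) - 1L)
      pars <- list(max_depth = p$max_depth, eta = p$eta, nthread = 1L,
                   seed = seed)
      if (k > 2L) {
        pars$objective <- "multi:softprob"; pars$num_class <- k
      } else {
        pars$objective <- "binary:logistic"
      }
      m <- with_seed(seed, xgboost::xgb.train(params = pars, data = dtrain,
                                              nrounds = p$nrounds,
                                              verbose = 0))
      list(model = m, levels = lev)
    },
    DT = function(x, y) {
      lev <- sort(unique(y))
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = lev)
      m <- with_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(cp = p$cp, minsplit = p$minsplit)))
      list(model = m, levels = lev, cols = colnames(x))
    },
    MLP = function(x, y) {
      lev <- sort(unique(y))
      yi <- nnet::class.ind(factor(y, levels = lev))
      m <- with_seed(seed, nnet::nnet(
        x, yi, size = p$size, decay = p$decay, maxit = p$maxit,
        softmax = length(lev) > 1L, MaxNWts = 50000L, trace = FALSE))
      list(model = m, levels = lev)
    })

  predict_fun <- switch(name,
    SVC = function(fit, x) {
      pr <- predict(fit$model, x, probability = TRUE)
      sc <- attr(pr, "probabilities")
      sc <- full_score_matrix(sc, as.character(fit$levels))
      list(class = fit$levels[max.col(sc, ties.method = "first")],
           scores = sc)
    },
    KNN = function(fit, x) {
      lev <- fit$levels
      pr <- class::knn(fit$x, x, factor(fit$y, levels = lev), k = p$k,
                       prob = TRUE)
      win <- as.integer(as.character(pr))
      wp <- attr(pr, "prob")
      sc <- matrix((1 - wp) / max(1L, length(lev) - 1L), length(win),
                   length(lev), dimnames = list(NULL, as.character(lev)))
      sc[cbind(seq_along(win), match(win, lev))] <- wp
      list(class = win, scores = sc)
    },
    RF = function(fit, x) {
      sc <- predict(fit$model, x, type = "prob")
      sc <- full_score_matrix(sc, as.character(fit$levels))
      list(class = fit$levels[max.col(sc, ties.method = "first")],
           scores = sc)
    },
    GNB = function(fit, x) {
      df <- as.data.frame(x)
      colnames(df) <- fit$cols
      sc <- predict(fit$model, df, type = "raw")
      colnames(sc) <- as.character(fit$levels)
      list(class = fit$levels[max.col(sc, ties.method = "first")],
           scores = sc)
    },
    GB = function(fit, x) {
      k <- length(fit$levels)
      pr <- predict(fit$model, xgboost::xgb.DMatrix(as.matrix(x)))
      sc <- if (k > 2L) matrix(pr, ncol = k) else cbind(1 - pr, pr)
      colnames(sc) <- as.character(fit$levels)
      list(class = fit$levels[max.col(sc, ties.method = "first")],
           scores = sc)
    },
    DT = function(fit, x) {
      df <- as.data.frame(x)
      colnames(df) <- fit$cols
      sc <- predict(fit$model, df, type = "prob")
      sc <- full_score_matrix(sc, as.character(fit$levels))
      list(class = fit$levels[max.col(sc, ties.method = "first")],
           scores = sc)
    },
    MLP = function(fit, x) {
      sc <- predict(fit$model, x)
      if (ncol(sc) == 1L) sc <- cbind(1 - sc, sc)
      colnames(sc) <- as.character(fit$levels)
      list(class = fit$levels[max.col(sc, ties.method = "first")],
           scores = sc)
    })

  structure(list(name = name, seed = seed, params = p, fit = fit_fun,
                 predict = predict_fun),
            class = "classifier_handle")
}

#' @export
print.classifier_handle <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "(no hyperparameters)"
  cat(sprintf("<classifier %s> seed %d; %s\n", x$name, x$seed, ps))
  invisible(x)
}
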