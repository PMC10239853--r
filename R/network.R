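#' Training configuration
#'
#' Canonical settings: learning rate 1e-4 (1e-3 is the documented
#' alternative), batch size 50, 300 epochs, Adam optimizer, categorical
#' cross-entropy loss. Tests and quick runs reduce `epochs`; the optimizer
#' and loss are fixed.
#'
#' @param learning_rate Adam step size (> 0, or 0 for the degenerate
#'   no-update limit used in invariance checks).
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Number of passes over the training data (>= 1).
#' @param seed Integer seed driving weight initialization, shuffling and
#'   dropout.
#' @param validation_fraction Optional fraction in (0, 1) held out (seeded)
#'   to record a validation accuracy/loss series per epoch.
#' @return Object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 50L,
                            epochs = 300L, seed = 1L,
                            validation_fraction = NULL) {
  stopifnot(learning_rate >= 0, batch_size >= 1L, epochs >= 1L)
  if (!is.null(validation_fraction)) {
    stopifnot(validation_fraction > 0, validation_fraction < 1)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = "adam",
                 loss = "categorical_crossentropy", seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "training_config")
}

.bn_eps <- 1e-5
.adam_beta1 <- 0.9
.adam_beta2 <- 0.999
.adam_eps <- 1e-8

# Fan-in-scaled uniform initializer: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
init_params <- function(arch) {
  in_shape <- c(arch$input_length, arch$input_channels)
  params <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "conv1d") {
      fan_in <- ly$kernel_size * in_shape[2L]
      lim <- sqrt(6 / fan_in)
      params[[i]] <- list(
        W = matrix(stats::runif(fan_in * ly$filters, -lim, lim),
                   fan_in, ly$filters),
        b = numeric(ly$filters))
    } else if (ly$kind == "batchnorm") {
      C <- in_shape[2L]
      params[[i]] <- list(gamma = rep(1, C), beta = numeric(C),
                          rmean = numeric(C), rvar = rep(1, C))
    } else if (ly$kind == "dense") {
      fan_in <- in_shape[1L]
      lim <- sqrt(6 / fan_in)
      params[[i]] <- list(
        W = matrix(stats::runif(fan_in * ly$units, -lim, lim),
                   fan_in, ly$units),
        b = numeric(ly$units))
    }
    in_shape <- arch$shapes[[i]]
  }
  params
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass over a (L, 1, N) batch array. Returns the output (softmax
# probabilities N x K, or the tap-layer activations if `tap` is given), a
# per-layer cache for backprop when `keep_cache`, and updated batchnorm
# running statistics when training.
net_forward <- function(arch, params, X, training = FALSE, tap = NULL,
                        keep_cache = FALSE, dropout_rng = TRUE) {
  cur <- X
  cache <- if (keep_cache) vector("list", length(arch$layers)) else NULL
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "conv1d") {
      if (keep_cache) cache[[i]] <- list(X = cur)
      cur <- cpp_conv1d_fwd(cur, params[[i]]$W, params[[i]]$b,
                            ly$kernel_size)
    } else if (ly$kind == "batchnorm") {
      p <- params[[i]]
      if (training) {
        res <- cpp_bn_fwd_train(cur, p$gamma, p$beta, .bn_eps)
        if (keep_cache) cache[[i]] <- list(X = cur, mu = res$mu, var = res$var)
        params[[i]]$rmean <- ly$momentum * p$rmean +
          (1 - ly$momentum) * as.numeric(res$mu)
        params[[i]]$rvar <- ly$momentum * p$rvar +
          (1 - ly$momentum) * as.numeric(res$var)
        cur <- res$Y
      } else {
        cur <- cpp_bn_fwd_infer(cur, p$gamma, p$beta, p$rmean, p$rvar,
                                .bn_eps)
      }
    } else if (ly$kind == "activation") {
      cur <- cpp_relu_fwd(cur)
      if (keep_cache) cache[[i]] <- list(Y = cur)
    } else if (ly$kind == "maxpool1d") {
      L_in <- dim(cur)[1L]
      res <- cpp_maxpool_fwd(cur, ly$pool_size, ly$stride)
      if (keep_cache) cache[[i]] <- list(idx = res$idx, L_in = L_in)
      cur <- res$Y
    } else if (ly$kind == "flatten") {
      d <- dim(cur)
      if (keep_cache) cache[[i]] <- list(dims = d)
      cur <- t(matrix(cur, d[1L] * d[2L], d[3L]))
    } else if (ly$kind == "dense") {
      if (keep_cache) cache[[i]] <- list(X = cur)
      z <- cur %*% params[[i]]$W
      z <- sweep(z, 2L, params[[i]]$b, "+")
      cur <- switch(ly$activation,
                    relu = pmax(z, 0),
                    softmax = softmax_rows(z),
                    linear = z)
      if (keep_cache) cache[[i]]$Y <- cur
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0 && dropout_rng) {
        keep <- 1 - ly$rate
        mask <- (matrix(stats::runif(length(cur)), nrow(cur)) < keep) / keep
        if (keep_cache) cache[[i]] <- list(mask = mask)
        cur <- cur * mask
      }
    }
    if (!is.null(tap) && i == tap) {
      return(list(out = cur, cache = cache, params = params))
    }
  }
  list(out = cur, cache = cache, params = params)
}

# Backward pass. `probs` is the softmax output, `Y1hot` the one-hot labels.
# Returns gradients in the same nesting as `params`. The cross-entropy +
# softmax head collapses to (probs - Y) / N at the logits.
net_backward <- function(arch, params, cache, probs, Y1hot) {
  grads <- vector("list", length(arch$layers))
  n <- nrow(probs)
  d <- (probs - Y1hot) / n
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    if (ly$kind == "dense") {
      # d arrives at the activation output; softmax head already folded in
      if (ly$activation == "relu") d <- d * (cache[[i]]$Y > 0)
      Xin <- cache[[i]]$X
      dW <- crossprod(Xin, d)
      if (ly$l2 > 0) dW <- dW + 2 * ly$l2 * params[[i]]$W
      grads[[i]] <- list(W = dW, b = colSums(d))
      d <- tcrossprod(d, params[[i]]$W)
    } else if (ly$kind == "dropout") {
      if (!is.null(cache[[i]])) d <- d * cache[[i]]$mask
    } else if (ly$kind == "flatten") {
      dims <- cache[[i]]$dims
      d <- array(t(d), dim = dims)
    } else if (ly$kind == "maxpool1d") {
      d <- cpp_maxpool_bwd(cache[[i]]$idx, d, cache[[i]]$L_in)
    } else if (ly$kind == "activation") {
      d <- cpp_relu_bwd(cache[[i]]$Y, d)
    } else if (ly$kind == "batchnorm") {
      res <- cpp_bn_bwd(cache[[i]]$X, params[[i]]$gamma, cache[[i]]$mu,
                        cache[[i]]$var, .bn_eps, d)
      grads[[i]] <- list(gamma = as.numeric(res$dgamma),
                         beta = as.numeric(res$dbeta))
      d <- res$dX
    } else if (ly$kind == "conv1d") {
      res <- cpp_conv1d_bwd(cache[[i]]$X, params[[i]]$W, d, ly$kernel_size)
      grads[[i]] <- list(W = res$dW, b = as.numeric(res$db))
      d <- res$dX
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    trainable <- intersect(names(p), c("W", "b", "gamma", "beta"))
    stats::setNames(lapply(trainable, function(nm) {
      list(m = p[[nm]] * 0, v = p[[nm]] * 0)
    }), trainable)
  })
}

adam_step <- function(params, grads, opt, lr, t) {
  b1 <- .adam_beta1; b2 <- .adam_beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      opt[[i]][[nm]] <- st
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + .adam_eps)
    }
  }
  list(params = params, opt = opt)
}

#' Convert a labeled dataset to a batch array
#'
#' @param dataset A [labeled_dataset()].
#' @return Numeric array of dim `(epoch_length, 1, n_epochs)`.
#' @export
as_batch_array <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  L <- epoch_length(dataset)
  array(unlist(lapply(dataset$records, function(r) r$samples)),
        dim = c(L, 1L, n_epochs(dataset)))
}

one_hot <- function(labels, k) {
  Y <- matrix(0, length(labels), k)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

l2_penalty <- function(arch, params) {
  pen <- 0
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "dense" && ly$l2 > 0) {
      pen <- pen + ly$l2 * sum(params[[i]]$W^2)
    }
  }
  pen
}

#' Train the network
#'
#' Minibatch Adam on categorical cross-entropy (plus the dense layer's L2
#' penalty), with per-channel batch normalization in training mode and
#' inverted dropout. All randomness -- weight initialization, epoch
#' shuffling, dropout masks, the optional validation split -- is drawn from
#' one RNG stream seeded by `config$seed`, so identical calls produce
#' identical histories and weights.
#'
#' @param arch A `cnn_architecture` from [build_architecture()] or
#'   [build_compact_architecture()].
#' @param dataset A [labeled_dataset()] whose epoch length equals
#'   `arch$input_length` and whose labels cover `1..arch$n_classes`.
#' @param config A [training_config()].
#' @return List with elements `network` (a `trained_cnn`: architecture,
#'   weights, feature tap index, config) and `history` (a
#'   `training_history`: per-epoch `accuracy` and `loss`, plus
#'   `val_accuracy`/`val_loss` when a validation split was held out).
#' @export
train_network <- function(arch, dataset, config = training_config()) {
  stopifnot(inherits(arch, "cnn_architecture"),
            inherits(dataset, "labeled_dataset"),
            inherits(config, "training_config"))
  if (epoch_length(dataset) != arch$input_length) {
    stop(sprintf(
      "train_network: dataset epoch length %d != architecture input %d",
      epoch_length(dataset), arch$input_length), call. = FALSE)
  }
  if (max(dataset$labels) > arch$n_classes) {
    stop("train_network: labels exceed the architecture's class count",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  X <- as_batch_array(dataset)
  Y <- one_hot(dataset$labels, arch$n_classes)
  n <- n_epochs(dataset)

  val_idx <- integer(0)
  if (!is.null(config$validation_fraction)) {
    val_idx <- sample.int(n, max(1L, round(config$validation_fraction * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  params <- init_params(arch)
  opt <- adam_init(params)
  t_step <- 0L
  hist <- list(accuracy = numeric(config$epochs),
               loss = numeric(config$epochs))
  if (length(val_idx) > 0L) {
    hist$val_accuracy <- numeric(config$epochs)
    hist$val_loss <- numeric(config$epochs)
  }

  for (ep in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      Xb <- X[, , bi, drop = FALSE]
      Yb <- Y[bi, , drop = FALSE]
      fw <- net_forward(arch, params, Xb, training = TRUE, keep_cache = TRUE)
      params <- fw$params  # running BN stats advanced
      probs <- fw$out
      ce <- -mean(log(pmax(probs[Yb == 1], 1e-12)))
      loss <- ce + l2_penalty(arch, params)
      if (!is.finite(loss)) {
        stop(sprintf("train_network: training diverged at epoch %d", ep),
             call. = FALSE)
      }
      ep_loss <- ep_loss + loss * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(probs, ties.method = "first") == dataset$labels[bi])
      grads <- net_backward(arch, params, fw$cache, probs, Yb)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, opt, config$learning_rate, t_step)
      params <- upd$params; opt <- upd$opt
    }
    hist$accuracy[ep] <- ep_correct / length(ord)
    hist$loss[ep] <- ep_loss / length(ord)
    if (length(val_idx) > 0L) {
      pv <- net_forward(arch, params, X[, , val_idx, drop = FALSE])$out
      hist$val_accuracy[ep] <-
        mean(max.col(pv, ties.method = "first") == dataset$labels[val_idx])
      hist$val_loss[ep] <-
        -mean(log(pmax(pv[one_hot(dataset$labels[val_idx],
                                  arch$n_classes) == 1], 1e-12))) +
        l2_penalty(arch, params)
    }
  }

  net <- structure(list(architecture = arch, params = params,
                        feature_tap = feature_tap_index(arch),
                        config = config),
                   class = "trained_cnn")
  history <- structure(hist, class = "training_history")
  list(network = net, history = history)
}

#' Initialize an untrained network
#'
#' Seeded weight initialization without any training; useful for forward
#' pass checks and as a fixed random feature extractor.
#'
#' @param arch A `cnn_architecture`.
#' @param seed Integer seed.
#' @return A `trained_cnn` with freshly initialized weights.
#' @export
init_network <- function(arch, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  structure(list(architecture = arch, params = init_params(arch),
                 feature_tap = feature_tap_index(arch),
                 config = NULL),
            class = "trained_cnn")
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat(sprintf("<trained_cnn '%s'> input (%d,1), %d classes, tap layer %d\n",
              x$architecture$variant, x$architecture$input_length,
              x$architecture$n_classes, x$feature_tap))
  invisible(x)
}

#' Class probabilities for a batch
#'
#' Inference-mode forward pass: dropout off, batch normalization uses the
#' moving statistics.
#'
#' @param object A `trained_cnn`.
#' @param newdata A [labeled_dataset()] or a `(L, 1, N)` array.
#' @param ... Unused.
#' @return N x K matrix of softmax probabilities.
#' @export
predict.trained_cnn <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) as_batch_array(newdata)
       else newdata
  if (dim(X)[1L] != object$architecture$input_length) {
    stop("predict.trained_cnn: input length does not match the architecture",
         call. = FALSE)
  }
  net_forward(object$architecture, object$params, X)$out
}

#' Serialize / restore a trained network
#'
#' `save_network` writes a single-file archive holding the weights next to
#' a JSON manifest (architecture summary, variant, training settings, seed)
#' so feature extraction is reproducible across sessions;
#' `network_manifest` returns that manifest as a JSON string.
#'
#' @param net A `trained_cnn`.
#' @param path Archive path.
#' @return `load_network` returns the `trained_cnn`; `save_network`
#'   returns `path` invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "trained_cnn"))
  saveRDS(list(manifest = network_manifest(net), net = net), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$net, "trained_cnn"))
  obj$net
}

#' @rdname save_network
#' @export
network_manifest <- function(net) {
  stopifnot(inherits(net, "trained_cnn"))
  arch <- net$architecture
  jsonlite::toJSON(list(
    variant = arch$variant, input_length = arch$input_length,
    n_classes = arch$n_classes, feature_tap = net$feature_tap,
    total_params = sum(arch$param_counts),
    layers = summary(arch),
    training = if (!is.null(net$config)) unclass(net$config)),
    auto_unbox = TRUE, digits = NA)
}

#' @export
print.training_history <- function(x, ...) {
  n <- length(x$accuracy)
  cat(sprintf("<training_history> %d epochs; final acc %.4f, loss %.4f\n",
              n, x$accuracy[n], x$loss[n]))
  invisible(x)
}
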