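#' Export deep feature maps from the tap layer
#'
#' Runs an inference-mode forward pass (dropout off, batch normalization on
#' moving statistics) truncated at the network's feature tap -- the last
#' max-pooling layer, just ahead of the flatten stage. For the reference
#' architecture at input length 4,097 the tap emits a 23 x 128 map per
#' epoch.
#'
#' @param net A `trained_cnn`.
#' @param dataset A [labeled_dataset()] (or `(L, 1, N)` array) whose epoch
#'   length matches the network input.
#' @return A `feature_map_batch`: numeric array of dim `(N, T, C)` with
#'   attribute `manifest` referencing the producing network.
#' @export
extract_feature_maps <- function(net, dataset) {
  stopifnot(inherits(net, "trained_cnn"))
  X <- if (inherits(dataset, "labeled_dataset")) as_batch_array(dataset)
       else dataset
  if (dim(X)[1L] != net$architecture$input_length) {
    stop(sprintf(
      "extract_feature_maps: epoch length %d does not match network input %d",
      dim(X)[1L], net$architecture$input_length), call. = FALSE)
  }
  tap_out <- net_forward(net$architecture, net$params, X,
                         tap = net$feature_tap)$out  # (T, C, N)
  maps <- aperm(tap_out, c(3L, 1L, 2L))              # (N, T, C)
  structure(maps, class = "feature_map_batch",
            manifest = sprintf("trained_cnn:%s:L%d:tap%d",
                               net$architecture$variant,
                               net$architecture$input_length,
                               net$feature_tap))
}

#' Fit one-component PCA projectors per channel
#'
#' For each of the C channels, the N x T matrix of that channel's temporal
#' columns is centered and its first principal axis (top right-singular
#' vector) stored as a unit-norm loading. The PCA sign is arbitrary, so
#' each loading is flipped to make its largest-magnitude coefficient
#' positive. Channels with (numerically) zero variance get a zero loading
#' and are flagged; their projected scores are constant 0.
#'
#' @param train_maps A `feature_map_batch` of N >= 2 training maps.
#' @param tol Relative variance threshold below which a channel is treated
#'   as zero-variance.
#' @return A `channel_projector`: list with `means` (C x T), `loadings`
#'   (C x T, unit rows), `zero_variance` (logical C), `sdev` (C, the
#'   standard deviation captured by each loading).
#' @export
fit_channel_projectors <- function(train_maps, tol = 1e-12) {
  stopifnot(inherits(train_maps, "feature_map_batch") ||
              (is.array(train_maps) && length(dim(train_maps)) == 3L))
  d <- dim(train_maps)
  n <- d[1L]; T_ <- d[2L]; C <- d[3L]
  if (n < 2L) {
    stop("fit_channel_projectors: need at least 2 training maps",
         call. = FALSE)
  }
  means <- matrix(0, C, T_)
  loadings <- matrix(0, C, T_)
  zero_var <- logical(C)
  sdev <- numeric(C)
  for (c in seq_len(C)) {
    M <- train_maps[, , c, drop = TRUE]
    if (n == 2L || T_ == 1L) M <- matrix(M, n, T_)
    mu <- colMeans(M)
    Mc <- sweep(M, 2L, mu)
    total_var <- sum(Mc^2)
    means[c, ] <- mu
    if (total_var <= tol * max(1, sum(M^2))) {
      zero_var[c] <- TRUE
      next
    }
    sv <- svd(Mc, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    j <- which.max(abs(v))
    if (v[j] < 0) v <- -v
    loadings[c, ] <- v
    sdev[c] <- sv$d[1L] / sqrt(n - 1L)
  }
  structure(list(means = means, loadings = loadings,
                 zero_variance = zero_var, sdev = sdev),
            class = "channel_projector")
}

#' @export
print.channel_projector <- function(x, ...) {
  cat(sprintf("<channel_projector> %d channels x %d timepoints, %d zero-variance\n",
              nrow(x$loadings), ncol(x$loadings), sum(x$zero_variance)))
  invisible(x)
}

#' Project feature maps to per-channel scores
#'
#' `score[n, c] = loading_c . (map[n, , c] - mean_c)`: each epoch's T x C
#' map collapses to one score per channel, giving an N x C feature matrix
#' (N x 128 for the reference architecture).
#'
#' @param maps A `feature_map_batch`.
#' @param projectors A `channel_projector` fitted on training maps with the
#'   same channel count.
#' @return N x C numeric matrix of projected scores.
#' @export
project_features <- function(maps, projectors) {
  stopifnot(inherits(projectors, "channel_projector"))
  d <- dim(maps)
  if (d[3L] != nrow(projectors$loadings)) {
    stop(sprintf("project_features: %d channels in maps vs %d projectors",
                 d[3L], nrow(projectors$loadings)), call. = FALSE)
  }
  if (d[2L] != ncol(projectors$loadings)) {
    stop("project_features: temporal length does not match the projectors",
         call. = FALSE)
  }
  n <- d[1L]; C <- d[3L]
  scores <- matrix(0, n, C)
  for (c in seq_len(C)) {
    M <- matrix(maps[, , c], n, d[2L])
    scores[, c] <- sweep(M, 2L, projectors$means[c, ]) %*%
      projectors$loadings[c, ]
  }
  colnames(scores) <- sprintf("pc%03d", seq_len(C))
  scores
}

#' Serialize projector loadings, means and scores to CSV
#'
#' @param projectors A `channel_projector`.
#' @param scores Optional N x C score matrix from [project_features()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly. Writes `loadings.csv` and `means.csv`
#'   (C x T), and `scores.csv` when given.
#' @export
write_projectors <- function(projectors, dir, scores = NULL) {
  stopifnot(inherits(projectors, "channel_projector"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(projectors$loadings, file.path(dir, "loadings.csv"),
                   row.names = FALSE)
  utils::write.csv(projectors$means, file.path(dir, "means.csv"),
                   row.names = FALSE)
  if (!is.null(scores)) {
    utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
  }
  invisible(dir)
}
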