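#' Layer specifications
#'
#' Constructors for the layer kinds the network uses. All convolution and
#' pooling layers use "valid" padding (no zero padding): a convolution of
#' kernel size k maps temporal length L to L - k + 1, and a pool of size p
#' with stride s maps L to floor((L - p) / s) + 1.
#'
#' @param filters Number of output channels of a convolution.
#' @param kernel_size Convolution window length (samples).
#' @param stride Temporal stride (convolutions here always use 1).
#' @param momentum Batch-normalization moving-average momentum.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param units Dense layer width.
#' @param activation `"relu"`, `"softmax"` or `"linear"`.
#' @param l2 L2 penalty coefficient on the dense kernel (0 = none).
#' @param rate Dropout rate in `[0, 1)`.
#' @return A `layer_spec` object.
#' @name layer_specs
NULL

new_layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layer_specs
#' @export
layer_conv1d <- function(filters, kernel_size, stride = 1L) {
  stopifnot(filters >= 1L, kernel_size >= 1L, stride >= 1L)
  new_layer("conv1d", filters = as.integer(filters),
            kernel_size = as.integer(kernel_size),
            stride = as.integer(stride), padding = "valid")
}

#' @rdname layer_specs
#' @export
layer_batchnorm <- function(momentum = 0.9) {
  stopifnot(momentum >= 0, momentum < 1)
  new_layer("batchnorm", momentum = momentum, axis = "channel")
}

#' @rdname layer_specs
#' @export
layer_activation <- function(activation = "relu") {
  new_layer("activation", activation = match.arg(activation, "relu"))
}

#' @rdname layer_specs
#' @export
layer_maxpool1d <- function(pool_size, pool_stride = pool_size) {
  stopifnot(pool_size >= 1L, pool_stride >= 1L)
  new_layer("maxpool1d", pool_size = as.integer(pool_size),
            stride = as.integer(pool_stride), padding = "valid")
}

#' @rdname layer_specs
#' @export
layer_flatten <- function() new_layer("flatten")

#' @rdname layer_specs
#' @export
layer_dense <- function(units, activation = c("relu", "softmax", "linear"),
                        l2 = 0) {
  stopifnot(units >= 1L, l2 >= 0)
  new_layer("dense", units = as.integer(units),
            activation = match.arg(activation), l2 = l2)
}

#' @rdname layer_specs
#' @export
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  new_layer("dropout", rate = rate)
}

#' Output shape of one layer
#'
#' Valid-padding shape arithmetic: convolutions shrink the temporal axis by
#' `kernel_size - 1`; pooling maps L to `floor((L - pool) / stride) + 1`;
#' batch normalization, activations and dropout are shape-preserving;
#' flatten collapses `(L, C)` to `L * C`.
#'
#' @param in_shape Integer vector `(length, channels)`, or a single integer
#'   for post-flatten layers.
#' @param layer A `layer_spec`.
#' @return The output shape in the same convention.
#' @export
layer_output_shape <- function(in_shape, layer) {
  stopifnot(inherits(layer, "layer_spec"), all(in_shape >= 1L))
  switch(layer$kind,
    conv1d = {
      L <- in_shape[1L]
      if (layer$kernel_size > L) {
        stop(sprintf("conv1d kernel %d exceeds input length %d",
                     layer$kernel_size, L), call. = FALSE)
      }
      c((L - layer$kernel_size) %/% layer$stride + 1L, layer$filters)
    },
    maxpool1d = {
      L <- in_shape[1L]
      if (layer$pool_size > L) {
        stop(sprintf("maxpool1d window %d exceeds input length %d",
                     layer$pool_size, L), call. = FALSE)
      }
      c((L - layer$pool_size) %/% layer$stride + 1L, in_shape[2L])
    },
    flatten = as.integer(prod(in_shape)),
    dense = layer$units,
    in_shape  # batchnorm / activation / dropout
  )
}

#' Trainable + moving parameter count of one layer
#'
#' Convolution: `kernel_size * in_channels * filters + filters`. Batch
#' normalization: 4 per channel (scale, shift, moving mean, moving
#' variance). Dense: `in_units * units + units`. All other layers are
#' parameter-free.
#'
#' @param layer A `layer_spec`.
#' @param in_channels Input channel count (or input width for dense layers).
#' @return Integer parameter count.
#' @export
layer_param_count <- function(layer, in_channels) {
  stopifnot(inherits(layer, "layer_spec"), in_channels >= 1L)
  switch(layer$kind,
    conv1d = layer$kernel_size * in_channels * layer$filters + layer$filters,
    batchnorm = 4L * in_channels,
    dense = in_channels * layer$units + layer$units,
    0L)
}

#' Assemble and validate an architecture
#'
#' Runs the shape chain through every layer, failing with the name of the
#' offending layer if any intermediate temporal length would drop below 1.
#'
#' @param layers List of `layer_spec` objects, in forward order.
#' @param input_length Epoch length in samples.
#' @param n_classes Number of output classes (>= 2).
#' @param variant Free-form tag describing the architecture family.
#' @return Object of class `cnn_architecture` with per-layer shapes and
#'   parameter counts precomputed.
#' @export
architecture_spec <- function(layers, input_length, n_classes,
                              variant = "custom") {
  stopifnot(input_length >= 1L, n_classes >= 2L)
  shape <- c(as.integer(input_length), 1L)
  shapes <- vector("list", length(layers))
  params <- integer(length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    in_ch <- shape[length(shape)]  # channels, or width after flatten
    out <- tryCatch(layer_output_shape(shape, ly), error = function(e) {
      stop(sprintf(
        "architecture invalid for input length %d: layer %d (%s): %s",
        input_length, i, ly$kind, conditionMessage(e)), call. = FALSE)
    })
    params[i] <- layer_param_count(ly, in_ch)
    shapes[[i]] <- out
    shape <- out
  }
  structure(list(layers = layers, input_length = as.integer(input_length),
                 input_channels = 1L, n_classes = as.integer(n_classes),
                 shapes = shapes, param_counts = params, variant = variant),
            class = "cnn_architecture")
}

#' The reference 24-layer network
#'
#' Five convolution blocks (conv -> batchnorm -> ReLU -> maxpool) with
#' filters 32/64/128/256/128, kernels 3/5/13/17/9 and pools 2/4/4/2/2, all
#' valid-padded, followed by flatten, a 64-unit ReLU dense layer with L2
#' penalty 0.03, dropout 0.4, and a softmax head. At the canonical input
#' length of 4,097 samples the last pooling layer emits a 23 x 128 feature
#' map (2,944 values), which is the tap point for deep-feature extraction.
#'
#' The architecture is only valid for inputs long enough to survive the
#' shape chain; shorter epochs (e.g. 1,024 samples) must either be
#' zero-padded (see [pad_dataset()]) or use [build_compact_architecture()].
#'
#' @param input_length Epoch length in samples.
#' @param n_classes Number of output classes.
#' @return A `cnn_architecture`.
#' @export
build_architecture <- function(input_length, n_classes) {
  filters <- c(32L, 64L, 128L, 256L, 128L)
  kernels <- c(3L, 5L, 13L, 17L, 9L)
  pools   <- c(2L, 4L, 4L, 2L, 2L)
  layers <- list()
  for (b in 1:5) {
    layers <- c(layers, list(
      layer_conv1d(filters[b], kernels[b]),
      layer_batchnorm(momentum = 0.9),
      layer_activation("relu"),
      layer_maxpool1d(pools[b])))
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(64L, "relu", l2 = 0.03),
    layer_dropout(0.4),
    layer_dense(as.integer(n_classes), "softmax")))
  architecture_spec(layers, input_length, n_classes, variant = "reference")
}

#' Compact architecture for short epochs
#'
#' Same five-block topology and filter counts as [build_architecture()],
#' with kernels shrunk to 3/5/9/9/5 so the valid-padding shape chain
#' survives epochs of about 1,000 samples (the EEG-Epilepsy geometry).
#' At 1,024 samples the tap layer emits a 3 x 128 feature map; the
#' per-channel projection still yields 128 features per epoch.
#'
#' @inheritParams build_architecture
#' @return A `cnn_architecture`.
#' @export
build_compact_architecture <- function(input_length, n_classes) {
  filters <- c(32L, 64L, 128L, 256L, 128L)
  kernels <- c(3L, 5L, 9L, 9L, 5L)
  pools   <- c(2L, 4L, 4L, 2L, 2L)
  layers <- list()
  for (b in 1:5) {
    layers <- c(layers, list(
      layer_conv1d(filters[b], kernels[b]),
      layer_batchnorm(momentum = 0.9),
      layer_activation("relu"),
      layer_maxpool1d(pools[b])))
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(64L, "relu", l2 = 0.03),
    layer_dropout(0.4),
    layer_dense(as.integer(n_classes), "softmax")))
  architecture_spec(layers, input_length, n_classes, variant = "compact")
}

#' Index of the feature tap layer
#'
#' The tap is the last max-pooling layer, i.e. the layer whose output feeds
#' the flatten stage; deep features are read there.
#'
#' @param arch A `cnn_architecture`.
#' @return Integer layer index.
#' @export
feature_tap_index <- function(arch) {
  stopifnot(inherits(arch, "cnn_architecture"))
  idx <- which(vapply(arch$layers, function(l) l$kind, "") == "maxpool1d")
  idx[length(idx)]
}

layer_display_name <- function(layer) {
  switch(layer$kind,
    conv1d = "1D Convolution", batchnorm = "BatchNorm",
    activation = "Activation", maxpool1d = "1D MaxPooling",
    flatten = "Flatten", dense = "Dense", dropout = "Dropout")
}

#' Summarize an architecture layer by layer
#'
#' @param object A `cnn_architecture`.
#' @param ... Unused.
#' @return A `data.frame` with columns `no`, `layer`, `output_shape`
#'   (string, e.g. `"(23,128)"`) and `n_params`, one row per layer.
#' @export
summary.cnn_architecture <- function(object, ...) {
  fmt <- function(s) {
    if (length(s) == 1L) as.character(s)
    else sprintf("(%s)", paste(s, collapse = ","))
  }
  data.frame(
    no = seq_along(object$layers),
    layer = vapply(object$layers, layer_display_name, ""),
    output_shape = vapply(object$shapes, fmt, ""),
    n_params = object$param_counts,
    stringsAsFactors = FALSE)
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture '%s'> input (%d,1), %d classes, %s params\n",
              x$variant, x$input_length, x$n_classes,
              format(sum(x$param_counts), big.mark = ",")))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Zero-pad every epoch of a dataset to a target length
#'
#' Symmetric zero padding (extra sample on the right when the deficit is
#' odd). The default policy for running short-epoch datasets through the
#' reference architecture, preserving its published feature geometry.
#'
#' @param dataset A [labeled_dataset()].
#' @param target_length Desired epoch length (>= current length).
#' @return A [labeled_dataset()] with padded records.
#' @export
pad_dataset <- function(dataset, target_length = 4097L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  L <- epoch_length(dataset)
  if (L > target_length) {
    stop("pad_dataset: epochs are longer than target_length", call. = FALSE)
  }
  if (L == target_length) return(dataset)
  lpad <- (target_length - L) %/% 2L
  rpad <- target_length - L - lpad
  recs <- lapply(dataset$records, function(r) {
    eeg_record(c(numeric(lpad), r$samples, numeric(rpad)), r$sampling_rate,
               r$set_id, r$dataset_id, r$source_path)
  })
  labeled_dataset(recs, dataset$labels, dataset$class_names,
                  dataset$dataset_id)
}
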