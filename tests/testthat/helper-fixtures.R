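# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Tiny binary dataset at a short epoch length for fast unit tests.
tiny_binary_dataset <- function(n = 10L, len = 64L) {
  fixture(sprintf("tiny_%d_%d", n, len), function() {
    generate_dataset(synthesis_config(
      n_per_class = n, epoch_length = len, sampling_rate = 200, seed = 11,
      class_specs = list(
        class_spec("calm", background_band = c(8, 13),
                   background_amplitude = 1, noise_sd = 0.2),
        class_spec("burst", background_band = c(8, 13),
                   background_amplitude = 1,
                   rhythmic_burst = list(freq = 4, amplitude = 5,
                                         duty = 0.8),
                   noise_sd = 0.2))))
  })
}

# A small architecture that exercises every layer kind but runs in
# milliseconds: one conv block plus the dense head.
tiny_architecture <- function(len = 64L, n_classes = 2L, dropout = 0) {
  layers <- list(
    layer_conv1d(4L, 5L),
    layer_batchnorm(momentum = 0.9),
    layer_activation("relu"),
    layer_maxpool1d(2L),
    layer_conv1d(6L, 3L),
    layer_batchnorm(momentum = 0.9),
    layer_activation("relu"),
    layer_maxpool1d(2L),
    layer_flatten(),
    layer_dense(8L, "relu", l2 = 0.01))
  if (dropout > 0) layers <- c(layers, list(layer_dropout(dropout)))
  layers <- c(layers, list(layer_dense(n_classes, "softmax")))
  architecture_spec(layers, len, n_classes, variant = "tiny")
}

# Fake per-set records mimicking the on-disk set layout, for harness and
# io tests that do not need a trained network.
synthetic_records_by_set <- function(set_ids, n_per_set = 12L, len = 64L) {
  specs <- default_class_presets()
  out <- list()
  for (i in seq_along(set_ids)) {
    spec <- specs[[(i - 1L) %% length(specs) + 1L]]
    out[[set_ids[i]]] <- lapply(seq_len(n_per_set), function(j) {
      r <- generate_epoch(spec, len, 200, rng_seed = 1000L * i + j)
      r$set_id <- set_ids[i]
      r
    })
  }
  out
}

# Fraction of periodogram power inside a frequency band -- the independent
# spectral oracle used to validate the synthetic generator.
band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x))[seq_len(n %/% 2)])^2
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  sum(spec[freq >= band[1] & freq <= band[2]]) / sum(spec)
}
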