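#' Describe one synthetic EEG class
#'
#' A class is a recipe for epoch synthesis: a band-limited background
#' oscillation, sparse biphasic transients (epileptiform "spikes") placed by
#' a Poisson process, an optional sustained rhythmic burst (the ictal
#' discharge morphology), and additive Gaussian noise.
#'
#' @param class_name Class label.
#' @param background_band Length-2 numeric, low/high edge (Hz) of the
#'   dominant background oscillation. Must satisfy `low < high < fs/2` at
#'   generation time.
#' @param background_amplitude Amplitude of the background oscillation (a.u.).
#' @param spike_rate Expected number of transients per second (>= 0).
#' @param spike_amplitude Peak amplitude of each transient (a.u.).
#' @param rhythmic_burst `NULL`, or a list with elements `freq` (Hz),
#'   `amplitude` (a.u.) and `duty` (fraction of the epoch covered by the
#'   burst, in (0, 1]).
#' @param noise_sd Standard deviation of the additive white noise (a.u.).
#' @return Object of class `class_spec`.
#' @export
class_spec <- function(class_name, background_band = c(8, 13),
                       background_amplitude = 1, spike_rate = 0,
                       spike_amplitude = 0, rhythmic_burst = NULL,
                       noise_sd = 0.2) {
  stopifnot(length(background_band) == 2L,
            background_band[1L] < background_band[2L],
            background_amplitude >= 0, spike_rate >= 0,
            spike_amplitude >= 0, noise_sd >= 0)
  if (!is.null(rhythmic_burst)) {
    stopifnot(is.list(rhythmic_burst),
              all(c("freq", "amplitude", "duty") %in% names(rhythmic_burst)),
              rhythmic_burst$freq > 0, rhythmic_burst$amplitude >= 0,
              rhythmic_burst$duty > 0, rhythmic_burst$duty <= 1)
  }
  structure(list(class_name = class_name,
                 background_band = as.numeric(background_band),
                 background_amplitude = background_amplitude,
                 spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 rhythmic_burst = rhythmic_burst, noise_sd = noise_sd),
            class = "class_spec")
}

#' Default synthetic class presets
#'
#' Three presets mimicking the qualitative morphology of the clinical
#' classes: `normal` (moderate 8-13 Hz alpha-like background), `interictal`
#' (background plus sparse large biphasic transients), and `ictal`
#' (sustained high-amplitude 3-5 Hz rhythmic discharge). Transient and
#' burst amplitudes are 25x the noise standard deviation, comfortably above
#' the 5x floor at which the classes are linearly separable from simple
#' band-power features.
#'
#' @return Named list of three [class_spec()] objects.
#' @export
default_class_presets <- function() {
  list(
    normal = class_spec("normal", background_band = c(8, 13),
                        background_amplitude = 1, noise_sd = 0.2),
    interictal = class_spec("interictal", background_band = c(8, 13),
                            background_amplitude = 1, spike_rate = 1,
                            spike_amplitude = 5, noise_sd = 0.2),
    ictal = class_spec("ictal", background_band = c(8, 13),
                       background_amplitude = 1,
                       rhythmic_burst = list(freq = 4, amplitude = 5,
                                             duty = 0.8),
                       noise_sd = 0.2)
  )
}

#' Synthesis configuration
#'
#' @param n_per_class Epochs per class (>= 1).
#' @param epoch_length Samples per epoch (>= 64). The two geometries used
#'   throughout the package are 4,097 samples at 173.61 Hz (Bonn-style) and
#'   1,024 samples at 200 Hz (EEG-Epilepsy-style).
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer base seed. Every epoch derives its own substream
#'   from `(seed, epoch counter)` so a dataset is reproducible epoch by
#'   epoch and extending it does not perturb earlier epochs.
#' @param class_specs List of [class_spec()] objects (>= 2 for
#'   classification use).
#' @return Object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_per_class = 100L, epoch_length = 4097L,
                             sampling_rate = 173.61, seed = 1L,
                             class_specs = default_class_presets()) {
  stopifnot(n_per_class >= 1L, epoch_length >= 64L, sampling_rate > 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 epoch_length = as.integer(epoch_length),
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 class_specs = class_specs),
            class = "synthesis_config")
}

# Counter-split substream: a deterministic per-epoch seed below 2^31 derived
# from the base seed and the epoch counter by an LCG-style mix.
epoch_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2L)) {
    s <- (s * 48271 + as.double(counter) * 16807 + 11) %% 2147483647
  }
  as.integer(s)
}

# Biphasic transient shape: derivative of a Gaussian, normalized to unit
# peak amplitude. Width ~70 ms, the duration of a typical epileptiform spike.
biphasic_shape <- function(fs, width_s = 0.07) {
  half <- max(3L, round(width_s * fs))
  t <- seq(-half, half)
  sigma <- half / 2.5
  w <- -t * exp(-t^2 / (2 * sigma^2))
  w / max(abs(w))
}

#' Generate one synthetic EEG epoch
#'
#' The epoch is the sum of (i) a band-limited background built from three
#' sinusoids with random frequencies inside `background_band` and random
#' phases, (ii) Poisson-placed biphasic transients, (iii) an optional
#' rhythmic burst occupying a random contiguous window of the requested
#' duty fraction, and (iv) white Gaussian noise. Deterministic given
#' `rng_seed`.
#'
#' @param spec A [class_spec()].
#' @param length Epoch length in samples.
#' @param fs Sampling rate (Hz). `background_band` and any burst frequency
#'   must lie below `fs / 2`.
#' @param rng_seed Integer seed for this epoch's RNG substream.
#' @return An [eeg_record()] with `dataset_id = "synthetic"`.
#' @export
generate_epoch <- function(spec, length, fs, rng_seed) {
  stopifnot(inherits(spec, "class_spec"), length >= 1L, fs > 0)
  if (spec$background_band[2L] >= fs / 2) {
    stop("generate_epoch: background band exceeds the Nyquist frequency",
         call. = FALSE)
  }
  if (!is.null(spec$rhythmic_burst) && spec$rhythmic_burst$freq >= fs / 2) {
    stop("generate_epoch: burst frequency exceeds the Nyquist frequency",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)

  t <- seq_len(length) / fs
  x <- numeric(length)

  if (spec$background_amplitude > 0) {
    for (i in 1:3) {
      f <- stats::runif(1, spec$background_band[1L], spec$background_band[2L])
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + (spec$background_amplitude / 3) * sin(2 * pi * f * t + ph)
    }
  }

  if (spec$spike_rate > 0 && spec$spike_amplitude > 0) {
    n_spk <- stats::rpois(1, spec$spike_rate * length / fs)
    if (n_spk > 0) {
      shape <- biphasic_shape(fs)
      half <- (length(shape) - 1L) %/% 2L
      centers <- sort(sample.int(length, min(n_spk, length)))
      for (ctr in centers) {
        pol <- sample(c(-1, 1), 1)
        lo <- max(1L, ctr - half); hi <- min(length, ctr + half)
        seg <- shape[(lo - ctr + half + 1L):(hi - ctr + half + 1L)]
        x[lo:hi] <- x[lo:hi] + pol * spec$spike_amplitude * seg
      }
    }
  }

  if (!is.null(spec$rhythmic_burst)) {
    rb <- spec$rhythmic_burst
    span <- max(1L, round(rb$duty * length))
    start <- if (span >= length) 1L else sample.int(length - span + 1L, 1)
    idx <- start:(start + span - 1L)
    ph <- stats::runif(1, 0, 2 * pi)
    env <- sin(pi * seq_along(idx) / length(idx))  # smooth on/off ramp
    x[idx] <- x[idx] + rb$amplitude * env * sin(2 * pi * rb$freq * t[idx] + ph)
  }

  if (spec$noise_sd > 0) x <- x + stats::rnorm(length, sd = spec$noise_sd)

  eeg_record(x, fs, set_id = spec$class_name, dataset_id = "synthetic",
             source_path = sprintf("synthetic:%s:seed%d", spec$class_name,
                                   rng_seed))
}

#' Generate a labeled synthetic dataset
#'
#' Emits `n_per_class` epochs for every class in `config$class_specs`,
#' labeled in spec order. Each epoch draws from its own counter-derived RNG
#' substream, so two runs with the same config are byte-identical and
#' growing `n_per_class` leaves existing epochs unchanged.
#'
#' @param config A [synthesis_config()].
#' @return A [labeled_dataset()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  if (length(config$class_specs) < 2L) {
    stop("generate_dataset: need at least 2 class specs", call. = FALSE)
  }
  records <- list()
  labels <- integer(0)
  counter <- 0L
  for (k in seq_along(config$class_specs)) {
    spec <- config$class_specs[[k]]
    for (i in seq_len(config$n_per_class)) {
      counter <- counter + 1L
      records[[counter]] <- generate_epoch(
        spec, config$epoch_length, config$sampling_rate,
        epoch_seed(config$seed, (k - 1L) * 100000L + i))
      labels[counter] <- k
    }
  }
  labeled_dataset(records, labels,
                  vapply(config$class_specs, function(s) s$class_name, ""),
                  dataset_id = "synthetic")
}

#' Write a synthetic dataset in the ASCII epoch layout
#'
#' One subdirectory per class, one file per epoch, one sample per line --
#' the same layout [load_set()] reads, so synthetic data can stand in for
#' on-disk clinical sets.
#'
#' @param dataset A [labeled_dataset()].
#' @param directory Output root directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_synthetic_ascii <- function(dataset, directory) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  counts <- integer(length(dataset$class_names))
  for (i in seq_along(dataset$records)) {
    k <- dataset$labels[i]
    counts[k] <- counts[k] + 1L
    sub <- file.path(directory, dataset$class_names[k])
    dir.create(sub, showWarnings = FALSE)
    write_ascii_epoch(dataset$records[[i]],
                      file.path(sub, sprintf("epoch%04d.txt", counts[k])))
  }
  invisible(directory)
}

#' Read / write a synthesis configuration as YAML
#'
#' @param config A [synthesis_config()].
#' @param path YAML file path.
#' @return `read_synthesis_config` returns a [synthesis_config()];
#'   `write_synthesis_config` returns `path` invisibly.
#' @export
write_synthesis_config <- function(config, path) {
  stopifnot(inherits(config, "synthesis_config"))
  lst <- unclass(config)
  lst$class_specs <- lapply(lst$class_specs, unclass)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_synthesis_config
#' @export
read_synthesis_config <- function(path) {
  lst <- yaml::read_yaml(path)
  specs <- lapply(lst$class_specs, function(s) {
    class_spec(s$class_name, unlist(s$background_band),
               s$background_amplitude, s$spike_rate, s$spike_amplitude,
               s$rhythmic_burst, s$noise_sd)
  })
  synthesis_config(lst$n_per_class, lst$epoch_length, lst$sampling_rate,
                   lst$seed, specs)
}
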