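test_that("null class spec yields an all-zero epoch; determinism holds", {
  null_spec <- class_spec("null", background_amplitude = 0, spike_rate = 0,
                          spike_amplitude = 0, noise_sd = 0)
  rec <- generate_epoch(null_spec, 256L, 200, rng_seed = 5)
  expect_identical(rec$samples, numeric(256))

  spec <- default_class_presets()$ictal
  a <- generate_epoch(spec, 512L, 200, rng_seed = 42)
  b <- generate_epoch(spec, 512L, 200, rng_seed = 42)
  expect_identical(a$samples, b$samples)
  expect_true(all(is.finite(a$samples)))

  # Nyquist validation
  bad <- class_spec("bad", background_band = c(90, 120))
  expect_error(generate_epoch(bad, 256L, 200, 1), "Nyquist")
})

test_that("ictal-like epochs concentrate power in the 3-5 Hz burst band", {
  presets <- default_class_presets()
  for (seed in c(3, 17, 91)) {
    ict <- generate_epoch(presets$ictal, 1024L, 200, rng_seed = seed)
    nor <- generate_epoch(presets$normal, 1024L, 200, rng_seed = seed)
    expect_gt(band_power_fraction(ict$samples, 200, c(3, 5)),
              band_power_fraction(nor$samples, 200, c(3, 5)))
  }
})

test_that("generate_dataset is reproducible and extension-stable", {
  cfg <- synthesis_config(n_per_class = 5L, epoch_length = 128L,
                          sampling_rate = 200, seed = 9)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(n_epochs(ds1), 15L)
  expect_identical(as.integer(table(ds1$labels)), c(5L, 5L, 5L))
  expect_identical(ds1$class_names, c("normal", "interictal", "ictal"))
  expect_identical(lapply(ds1$records, `[[`, "samples"),
                   lapply(ds2$records, `[[`, "samples"))

  # counter-split substreams: growing the dataset keeps earlier epochs
  cfg_big <- synthesis_config(n_per_class = 8L, epoch_length = 128L,
                              sampling_rate = 200, seed = 9)
  ds3 <- generate_dataset(cfg_big)
  per_class_small <- split(seq_len(15), ds1$labels)
  per_class_big <- split(seq_len(24), ds3$labels)
  for (k in 1:3) {
    for (j in 1:5) {
      expect_identical(
        ds1$records[[per_class_small[[k]][j]]]$samples,
        ds3$records[[per_class_big[[k]][j]]]$samples)
    }
  }
})

test_that("background-only epochs have no DC bias as n grows", {
  spec <- class_spec("bg", background_band = c(8, 13),
                     background_amplitude = 1, noise_sd = 0.3)
  means <- vapply(1:60, function(i) {
    mean(generate_epoch(spec, 512L, 200, rng_seed = i)$samples)
  }, 1)
  # each epoch mean is already small; the grand mean shrinks further
  expect_lt(abs(mean(means)), 0.02)
  expect_lt(abs(mean(means)), sd(means))
})

test_that("separable presets support >= 90% linear CV accuracy on band power;
           identical specs are indistinguishable from chance", {
  fs <- 200
  cfg <- synthesis_config(n_per_class = 40L, epoch_length = 512L,
                          sampling_rate = fs, seed = 21,
                          class_specs = default_class_presets()[c("normal",
                                                                  "ictal")])
  ds <- generate_dataset(cfg)
  # simple band-power features: fraction of power in delta/theta and alpha
  feats <- t(vapply(ds$records, function(r) {
    c(band_power_fraction(r$samples, fs, c(3, 5)),
      band_power_fraction(r$samples, fs, c(8, 13)))
  }, numeric(2)))
  folds <- stratified_folds(ds$labels, k = 5L, seed = 2)
  correct <- 0L
  for (f in 1:5) {
    te <- folds$fold == f
    fit <- suppressWarnings(stats::glm(
      y ~ ., family = binomial(),
      data = data.frame(y = ds$labels[!te] - 1L, feats[!te, ])))
    pred <- stats::predict(fit, newdata = data.frame(feats[te, ]),
                           type = "response") > 0.5
    correct <- correct + sum((ds$labels[te] - 1L) == pred)
  }
  expect_gte(correct / n_epochs(ds), 0.90)

  # identical class specs: same generator for both labels, accuracy must sit
  # inside the 99% binomial band around 0.5
  cfg0 <- synthesis_config(n_per_class = 40L, epoch_length = 512L,
                           sampling_rate = fs, seed = 22,
                           class_specs = list(
                             class_spec("a"), class_spec("b")))
  ds0 <- generate_dataset(cfg0)
  feats0 <- t(vapply(ds0$records, function(r) {
    c(band_power_fraction(r$samples, fs, c(3, 5)),
      band_power_fraction(r$samples, fs, c(8, 13)))
  }, numeric(2)))
  folds0 <- stratified_folds(ds0$labels, k = 5L, seed = 2)
  correct0 <- 0L
  for (f in 1:5) {
    te <- folds0$fold == f
    fit <- suppressWarnings(stats::glm(
      y ~ ., family = binomial(),
      data = data.frame(y = ds0$labels[!te] - 1L, feats0[!te, ])))
    pred <- stats::predict(fit, newdata = data.frame(feats0[te, ]),
                           type = "response") > 0.5
    correct0 <- correct0 + sum((ds0$labels[te] - 1L) == pred)
  }
  band <- qbinom(c(0.005, 0.995), n_epochs(ds0), 0.5) / n_epochs(ds0)
  acc0 <- correct0 / n_epochs(ds0)
  expect_gte(acc0, band[1])
  expect_lte(acc0, band[2])
})

test_that("synthesis configs round-trip through YAML and ASCII layout", {
  dir <- withr::local_tempdir()
  cfg <- synthesis_config(n_per_class = 3L, epoch_length = 64L,
                          sampling_rate = 200, seed = 4)
  yml <- file.path(dir, "synth.yaml")
  write_synthesis_config(cfg, yml)
  cfg2 <- read_synthesis_config(yml)
  expect_identical(generate_dataset(cfg)$records[[1]]$samples,
                   generate_dataset(cfg2)$records[[1]]$samples)

  ds <- generate_dataset(cfg)
  out <- file.path(dir, "ascii")
  write_synthetic_ascii(ds, out)
  back <- load_set(file.path(out, "normal"), "normal",
                   sampling_rate = 200)
  expect_length(back, 3L)
  expect_equal(back[[1]]$samples, ds$records[[1]]$samples)
})
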