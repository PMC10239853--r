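---
title: "Deep EEG features with shallow classifiers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep EEG features with shallow classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(deepeeg)
```

# The problem and the pipeline

Epileptic seizure detection from single-channel EEG is treated here as
epoch classification: each fixed-length amplitude vector is labeled
normal, interictal (between seizures) or ictal (seizure). The package
implements a three-stage pipeline:

1. a 1D convolutional network trained end-to-end on raw epochs,
2. compression of its penultimate pooled feature map by per-channel
   principal component projections, and
3. shallow classifiers evaluated under stratified k-fold cross-validation.

The two supported data geometries mirror the public benchmarks in this
area: 4,097 samples at 173.61 Hz in five sets A–E of 100 epochs (surface
recordings of healthy volunteers with eyes open/closed, interictal and
ictal intracranial recordings), and 1,024 samples at 200 Hz in three sets
F–H of 50 epochs (ictal / interictal / preictal scalp recordings).
`builtin_cases()` enumerates the 17 standard case definitions over these
sets — binary screens such as A vs. E or the imbalanced ABCD vs. E, the
ternary A–C–E, AB–CD–E and F–G–H problems, and the full five-class
A–B–C–D–E separation.

# The network

`build_architecture(input_length, n_classes)` constructs the fixed
24-layer specification: five blocks of

    conv1d(filters, kernel, stride 1, valid) -> batchnorm -> ReLU ->
    maxpool1d(pool, stride = pool, valid)

with filters 32/64/128/256/128, kernels 3/5/13/17/9 and pools 2/4/4/2/2,
followed by `flatten`, `dense(64, ReLU, L2 = 0.03)`, `dropout(0.4)` and a
softmax head. All convolutions and pools are valid-padded, so temporal
length shrinks deterministically: a convolution maps L to L − k + 1 and a
pool maps L to floor((L − p)/s) + 1. At input length 4,097 the chain ends
in a 23 × 128 map ahead of the flatten (2,944 values); the full summary,
including parameter counts (conv: k·C_in·F + F; batchnorm: 4 per channel,
counting scale, shift and both moving statistics; dense: in·out + out),
totals 1,160,645 parameters and is printed by `summary()`.

Batch normalization operates per channel over all temporal positions and
batch members, with momentum 0.9 on the moving statistics and a variance
floor eps = 1e-5. Training uses Adam (beta1 = 0.9, beta2 = 0.999,
eps = 1e-8) on categorical cross-entropy plus the dense layer's L2
penalty (`l2 * sum(W^2)`, applied to the first dense kernel only, as the
layer table specifies). Dropout is the inverted variant, active only
during training. Weight initialization is fan-in-scaled uniform,
U(−sqrt(6/fan_in), +sqrt(6/fan_in)); the protocol this package follows
does not pin down the initializer family, and any documented seeded choice
fulfils the determinism contract — identical seeds reproduce identical
weights, shuffles, dropout masks and histories bit for bit.

Two learning rates are documented for this architecture, 1e-4 and 1e-3;
the canonical settings triple (learning rate, batch size, epochs) =
(1e-4, 50, 300) is the default and 1e-3 remains available through
`training_config()`. The forward/backward passes are implemented in the
package itself (RcppArmadillo kernels for convolution via im2col + GEMM,
pooling with argmax bookkeeping, and batch normalization), which keeps
the training loop fully seeded and self-contained; correctness is pinned
by finite-difference gradient checks and nested-loop convolution oracles
in the test suite.

## Short epochs

The reference shape chain collapses below one temporal step for inputs
much shorter than ~1,300 samples: at 1,024 samples the fourth-block
output (length 6) cannot feed the 9-wide fifth-block kernel, so
`build_architecture(1024, k)` refuses with an error naming the offending
layer. Two policies are provided for short-epoch datasets
(`pipeline_config(short_epoch_policy = ...)`):

* `"pad"` (default): symmetric zero-padding to 4,097 samples, preserving
  the published 23 × 128 feature geometry exactly;
* `"compact"`: `build_compact_architecture()`, the same five-block
  topology and filter progression with kernels shrunk to 3/5/9/9/5, valid
  at the native 1,024-sample length (tap map 3 × 128, still 128 projected
  features).

Padding keeps the printed feature dimensions exact at roughly 4× the
compute; the compact variant is the economical choice for experiments
whose point is the pipeline rather than the published geometry.

# Deep features and per-channel PCA

`extract_feature_maps()` runs an inference-mode forward pass (dropout
off, batch normalization on moving statistics) truncated at the last
pooling layer. The T × C map of each epoch is then compressed channel by
channel: `fit_channel_projectors()` centers the N × T matrix of channel c
across the training epochs and stores its first principal axis, and
`project_features()` maps each epoch to the 128 scores
`loading_c · (map_c − mean_c)`. This per-channel reading — reduce each
23 × 1 channel column to a single score — is the only interpretation
under which "reduce a 23 × 1 vector to 1 × 1 by PCA" is well defined;
one component is kept per channel.

Numerical conventions: loadings are unit-norm; the PCA sign is arbitrary,
so each loading is flipped to make its largest-magnitude coefficient
positive (reproducibility requires some fixed rule); channels with
numerically zero variance get a zero loading and an explicit flag, so
their scores are constant 0 and degenerate inputs still flow through the
classifiers rather than erroring.

Because the projectors are data-dependent, their fitting scope matters
for leakage. The default (`pca_scope = "fold"`) refits them inside every
training fold. A `"full"` scope (fit once on all records) exists for
replication of protocols that fit PCA globally; it is only meaningful
together with the shared-network mode below.

# The experimental harness

`stratified_folds()` shuffles each class (seeded) and deals records
round-robin into k = 10 folds, so per-class counts differ by at most one
and the 400-vs-100 screening geometry yields folds of exactly 40 + 10.
The fold seed is independent of the classifier seed, so all classifiers
see identical folds (paired comparisons).

`run_case()` supports two training scopes, because protocols in this
literature are often ambiguous about whether the feature network is
retrained per fold or trained once per dataset and reused:

* `dnn_scope = "fold"` (strict, default): the network and the projectors
  are refitted inside every training fold; no test record influences any
  fitted component. Per-fold fingerprints of the projector-fitting inputs
  are stored and asserted in tests.
* `dnn_scope = "dataset"` ("paper mode"): one network is trained on the
  full dataset and its features are reused across folds. Cheaper and
  matching one reading of the protocol, but the extractor has seen the
  test epochs' inputs; chance-level controls are only meaningful in
  strict mode.

Seven shallow classifiers run behind one fit/predict surface
(`make_classifier()`): SVC (`e1071::svm`, radial, cost 1, probability
outputs), KNN (`class::knn`, k = 5), RF (`randomForest`, 300 trees), GNB
(`e1071::naiveBayes` with a small variance floor — zero within-class
variances from dead tap channels would otherwise produce NaN posteriors),
GB (`xgboost`, 100 rounds, depth 3, eta 0.3, single-thread), DT
(`rpart`, standard CART settings) and MLP (`nnet`, 16 hidden units,
decay 1e-4, 200 iterations). No hyperparameter search is performed and
no tuned settings are assumed; these library defaults are frozen here and
echoed in run logs.

Metrics are computed per fold and aggregated two ways: pooled confusion
counts (micro; reported by default, since per-case benchmark tables in
this literature print single values) and fold-averaged metrics. For
K ≥ 3 classes the report combines overall accuracy (trace/total) with
macro one-vs-rest averages of the remaining six metrics; multi-class
specificity/NPV have no universal definition, so the macro one-vs-rest
choice is a documented package convention, not an attribution. Zero-denominator
metrics are flagged undefined and excluded from fold averages — silent
zeros would corrupt them. ROC curves sweep thresholds over unique scores
(ties grouped), AUC is the trapezoid area and equals the Mann–Whitney
concordance probability, verified against a brute-force pairwise oracle
and against pROC.

# The synthetic generator

`generate_dataset()` emulates the qualitative morphology of the three
clinical classes: a band-limited background (three random sinusoids in
8–13 Hz by default), Poisson-placed biphasic transients (derivative-of-
Gaussian, ~70 ms wide) for the interictal preset, and a sustained
high-amplitude 3–5 Hz rhythmic burst (80% duty, smooth on/off envelope)
for the ictal preset, plus white Gaussian noise. Default transient/burst
amplitudes are 25× the noise SD — far above the 5× floor at which simple
band-power features already separate the classes — so end-to-end tests
probe the pipeline's bookkeeping and leakage behaviour, not borderline
detectability. Each epoch draws from a counter-derived RNG substream, so
datasets are reproducible epoch-by-epoch and extending a dataset never
perturbs existing epochs.

What the generator deliberately does **not** emulate: 1/f background
spectra, channel correlation or montage structure, artifacts, amplifier
nonlinearities, patient-to-patient variability. Passing tests on this
data demonstrates that the implementation is correct and leakage-free; it
does not demonstrate clinical performance. Replicating the published
accuracies requires downloading the Bonn and EEG-Epilepsy recordings and
pointing `load_set()` / `run_all_cases()` at them with
`training_config(epochs = 300)`.

# Problem sizes used by the tests and the acceptance script

The end-to-end checks run the strict 10-fold pipeline twice (separable
and label-permuted) on 100 epochs per class at the 1,024-sample compact
geometry with 10 training epochs per fold. These sizes are the package's
choice of a benchmark that a single CPU core completes in a few minutes:
retraining the reference 4,097-sample network inside every fold would
take hours without changing what the checks demonstrate, since the
architecture conformance and 23 × 128 feature geometry are verified
separately by direct forward passes at 4,097 samples. With the default
presets, 10 epochs of feature training are ample — the projected deep
features are linearly separable essentially from initialization — and the
label-permuted control must land inside the 99% binomial band around
chance, which only a leakage-free protocol guarantees.

# Known limitations

* Epoch-level cross-validation follows the published protocol; records
  from one subject can appear in both training and test folds, so
  reported numbers are not subject-level generalization estimates.
* The compact architecture is a package-defined adaptation; published
  feature dimensions apply to the 4,097-sample reference geometry only.
* Class imbalance (e.g. 400 vs 100) is trained unweighted, matching the
  apparent protocol; no class weights are exposed.
* AUC is reported without confidence intervals.
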