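---
title: "Methods: GMM-UBM cry-pathology detection in crydx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GMM-UBM cry-pathology detection in crydx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crydx detects newborn health conditions from cry acoustics with a
verification-style architecture borrowed from speaker recognition: a
universal background model (UBM) captures what cries sound like in general,
a class model adapted from the UBM captures what the hypothesized class
sounds like, and each recording is scored by the log-likelihood ratio
between the two. This vignette records the model, every default, and the
numerical choices the package makes, so that results are interpretable
without reading the source.

## Acoustic front end

Recordings are mono waveforms; stereo input is averaged (`to_mono()`).
Labeled segments of two voiced cry types are analyzed separately:
expiration (`EXP`, the main cry sound) and voiced inspiration (`INSV`).
Segments are split into ~3-second *cry units* (`split_cry_units()`); a
trailing shorter remainder is kept and flagged partial.

Per unit, `extract_features()` computes:

1. **Pre-emphasis** `y[n] = x[n] - 0.97 x[n-1]` (first sample passed
   through), a standard first-order high-pass that flattens the spectral
   tilt of voiced sounds.
2. **Framing**: 10 ms frames with 30 % overlap (at 44.1 kHz: frame length
   441 samples, hop 309, so 1 s of audio yields 142 frames and a full 3-s
   unit 427), each multiplied by a Hamming window.
3. **Mel filterbank**: 24 triangular filters with unit peaks, equally
   spaced on the mel scale between 0 and 4 kHz — newborn cry energy is
   concentrated well below 4 kHz, which `cumulative_power_fraction()` lets
   you verify on your own data.
4. **Cepstra**: 12 coefficients from the literal cosine transform
   `C_i = sum_k S_k cos(i (k - 1/2) pi / K)` of the log filterbank
   energies (no orthonormalization scaling), plus the log frame energy of
   the windowed frame (floored at 1e-10).
5. **Dynamics**: delta and acceleration coefficients by the standard
   regression formula over a +/-2-frame window with edge replication,
   giving the 39-dimensional vector `(c1..c12, e, d1..d13, a1..a13)`.

Waveform gain only shifts the energy column (by `2 log g`); the cepstra
are gain-invariant. This is tested.

## Models and adaptation

All mixtures are diagonal-covariance GMMs (`gmm_params()`), with the
simplex and positive-variance constraints validated at construction and
preserved by every operation.

The **UBM** is trained per cry type with native EM (`train_gmm_em()`;
k-means++ seeding, short Lloyd refinement, variance floor at 1e-3 of the
global per-dimension variance, empty components re-seeded at the
lowest-likelihood frame). Training frames are pooled *health-independently*
(`pool_balanced()`): the sick subclasses contribute equally to a pooled
sick total matched to the healthy total, so neither side of the detector
dominates the background. The default UBM size in
`experiment_config()` is `ubm_K = 16`, chosen for the synthetic benchmark
scale; clinical-scale corpora would support larger mixtures and the value
is an ordinary configuration knob.

Class models come from the UBM by one of four adaptation methods
(`adapt_gmm()`):

1. **Mean-only MAP** (`adapt_map()`): classic relevance-factor update
   `mu_i <- alpha_i E_i + (1 - alpha_i) mu_i`, `alpha_i = n_i / (n_i + r)`,
   `r = 16` by default. Weights and variances stay at the UBM's values.
2. **Boosted mixture learning, means and variances** (`adapt_bml()`): a
   greedy per-component refinement. For component k, frame t gets sample
   weight `w_t = f_k(x_t) / F(x_t)` (component density over mixture
   density), normalized to responsibilities `gamma_t`; the component's
   mean and variance are re-estimated from the weighted frames and its
   weight moves to the mean posterior responsibility, with the remaining
   weights rescaled to keep the simplex. Components are visited in order
   of decreasing effective frame count, 2 sweeps of 3 fixed-point
   iterations by default. An alternative, literal self-multiplying weight
   update is available behind `literal_weight_update = TRUE` for
   comparison; the default posterior-mean reading is the one with a fixed
   point at the EM stationary condition.
3. **Coupled** (`adapt_coupled()`): BML estimates blended with the UBM
   through a single per-component coefficient `alpha_i = n_i / (n_i + r)`
   (counts under the UBM), with variances combined by second-moment
   matching so the blend is a proper moment interpolation.
4. **BML, means only**: method 2 with weight and variance updates
   disabled.

`adapt_bml()` caches the frame-by-component log-likelihood matrix and
refreshes only the refined component's column (weight renormalization is a
constant log-shift of the other columns), which is algebraically identical
to the naive recomputation (tested to 1e-10) and an order of magnitude
faster at realistic sizes.

## Scoring and normalization

A cry unit X is scored `Lambda(X) = avg_loglik(X | hyp) - avg_loglik(X |
alt)`, both terms averaged over frames (nats per frame) so short and long
units are comparable. The alternative is the UBM, or a set of B background
models combined as `logsumexp_b(avg_loglik_b) - log B`
(`alternative = "background_set"` uses the adapted non-target class
models). File scores are unweighted means of unit scores; a file with no
unit of the requested cry type gets `NA`, never an implicit zero.

Scores of each detector are **HNORM-normalized**: the mean and population
standard deviation of scores that *adapt-split* non-target files produce
on the detector map the imposter distribution to mean 0, sd 1. Test data
never enters the normalization.

## Evaluation

`det_points()` sweeps the threshold over all observed scores (plus
sentinels) with the convention *accept when score >= threshold*;
`eer()` interpolates the FAR = FRR crossing linearly; `roc_auc()` is the
rank-based Mann-Whitney statistic (equal to trapezoidal ROC integration).
The **operating point** minimizes the expected decision cost
`P(+) C_FN FRR + P(-) C_FP FAR` directly over thresholds. The point is
conventionally described by the ROC slope `S = (C_FP - C_TN) / (C_FN -
C_TP) * P(+)/P(-)` it attains, but an empirical ROC is a step function
whose local slopes are 0 or infinity, so direct cost minimization is the
numerically exact formulation of the same definition; with the default
symmetric costs (errors cost 0.5, correct decisions 0) and equal priors,
S = 1 and the optimum sits near the EER. Cross-validated error rates get
Wald intervals (80 % by default).

Test files can be filtered by available material: dataset A (any), B (at
least one full 3-s unit), C (at least three full units). Filter C
routinely empties the inspiration expert — inspirations are short — in
which case that expert reports `NA` rather than failing.

## Fusion

The two experts' HNORM scores form 2-D vectors (`build_score_vectors()`,
inner join on file id). `evaluate_fusion()` runs repeated stratified
K-fold cross-validation (defaults tied to K: 400/200/100 rounds for
K = 3/5/10), randomly oversampling the minority class *inside each
training fold only*, standardizing by training-fold statistics, and
training each classifier in the bank: an MLP (one hidden layer of 10 tanh
units, softmax output), a hand-rolled PNN (Gaussian kernels, spread 0.1 in
standardized units), and five SVMs (linear, quadratic, cubic, RBF, and
sigmoid `tanh(<x,x'> - 1)`).

## The synthetic benchmark

No clinical cry corpus can be shipped, so `make_corpus()` generates one:

* **Feature mode** samples 39-dimensional frames directly from per-class
  GMMs. Class models are a common base mixture whose component means are
  shifted by `separation` (default 1.5) per-dimension standard deviations
  along seeded random unit directions — `separation = 0` makes the classes
  identical and the knob increases difficulty monotonically (tested).
* **Audio mode** synthesizes WAV files (glottal pulse train at ~450 Hz
  with jitter/shimmer, formant resonators, aspiration noise) with label
  files, exercising the full I/O and DSP path.

Two structural choices matter for interpretation:

* **Between-infant variability** (`infant_sd`, default 0.75): every infant
  gets a persistent random mean offset. Splits are infant-disjoint, so
  the detector is always evaluated on unseen infants; without this term
  a synthetic benchmark degenerates into a re-identification task in
  which averaging enough unit scores solves everything and mean-only MAP
  is unbeatable by construction. With it, the benchmark measures
  generalization across infants, and the BML-family methods' variance and
  weight updates earn their keep: on the default benchmark methods 2 and
  3 beat method 1 in AUC on both cry types.
* **Recording noise** (`noise_level`, default 0.25): additive white
  feature noise emulating ward recording conditions.

Default sizes (12 UBM + 12 adaptation + 20 test infants per class, 2
recordings each, expirations 2–12 s, inspirations 0.5–5 s present in 85 %
of recordings) are desk-scale choices that keep a full four-method
experiment around a minute on one CPU while leaving all error rates off
the floor and ceiling. They are study conditions: results quoted in the
README use these defaults unchanged.

## Limitations

* The synthetic generator makes no claim of clinical realism; it is a
  controlled test bed for the machinery, with difficulty knobs whose
  effect directions are verified, not calibrated against hospital data.
* Diagonal covariances throughout; full-covariance mixtures are out of
  scope.
* The PNN stores its training set (true to the architecture), so it is
  memory-bound on large fusion sets.
* `read_wav()` supports PCM 16/24/32-bit and 32-bit float RIFF;
  compressed formats are out of scope.

## Reproducing the benchmark numbers

```{r, eval = FALSE}
library(crydx)
corpus <- make_corpus(synthetic_corpus_spec(seed = 1L), "feature")
report <- run_detector_experiment(corpus, experiment_config(
  method = 2L, ubm_K = 16L, plan = cv_plan(5L, rounds = 10L), seed = 2L))
print(report)
```

Every stochastic step (corpus generation, EM initialization, fold
assignment, oversampling, classifier initialization) is seeded from the
arguments shown, so runs are bit-reproducible.
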