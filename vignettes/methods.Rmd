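---
title: "Methods: image + weight sex classification of silkworm pupae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image + weight sex classification of silkworm pupae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In silkworm (*Bombyx mori*) seed production, breeders must know the sex of
each pupa before mating. The traditional approach cuts the cocoon open for
visual inspection, which damages the cocoon, stresses the pupa and costs
skilled labour. `pupasex` implements a non-destructive alternative: classify
sex from a photograph of the *intact* cocoon together with the cocoon
weight. Neither signal suffices alone — male and female cocoons with the
pupa inside have strongly overlapping weight distributions, and the visual
differences are subtle shape/texture cues rather than anything a single
pixel statistic can capture — but their combination, passed through the
feature pipeline below, separates the sexes well.

## Pipeline overview

1. **Preprocess** — grayscale (ITU-R BT.601 luma), bilinear resize to the
   canonical 128 × 64 (rows × columns) HOG window.
2. **HOG descriptor, FFT-accelerated** — 8 × 8-pixel cells, 9 unsigned
   orientation bins, 2 × 2-cell blocks at 1-cell stride, L2 block
   normalization: (16 − 1) × (8 − 1) = 105 blocks × 36 = **3780 features**.
3. **Block-wise Fisher LDA** — one discriminant coordinate per 36-feature
   block: 3780 → **105 features**.
4. **Weight fusion** — append the standardized cocoon weight: → **106
   features**.
5. **Feature selection** — recursive elimination ranked by mutual
   information gain, tracking stratified-CV performance along the path.
6. **Classification** — seven classifier families behind one interface;
   stratified 10-fold cross-validation; accuracy, precision, recall, F1 and
   rank-statistic AUC.
7. **Hyperparameter optimization** of the boosted-tree model by grid
   search, a classical genetic algorithm, and the teaching-learning-based
   population-selection genetic algorithm (TLBPSGA).

## Accelerated HOG

Gradients use the 1-D central-difference kernel $[-1, 0, 1]$ along rows and
columns with replicate border padding; magnitude is the Euclidean norm
$\sqrt{G_x^2 + G_y^2}$ and orientation $\arctan(G_y/G_x)$ folded to
$[0°, 180°)$. Each pixel is assigned **hard** to one of nine 20° bins — a
deliberate divergence from the Dalal–Triggs soft bilinear vote, because the
acceleration scheme is defined in terms of bin masks and filters.

Cell aggregation is where the FFT enters. For bin $k$, mask the magnitude
image to the pixels of that bin, then convolve with an 8 × 8 all-ones
summation filter:

$$c(x,y) = \mathcal{F}^{-1}\{\mathcal{F}\{g\}\cdot\mathcal{F}\{f_k\}\}$$

computed as a zero-padded *linear* convolution (padded to FFT-friendly
sizes with `stats::nextn`; circular wrap-around would corrupt border
cells). Sampling the full convolution at the cell anchor points
$(8i, 8j)$ yields exactly each cell's bin-$k$ histogram entry. Blocks of
2 × 2 cells are normalized by $v / \sqrt{\lVert v\rVert^2 + \varepsilon^2}$
with $\varepsilon = 10^{-10}$, so an all-zero block maps to zeros rather
than NaN, and concatenated row-major.

A direct spatial-domain accumulation path (`hog_features(method =
"reference")`) implements the identical contract and is used as the
numerical oracle: the two paths agree to better than $10^{-6}$ per element
(in practice ~$10^{-16}$). Relative speed of the two paths depends on
hardware, image size and the host language's loop cost, so it is never
asserted in tests; correctness equivalence is.

The descriptor is invariant to adding a constant to all pixels (gradients
remove DC), which the tests assert.

## Block-wise Fisher compression

Each contiguous 36-feature block gets its own one-dimensional Fisher
discriminant. With within-class scatter $S_W$ (sum of centered
cross-products per class) and between-class scatter $S_B$ (count-weighted
dispersion of class means about the grand mean, so that $S_W + S_B$ equals
total scatter), the projection is

$$w_b \propto (S_W + \lambda I)^{-1}(\mu_{male} - \mu_{female}), \qquad
\lambda = 10^{-6}\,\mathrm{tr}(S_W)/36 .$$

The ridge matters: gradient histograms inside a block are strongly
correlated and $S_W$ is frequently near-singular, especially inside CV
training folds. Binary labels admit at most one discriminant direction, so
"one component per block" is not a truncation choice. Two conventions make
refits comparable: $w_b$ has unit norm, and its sign is fixed so the male
class projects at least as high as the female class. A block that is
identically constant falls back to the first canonical basis vector with a
warning.

The weight feature is standardized ($z = (w - \bar w)/s$, statistics from
the **training split only**) before concatenation. Raw grams next to
unit-scale discriminant coordinates would dominate distance-based
classifiers (KNN, RBF-SVM), so plain concatenation of the raw value was
rejected.

All trainable stages — block LDA, weight statistics, the classifier — are
fitted inside each CV training fold (`pipeline_cv()`); reported metrics are
leakage-free. Fitting the compressor once on the full data before CV is a
common shortcut that inflates accuracy; the package does not do it.

## Mutual-information RFE

Feature importance is the information gain
$IG(X_i; Y) = H(X_i) - H(X_i \mid Y)$ in bits, with continuous features
discretized into 10 equal-frequency (quantile) bins. Equal-frequency
binning was chosen over equal-width because discriminant outputs are
heavy-tailed, and it makes the estimator exactly invariant under strictly
monotone transformations of the feature (a tested property). With a binary
label the gain is bounded by 1 bit. The $0\log 0 = 0$ convention applies
and tiny negative floating-point residue is clipped to zero.

RFE removes **one** feature per iteration — the lowest-ranked, ties broken
toward the higher index for determinism — and re-ranks the survivors each
iteration rather than using a one-shot static ranking. The path runs to a
single feature; the selected subset is the accuracy argmax over the whole
path (which includes the full set), ties resolved toward the smaller
subset. Importance is model-agnostic (the same MI ranking for every
classifier family), which differs from classic model-coefficient RFE; it
keeps the ranking comparable across families.

## Classifiers and metrics

The seven families (SVM, KNN, naive Bayes, decision tree, random forest,
extreme gradient boosting, AdaBoost) are standard algorithms, delegated to
`e1071`, `class`, `rpart`, `randomForest` and `xgboost` behind a uniform
`fit`/`predict`/`predict_score` wrapper with explicit seeding. AdaBoost is
the one exception: discrete AdaBoost over depth-1 `rpart` stumps is
implemented in-package (weak-learner weight
$\alpha_m = \tfrac12\log\frac{1-\epsilon_m}{\epsilon_m}$, logistic score on
the weighted margin).

Male is the positive class throughout — an arbitrary but fixed convention.
Metrics: accuracy, precision, recall, F1 from the pooled and per-fold
confusion matrices (zero-denominator cases reported as 0 and flagged), and
AUC from the **pooled** out-of-fold scores by the Mann–Whitney rank
statistic with midranks (constant scores give exactly 0.5). Reported
accuracy/precision/recall/F1 are fold means; pooling versus averaging for
AUC was an open choice and pooling was preferred because per-fold AUCs at
small fold sizes are noisy.

Stratified folds are dealt round-robin within each shuffled class, so every
fold's class counts are within one of exact proportion and every specimen
is tested exactly once.

## Hyperparameter optimization

Seven boosted-tree dimensions are searched: learning rate (log-uniform,
[0.01, 0.3]), number of trees [50, 500], maximum depth [3, 10], minimum
child weight [1, 10], gamma [0, 5], subsample [0.5, 1] and column sample
by tree [0.5, 1] — standard tuning ranges, all configurable. Optimizers
work on chromosomes of 7 genes normalized to $[0,1]$ (so crossover,
mutation and the teaching-learning arithmetic are scale-free); integers
round half-up on decode. The fitness is mean stratified-CV accuracy of the
decoded model, memoized per decoded point.

The crossover probability follows a linear schedule
$R(g) = R_{\min} + (R_{\max} - R_{\min})\,g/G$ (defaults 0.6 → 0.95):
low early to preserve good schemata in a diverse population, higher as
individuals converge. A linear form is the simplest monotone schedule
consistent with that behaviour; the exact functional form was an open
design choice.

**Classical GA**: fitness-proportional selection, single-point crossover at
$R(g)$, per-gene uniform mutation (resample from $U[0,1]$, rate 0.1),
elitism 1.

**TLBPSGA** replaces random population maintenance with teaching-learning
refinement. The initial population (100 by default) is refined to half its
size: in the *teaching phase* every learner moves by
$x' = x + r\,(x_{teacher} - T_F\,\bar{x})$ with per-gene $r \sim U(0,1)$
and teaching factor $T_F = \mathrm{round}(1 + U(0,1)) \in \{1,2\}$
(the canonical teaching-learning-optimization rule; $\bar x$ is the
per-gene population mean), accepted on improvement, the teacher replaced by
any learner that surpasses it; in the *learner phase* each learner pairs
with a random other and moves toward a fitter partner or away from a less
fit one, again accepted on improvement; finally the fittest half are kept.
Parents then come from tournament selection ($k = 3$), and one refinement
pass re-runs every generation (whether refinement is once-only or
per-generation was ambiguous; per-generation is the default, with
`refine_each_generation = FALSE` available). The run stops at the
generation budget or after 25 generations without improvement.

*Convergence measurement.* The "first-attainment generation" is the first
generation whose best-so-far fitness comes within $10^{-4}$ of the run's
final best (generation 0 is the initial population). On continuous
benchmarks an optimizer keeps producing vanishing micro-improvements, so
"last strict improvement" would say nothing about when the solution was
effectively found; $10^{-4}$ is one decade finer than fitness scores are
conventionally reported. On the sphere benchmark (pop 30 → 15, 100
generations) TLBPSGA typically attains its optimum around generation 20–30
while the classical GA needs 80–100 — the same qualitative ordering as the
convergence behaviour reported for this optimizer family on real cocoon
data.

## The synthetic cocoon generator

Real rearing-station image sets are proprietary, so `generate_dataset()`
fabricates data with the statistical structure the pipeline assumes:

* **Image**: a bright, dome-shaded ellipse (the cocoon) on a dark
  background, 160 × 90 pixels before resize. The class signal lives in the
  **axis ratio** (male mean 2.30, female 2.10, sd 0.08) and the frequency
  of a multiplicative sinusoidal surface texture along the major axis
  (male 0.14, female 0.10 cycles/pixel, amplitude 0.18, random phase),
  plus Gaussian pixel noise (sd 10 on the 0–255 scale). Ellipse **area is
  held fixed** as the ratio varies, and the texture has random phase, so
  mean intensity carries almost no class information — the signal is in
  gradient-orientation statistics, which is exactly what the HOG → LDA
  path must see. Rotation (sd 5°) and center jitter add nuisance
  variation.
* **Weight**: per-class Gaussians, male 1.10 g, female 1.16 g, common sd
  0.20 g — Cohen's d = 0.3, so the best single weight threshold reaches
  only ≈ 0.56–0.58 accuracy (the theoretical ceiling for d = 0.3 is
  $\Phi(0.15) \approx 0.56$). This encodes the premise that cocoon weight
  with the pupa inside is a weak classifier.
* **Presets**: `synthetic_spec_fc1()` (1579 specimens, 837 male / 742
  female) and `synthetic_spec_fc2()` (1669; 832 / 837) reproduce the
  composition of the two foundation-cross varieties the method targets.

Everything is a pure function of the single seed in the spec.

The texture/noise/shading values were fixed once, at design time, to make
the dataset realistic in the qualitative sense that matters: subtle
per-feature signal, strong combined signal, weak single-scalar baselines.
What the generator does **not** emulate: real cocoon silhouettes and floss
texture, illumination/exposure variation, segmentation imperfections, or
any correlation between weight and image features. Passing tests therefore
demonstrate that the pipeline recovers the kind of shape/texture signal it
is designed for — not that any particular accuracy transfers to real
cocoon photographs, whose difficulty is unknown.

## Problem sizes and numerical choices

Tests and the acceptance script run at the sizes the analyses need rather
than maximal ones: the end-to-end study uses the full FC1-preset (1579
images, 10-fold CV); optimizer benchmarks use population 30 → 15 over 100
generations and 10 paired seeds; unit fixtures use a few dozen to a few
hundred samples. Other numerical choices collected in one place:

* FFT convolution pads to `nextn` sizes and verifies the imaginary residue
  is below $10^{-6}$ (relative) before discarding it.
* Zero-magnitude pixels take orientation 0°; orientation exactly on a bin
  edge belongs to the upper bin (half-open bins).
* MI estimator: quantile bins deduplicated before cutting, so discrete
  features degrade gracefully; constant features score 0 rather than
  erroring.
* Equal-frequency bin count 10: small enough to keep conditional counts
  stable at the class sizes involved, large enough to resolve the
  discriminant coordinates.
* Ties in MI ranking break by ascending feature index; RFE accuracy ties
  break toward the smaller subset — both for determinism.
* `stratified_cv` seeds the classifier per fold (`seed + fold`) so fold
  fits are independent but reproducible.

## Known limitations

* Synthetic difficulty is a free parameter; absolute synthetic accuracies
  are not comparable to accuracies on real cocoon images.
* Hard orientation binning loses the descriptor smoothness of soft-voted
  HOG; this is inherent to the mask-and-filter acceleration.
* Whether the original protocol fitted the compressor per fold or on full
  data is unknown; this package fits per fold, which is the conservative
  choice and may report lower numbers than a full-data fit would.
* The grid optimizer is exhaustive and therefore capped by a cell budget;
  it exists as a baseline, not a recommendation.
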