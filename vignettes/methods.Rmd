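---
title: "Weighted RDM regression and variance partitioning: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted RDM regression and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmdyn)
```

## The problem

When people view object images, the neural representation of those
objects unfolds over a few hundred milliseconds across the ventral
visual stream. A standard way to study this is representational
similarity analysis (RSA): at each time point, the multivariate
response pattern evoked by each image is summarised by a
representational dissimilarity matrix (RDM) over all image pairs, and
candidate models are evaluated by how well their RDMs explain the data
RDMs. Stacking the data RDMs over time gives an *RDM movie* per
participant and region of interest (ROI).

This package implements the full analysis chain for comparing two
model families in that space:

- a **network model**: one RDM per layer of feedforward and locally
  recurrent object-recognition networks (correlation distance,
  1 − Spearman, between layer activation vectors);
- a **visuo-semantic model**: one RDM per human-generated object
  label — colors, textures, shapes, object parts, and subordinate /
  basic / superordinate categories (squared difference between binary
  per-image label values).

Because real source-localised MEG RDM movies are not redistributable,
the package ships a synthetic generator that produces RDM movies from
*known* time-varying nonnegative mixtures of predictor RDMs, so every
stage of the pipeline can be validated against planted ground truth.

## Model construction

### Visuo-semantic dimensions

Labels pass through three stages, mirroring how such models are built
from labeling experiments:

1. **Generation threshold** (`select_generated_labels`): a label
   survives if at least 3 of 15 generation-experiment observers
   produced it for at least one image. Manual curation of
   inconsistent or redundant labels is modelled as an explicit
   exclusion list, not an algorithm.
2. **Validation agreement** (`validate_labels`): an image carries a
   label if at least 75% of 14 validation observers agreed (11/14
   passes, 10/14 does not). All-zero label columns are dropped.
3. **Correlated-dimension merging**
   (`merge_correlated_dimensions`): while any within-group pairwise
   Pearson correlation exceeds 0.9, the most-correlated pair is
   replaced by its elementwise mean and all correlations are
   recomputed. On binary columns Pearson equals the phi coefficient.
   We recompute after *every single* merge rather than sweeping all
   super-threshold pairs at once; with per-merge recomputation the
   procedure is deterministic (ties broken lexicographically by
   dimension name) and terminates, since each merge removes one
   dimension. Merging is restricted to dimensions within the same
   group so that submodel sizes stay well-defined.

Each surviving dimension becomes one squared-difference RDM
(`rdm_from_dimension`). For a binary dimension the dissimilarity is 0
when both images share the label state and 1 otherwise; merged
dimensions take fractional values and plain squared differences.

### The squared-weight identity

Fitting happens in RDM space because of an exact identity: scaling a
model dimension by $w$ before computing squared-difference
dissimilarities multiplies that dimension's dissimilarities by $w^2$,
and squared Euclidean distances sum over dimensions. Hence the RDM of
weighted dimensions equals the weighted sum of single-dimension RDMs
with weights $w^2$ — `weighted_sum_rdms` — and a nonnegative linear
fit of single-dimension RDMs is equivalent to fitting dimension
scalings directly. The test suite verifies this to machine precision
on random dimension sets.

### Network layers

`enumerate_layers` mirrors the layer bookkeeping of the two
architecture families: 4 area stages + decoder for the feedforward
family (5 layers) and 4 areas × 5 unrolled time steps + decoder for
the locally recurrent family (21 layers), 26 predictors in all. The
synthetic activation generator (`generate_activations`) gives each
image a fixed random unit profile and mixes in a category-prototype
pattern whose share grows with depth, so layer RDMs change
monotonically with depth and deeper layers align more with the
category partition — the qualitative depth gradient real networks
show. It does not emulate training dynamics, receptive fields, or any
image computation.

## First-level fitting

For one participant, ROI and time point, the data vector $y$ (the
vectorised RDM, row-major upper triangle) is modelled as
$y \approx Xw + b$ with $w \ge 0$, where the columns of $X$ are the
predictor RDM vectors standardized on the training pairs, $b$ is an
unpenalised intercept absorbing homogeneous dissimilarity changes, and
the fit minimises

$$\lVert y - Xw - b \rVert^2 + \lambda \lVert w \rVert^2,
  \quad w \ge 0.$$

Since standardized columns have zero mean, the intercept profiles out
to $b = \bar y$ and the remaining problem is solved *exactly* by an
active-set (Lawson–Hanson) nonnegative least-squares solver on the
ridge-augmented normal equations, implemented in compiled code
(`src/nnls.cpp`) and batched over time points so one Gram matrix
serves a whole movie. Active-set NNLS terminates in finitely many
steps; the only tolerance is a gradient threshold of $10^{-10}$
(scaled per right-hand side) deciding when a coordinate may enter the
passive set. Tests verify agreement with a dense two-stage
grid-search oracle and with an independent pure-R NNLS implementation.

### Cross-validation over images

To avoid overfitting to the stimulus set, predictions are
cross-validated at the *image* level (`make_fold`,
`fold_schedule`): each fold holds out a stratified test set — by
default 2 faces, 2 body parts (human body parts and animal bodies
pooled) and 4 inanimate objects, i.e. 8 of 92 images at full scale —
trains on the pairs of the remaining images, and predicts only the
test × test pairs (28 per fold at test size 8). Folds are drawn until
every image pair has been in a test set at least once; per pair,
predictions are averaged over covering folds. The penalty $\lambda$
is chosen per fold and time point by nested cross-validation: the
training images are split into inner image-folds (5 by default,
stratified when every stratum is large enough, plain otherwise), and
the grid value with minimal mean held-out squared error wins, ties
going to the larger (more conservative) penalty. The default grid is
20 log-spaced values over $[10^{-4}, 10^2]$; the desk-scale pipeline
configuration uses 5 values over $[10^{-3}, 10]$ and 3 inner folds,
which the noiseless-recovery tests show is ample at 24 images.
Predictors with zero variance on a fold's training pairs are dropped
from that fold with a warning (a binary label can be constant on a
small training subset).

## Second-level variance partitioning

The cross-validated prediction vectors (one per model class, per time
point) enter a second-level nonnegative GLM (`nnls_glm`) with a free
intercept: $R^2 = 1 - SS_{res}/SS_{tot}$, with $SS_{tot}$ about the
mean of $y$ at that time point. Predictions are *not* re-standardized
— they are already calibrated predictions, and the intercept absorbs
offsets. $R^2$ is reported raw (it can be negative for a forced bad
fit; baseline subtraction at inference handles bias). We use the
regression $R^2$ of the NNLS fit, not a squared prediction–data
correlation: the quantity of interest is the variance a constrained
GLM explains, and the two differ once weights are constrained.

- **Total variance** of a class: $R^2$ of the reduced GLM containing
  only that class's prediction (plus intercept).
- **Unique variance** of a class: $R^2(\text{full}) -
  R^2(\text{without that class})$. Because the feasible sets nest,
  unique variance is nonnegative up to solver tolerance — a property
  the tests assert at $-10^{-6}$ on every partition.

`partition_movie` / `partition_group` apply this per participant,
ROI and time point, for model classes and, with the same mechanics,
for submodels (the reduced GLM excluding one submodel keeps all other
predictors).

## Group inference over time

`infer_timecourse` implements the inference chain:

1. **Baseline subtraction**: per participant, subtract the mean over
   the prestimulus window (closed-open $[-200, 0)$ ms by default;
   the desk-scale configuration uses its whole prestimulus segment).
2. **Wilcoxon signed-rank test** across participants at each time
   point (one-sided against zero for variance measures; a two-sided
   variant serves model comparisons). Zeros are discarded before
   ranking and absolute values ranked with average ranks. The null is
   exact: the tabulated distribution when tie-free, full enumeration
   of the $2^n$ sign assignments when ties are present and
   $n \le 16$, and a tie-corrected normal approximation beyond — at
   10–15 participants the exact paths always apply.
3. **FDR control** at $q = 0.05$ per (measure, ROI) family across
   time points, Benjamini–Hochberg step-up (a Benjamini–Yekutieli
   option is available by argument).
4. **Continuity criterion**: significant runs shorter than 10
   consecutive samples (20 ms at 2 ms sampling) are removed.
5. **Onset**: the first time point of the first surviving run;
   reported from the *post*-continuity mask, matching the use of the
   criterion for reporting.

An 80 Hz order-6 Butterworth low-pass (`display_lowpass`, zero-phase
forward–backward) is provided for display only and never feeds
inference; deviations from the row mean are filtered so a constant
trajectory passes through unchanged despite the filter's zero-padded
edges.

## The synthetic generator

`generate_rdm_movie` draws each participant's frame as
$y_t = X\,w(t) + b + \varepsilon$, with nonnegative piecewise-linear
weight curves $w(t)$ (`weight_bump`: 20 ms linear rise to a plateau),
a homogeneous offset $b = 1$ (correlation-distance RDMs hover around
1), and iid Gaussian pair noise. Pair-level noise matches the
regression's error model exactly; a secondary `"pattern"` mode embeds
each frame as latent unit patterns (classical multidimensional
scaling of the double-centred Gram matrix), perturbs the patterns,
and re-derives a correlation-distance frame, exercising the
nonlinearity of realistic measurement noise. All generators are
bit-reproducible from their seeds.

`make_reversal_scenario` plants the motif the pipeline must be able
to detect: ROI 1 loads early (onset 60 ms) on network-layer
predictors, ROI 2 late (onset 140 ms) on visuo-semantic predictors,
and all weights are zero before stimulus onset. Defaults — 24 images
in the standard category proportions, 10 participants, 2 ms sampling
from −100 to 198 ms, noise SD 0.3 against plateau weights of 1 —
were fixed once as a realistic desk-scale regime: the per-pair
signal-to-noise is of order one, so detection must come from the
group statistics, not from a noise-free giveaway. These sizes keep a
full two-ROI, two-class run around three minutes on one core; the
full 92-image, −200…1000 ms epoch is a configuration change, not a
code change.

What passing tests on this generator do **not** show: robustness to
real MEG artifacts (correlated sensor noise, source leakage between
ROIs, inter-participant latency jitter), to the correlation-distance
nonlinearity at low SNR (exercised only qualitatively by the pattern
mode), or to model RDM collinearity as severe as that between 26 real
network layers. Empirical latencies from real data are therefore
emulated qualitatively, not reproduced.

## Numerical and design choices

- **Pair order**: row-major upper triangle ($i < j$), shared by every
  module; `vectorize`/`devectorize` are exact inverses.
- **Spearman ties**: average ranks (the standard convention).
- **Zero-variance activation rows** are an error, not a silent
  `NaN → 0`: after a ReLU an image can genuinely silence a layer, and
  the caller must screen rather than inherit an undefined
  correlation.
- **Dissimilarities are fit raw**: no rank transform of RDMs
  anywhere; the regression operates on the dissimilarities
  themselves.
- **Multiple coverage** of a pair across folds is resolved by the
  mean of its fold predictions.
- **Degenerate inputs**: constant data vectors give intercept-only
  ridge fits; a zero-variance data vector at the second level is an
  error (explained variance is undefined); constant predictor
  columns are dropped per fold (first level) or receive zero weight
  (second level).
- The **null control** runs the second level plus the full inference
  chain on no-signal movies (weights identically zero) rather than
  through first-level CV: the quantity under control — the rate of
  families with any surviving post-continuity significance — is a
  property of the inference chain, and this keeps 200 simulations
  within minutes.

## Known limitations

- The label pipeline models curation as an exclusion list; no
  free-text normalisation is attempted.
- No noise-ceiling estimation and no rank-based RDM comparison; this
  pipeline fits dissimilarities, it does not correlate ranks.
- No positive-semidefiniteness constraint on fitted RDMs.
- Onsets are sampling-resolution quantities; with 2 ms sampling and
  the continuity criterion, recovered onsets sit a sample or two
  after the planted ramp start (e.g. 62 ms for a 60 ms ramp), as
  expected when the ramp must clear the noise floor.
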