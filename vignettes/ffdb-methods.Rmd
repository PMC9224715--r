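---
title: "Staged benchmarking of DFFNN regressors for walking-distance prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged benchmarking of DFFNN regressors for walking-distance prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gaitffdb predicts a clinical walking-capacity score — the distance, in
meters, a patient covers in a standardized 2-minute walk — from a table of
wearable-sensor gait features, and benchmarks the deep feed-forward neural
network (DFFNN) configuration used to do so. This vignette records the
methods and the design decisions behind them; the README shows a worked
example.

## The model

The regressor is a fully connected feed-forward network

```
input_dim -> [round(spread * input_dim)] x depth -> 1
```

with ReLU hidden activations, a linear output neuron, and mean-squared-error
loss on the *unnormalized* target (meters). Two integers describe a shape:
`spread` scales the hidden width relative to the input dimension and
`depth` counts the hidden layers, so a cohort with 92 features at shape
(5, 6) trains six hidden layers of 460 neurons.

Training runs in single precision (C++/Armadillo with BLAS `sgemm`),
minibatched (default batch 32), with Glorot-uniform initialization and
per-epoch reshuffling driven by one integer seed, so a `(data, shape,
config, seed)` tuple is bit-reproducible within one build of the package.
Seven optimizers are supported — SGD, RMSProp, Adam, Adadelta, Adagrad,
Adamax, Nadam — each taking only the learning rate from the user; secondary
hyper-parameters stay at the framework defaults commonly used elsewhere
(epsilon 1e-7, Adam/Adamax/Nadam β₁ = 0.9, β₂ = 0.999, RMSProp ρ = 0.9,
Adadelta ρ = 0.95, Adagrad accumulator 0.1; Nadam uses Dozat's
simplification). A run whose loss becomes non-finite is flagged *diverged*
and stops early.

Note one single-precision subtlety: with learning rate 0 the weights are
exactly unchanged, yet the recorded epoch loss still varies at the ~1e-7
relative level because reshuffling changes the float summation order.

## Preprocessing

All preprocessing is fitted on the training split only and then applied to
both splits:

1. missing values are imputed with the training mean of the observed values;
2. values are winsorized at mean ± k·SD (default k = 4, sample SD);
3. features are z-scored with the post-clipping center and scale
   (constant features get scale 1).

The target is never transformed; errors stay in meters. The train/validation
split draws a seeded random partition with the training size rounded half
away from zero (500 patients at fraction 0.8 give exactly 400/100).

## The quality metric

Each benchmark arm runs `n_exp` independent experiments; every experiment
re-splits the data, re-fits preprocessing, and re-initializes the weights
from its own derived seed. The score is the mean relative validation error

```
MSEarr = mean(validation RMSE) / dist_avg
```

where `dist_avg` is the global cohort mean distance, with the SD taken over
the per-experiment relative RMSEs. Diverged runs are excluded and counted;
if more than half of an arm's runs fail, the arm scores the ceiling 1. The
metric is scale invariant: measuring in centimeters changes nothing.

Prediction quality of a final model ensemble is additionally summarized by
the absolute-error distribution (fractions within 15 m, between 15 and
25 m, above 25 m, plus a 5-m histogram) and by ICC(A,1) — the two-way
random-effects, absolute-agreement, single-measure intraclass correlation
computed from ANOVA mean squares with the McGraw & Wong F-based confidence
interval. When predicted equals measured exactly the interval collapses to
the estimate instead of degenerating.

## The staged benchmark (FFDB)

Exhaustive search over experiments × learning rates × shapes × algorithms
is the product `estimate_space(n_exp, c_lr, c_spread, c_depth, c_alg)` —
126,000 training runs at the default full scale — which motivates the
staged fractional design implemented by `run_ffdb()`:

1. **Epoch calibration** — one probe run per algorithm at a small learning
   rate for the configured `n_epoch` (default 1000). It produces evidence
   only: a plateau flag (relative loss improvement over the final 10% of
   epochs below 1%) and the loss curves. The budget is *not* adapted.
   Because the flag is relative, noiseless data — where the loss keeps
   shrinking toward machine zero — never plateaus; that is a property of
   the criterion, not an error.
2. **Learning-rate sweep** — per algorithm, `c_lr` points logarithmically
   equispaced on [1e-6, 1e-1] inclusive (default 50), each scored with
   `n_exp` experiments on a fixed mid-size shape (default (3, 3)). The
   optimal rate is the minimum of the moving-averaged curve (window 3);
   smoothing guards against single-experiment noise spikes, and ties break
   toward the smaller rate. An algorithm that fails at every point is
   excluded with a warning.
3. **Shape grid** — per surviving algorithm at its optimal rate, all
   spread × depth combinations (default 1..6 × 1..6); ties break toward
   smaller spread, then smaller depth.
4. **Final comparison** — each algorithm's best configuration re-scored
   with `n_exp` fresh experiments; the winner has minimal MSEarr, ties
   breaking toward the plan's algorithm order. The winner's trained models
   and pooled validation predictions are kept.

Every run's seed derives deterministically from the master seed and its
(stage, algorithm, configuration, experiment) coordinates, so any stage can
be re-executed in isolation and reproduces its records exactly. The
executed-run counter always equals the closed-form count
(`plan_run_count()`).

Reports carry no timestamps, and all numeric payloads are serialized as
full-precision (`%.17g`) text parsed back with base R's correctly-rounded
reader, so a written report (`write_ffdb_report()`) round-trips
bit-identically.

## The reverse-weight sanity check

To check that the winning ensemble uses plausible inputs, each input
feature gets a *reverse synapse weight*: the output neuron is assigned 1,
and each earlier neuron receives the weight matrix product with the next
layer's values divided by that layer's width —

```
rw(layer l) = W(l -> l+1) %*% rw(layer l+1) / width(l+1)
```

Biases and activations are ignored and signs are kept, so the score equals
the sum over all input-to-output paths of the path's weight product scaled
by Π 1/width — for an all-linear network it is exactly proportional to the
input gradient. `rsw_table()` averages the vector across an ensemble and
ranks features; `top_bottom_features()` excerpts the k best and worst. The
tests pin this semantics against exhaustive path enumeration.

## Synthetic cohorts

Because clinical gait data cannot ship with the package,
`simulate_gait_cohort()` generates tables with the same statistical shape:
a latent walking-ability factor per patient; a few informative features
that are noisy affine functions of it (cadence-, speed-, and stride-like,
with realistic units in the names); nuisance features sharing a low-rank
correlation to mimic redundant left/right/aggregate sensor columns;
distance affine in the latent factor with multiplicative noise, truncated
positive (defaults: center 137 m, spread 33 m, 511 patients, 92 features,
5 informative); and missingness plus inflation outliers at configurable
rates. With all corruption set to zero the distance is an exact function of
any informative feature, which makes recovery testing sharp: a benchmark
that cannot reach a small relative error there is broken. The generating
ground truth travels with the table (`ground_truth()`).

Linear-latent structure is deliberately the *weakest* structure a DFFNN
must recover; the generator makes no attempt at biomechanical realism.

## Problem sizes

The package's own default scales — 511 patients, 92 features, plan defaults
n_exp 10, c_lr 50, shapes 6×6, 7 algorithms — describe the intended
full-scale use. The test suite and the acceptance script run reduced but
structurally complete plans chosen to fit CI budgets; every reduction keeps
all four stages and the full decision path.

## Configuration and CLI

One YAML (or JSON) document specifies a benchmark completely: data source
(CSV path + target, or a synthetic spec), plan, master seed, output
directory. Unknown keys anywhere are rejected. Every exported report embeds
its configuration, so `inst/cli/ffdb.R sanity-check` can retrain the winner
ensemble from the report directory alone — the recoverability contract.
Subcommands: `run`, `simulate`, `report`, `sanity-check`, `icc`; exit codes
0 (success), 1 (runtime failure), 2 (usage/configuration error).
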