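---
title: "Two-stage gene selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage gene selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microarray and bulk expression studies of cancer produce matrices with tens
of samples and thousands to tens of thousands of genes. Most genes carry no
class information; a classifier trained on all of them overfits, and the
genes that do matter are drowned in noise. `mipsa` selects a compact,
discriminative gene subset in two stages:

1. **Filter (mutual information).** Each gene is scored by the mutual
   information, in bits, between its discretized expression and the binary
   class label (0 = "No Cancer", 1 = "Cancer"):
   \[ I(X;Y) \;=\; H(Y) - H(Y \mid X), \]
   with the plug-in entropies computed from observed frequencies. Genes are
   ranked by score, the top *k* kept, and genes highly correlated with a
   better-ranked retained gene are dropped as redundant.
2. **Wrapper (binary particle swarm + SVM).** A swarm of bit-vector
   particles searches subsets of the filtered pool, minimizing
   \[ f(x) \;=\; \alpha\,\mathrm{Error}(x) \;+\; \beta\,\frac{|x|}{D}, \]
   where \(\mathrm{Error}(x)\) is the cross-validated misclassification
   rate of a soft-margin SVM restricted to the genes whose bits are set,
   \(|x|\) the number of set bits, and \(D\) the pool size.

The selected subset is then evaluated by leave-one-out cross-validation
(LOOCV), with confusion-matrix metrics (ACC, precision, sensitivity,
F-score), ROC and precision–recall curves, and — because the stochastic
search is repeated over derived seeds — a best/average/worst accuracy
summary across runs.

## Discretization and the MI estimator

Expression is continuous, so the filter must discretize before applying the
plug-in estimator. We use **equal-frequency binning** with type-1
(inverse-ECDF) quantile breaks, default `n_bins = 10`. Because the breaks
are order statistics, the bin assignment — and therefore every MI score and
the resulting ranking — is invariant under any strictly monotone transform
of a gene's values (log, scaling, cube). That removes any dependence on
whether upstream processing stored raw, log, or rescaled intensities, and
it is robust to the heavy right tails typical of expression data, which
defeat equal-width bins. Two special cases matter:

* a gene with at most `n_bins` distinct values is already discrete and is
  used as-is, one state per value (a binary marker keeps its two states
  instead of collapsing);
* a constant gene has a single state and scores exactly 0 bits.

The estimate is clamped at zero against floating-point underflow. The
plug-in estimator on the empirical joint distribution automatically
respects \(0 \le I \le \min(H(X), H(Y))\); the test suite asserts this per
gene over a thousand generated datasets, and checks the identity route
\(H(Y) - H(Y|X)\) against a brute-force
\(\sum_{x,y} p(x,y)\log_2\frac{p(x,y)}{p(x)p(y)}\) oracle to `1e-12`. No
k-NN/KSG estimators are provided; at these sample sizes the histogram
estimator with rank-based bins is the standard choice for ranking.

Ties in the ranking are broken lexicographically by gene identifier so that
results are identical across platforms. Redundancy removal runs **after**
top-*k* truncation, scanning kept genes in rank order and dropping any gene
whose absolute Pearson correlation with an already-retained gene reaches
the threshold (default 0.90); the retained, higher-MI partner and the
correlation are recorded. The pool may therefore hold fewer than *k* genes;
nothing is backfilled. Default `k = 100`.

## The binary swarm

Velocities update as
\( v' = w\,v + c_1 r_1 (p - x) + c_2 r_2 (g - x) \)
with fresh uniform draws per component, clamped to \([-v_\mathrm{max},
v_\mathrm{max}]\); positions are resampled through the sigmoid transfer,
\(\Pr(x_j = 1) = 1/(1+e^{-v_j})\). Personal and global bests replace their
incumbents only on **strict** fitness improvement, which makes the
global-best trace non-increasing by construction. The run stops at
`max_iter` iterations or after `stall_iters` iterations without global-best
improvement.

**Inertia in the binary variant.** In real-valued PSO, inertia weights
around 0.7 are routine. In the sigmoid-sampling binary variant they are a
trap: once a particle agrees with its attractors, the attraction terms
vanish, the velocity decays geometrically toward 0, and the inclusion
probability of every settled bit relaxes to the sigmoid's 50% noise floor
(at \(w = 0.7,\ c_1 = c_2 = 1.5\) the stochastic equilibrium is
\(|v| \approx 0.8\), i.e. per-bit agreement of only ~0.69 — the swarm never
converges). We therefore default to \(w = 0.9\) with the classic
\(c_1 = c_2 = 2\); on a known-optimum oracle (Hamming distance to a planted
10-of-50 mask, 30 particles, 200 iterations) this recovers the mask to
Hamming distance 0–2 across seeds, where the low-inertia setting stalls
around distance 7. `v_max = 6` keeps every inclusion probability inside
\([0.25\%, 99.75\%]\), so no bit is ever frozen.

Remaining defaults: 30 particles, 100 iterations, stall patience 20,
initialization with each bit on at probability 0.1 (biased toward the small
subsets the method aims for) and velocities uniform on \((-1, 1)\). An
all-zero position is repaired by switching one uniformly chosen bit on — an
empty gene set has no defined classifier error. Fitness values are cached
by bit pattern; particles revisit subsets frequently, and caching changes
no result, only runtime.

**Fitness weights.** \(\alpha = 0.9,\ \beta = 0.1\): classification error
dominates, and the size term (0.001 per gene at \(D = 100\)) acts as a
tie-break that steadily prunes genes whose removal costs no error. The
error inside the search is estimated by stratified 5-fold cross-validation
with a fold shuffle fixed per swarm run, so fitness values are comparable
and cacheable across the run; LOOCV per particle per iteration would be
quadratically more expensive while changing the ranking of candidate
subsets very little. `error_estimator = "loocv"` restores full
leave-one-out inside the search for users who want it. Final reporting
always uses LOOCV.

## The wrapped classifier

The SVM is delegated to libsvm (via e1071); this package owns what matters
for honest evaluation: kernels as configuration (linear default, polynomial
and RBF available), cost `C = 1` default, and **fold hygiene** — per-gene
standardization statistics are computed on the training portion of each
fold only and applied to the held-out samples. The test suite asserts the
leakage contract directly: shifting only held-out values changes scores,
while shifting train and test jointly is absorbed by the refitted scaler.
Decision values are re-oriented so that larger always means class 1, which
fixes the orientation of ROC/PR curves. The RBF/polynomial \(\gamma\)
defaults to \(1/(d \cdot \mathrm{Var})\) of the pooled standardized
training values, the usual scaling convention.

LOOCV requires at least two samples per class: holding out a singleton
class necessarily leaves a single-class training fold, which has no defined
decision rule. Stratified k-fold, used inside the search, skips such
degenerate folds with a warning and adjusts the denominator — they can
arise on tiny fixtures, not at realistic sample sizes.

ROC and PR curves come from a threshold sweep over the unique held-out
decision scores; AUC uses the trapezoid rule, which on a rank sweep equals
the Mann–Whitney concordance probability with ties counted one half (the
suite checks this equivalence to `1e-12`, plus agreement with pROC).
Precision, sensitivity and F-score are reported as 0 and flagged when their
denominator is zero.

## Repeated runs and seeding

The search is stochastic, so the pipeline reruns it `n_runs` times (default
5) with child seeds derived deterministically as `base_seed + run - 1`, and
summarizes LOOCV accuracy across runs as best/average/worst. The best run
(ties broken toward the smaller subset, then the earlier run) supplies the
reported subset, metrics and curves. Every random element — the generator,
fold shuffles, swarm initialization and updates, the repair draw — flows
from explicit seeds, and all random draws restore the caller's RNG state,
so identical configuration and `base_seed` reproduce byte-identical output
files.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a Gaussian class-conditional model of the
microarray regime: few samples, many genes, two classes. Default study
conditions: 60 samples × 200 genes, 10 informative genes, per-gene
between-class shift of 2 noise-SD (direction randomized per gene, so
markers can be up- or down-regulated), balanced classes, per-gene baseline
means drawn once. An optional correlated block adds noisy copies of
informative genes (copy noise 0.2 SD, expected correlation ≈ 0.98) to
exercise redundancy removal, and planted genes are scattered to random
column positions so positional bugs cannot pass recovery tests. The matrix
regime is a deliberately scaled-down version of the breast-cancer
benchmarks this method targets (tens of samples against tens of thousands
of genes); 200 genes keep the full suite fast while preserving the
few-informative-among-many structure that the filter and wrapper must
resolve.

The generator does **not** attempt microarray-specific artifacts: probe
effects, batch effects, intensity-dependent variance, or correlated noise
beyond the explicit block. Passing recovery tests therefore demonstrates
that the machinery works under a clean additive-shift signal model; it does
not certify performance on real arrays, where normalization quality and
batch structure dominate. Real inputs are assumed preprocessed (no CEL
parsing, normalization, or probe-to-gene mapping).

## Behavior at the optimum worth knowing about

At effect size 2 with 60 samples, a handful (~4–5) of informative genes
already drive the cross-validated SVM error to zero. Past that point the
fitness offers no reward for adding the remaining informative genes, and
the size term steadily prunes them along with noise genes: the minimizer of
\(\alpha\,\mathrm{Error} + \beta|x|/D\) is the *minimal zero-error core*,
not the full planted set. Consequently the pipeline reliably returns small,
highly accurate subsets (LOOCV accuracy 1.0 on the default regime) that
contain a subset of the planted genes — users who want exhaustive marker
recovery should read the stage-1 ranking, which does place 9–10 of 10
planted genes in its top ranks, rather than the stage-2 subset, which is
optimized for compactness at equal accuracy. This is a property of the
objective, not of the optimizer.

## Numerical and degenerate-input choices

* Entropies use log base 2 throughout; \(0 \log 0 \equiv 0\).
* MI is clamped at 0; the bound check allows `1e-12` slack for rounding.
* Correlation with a constant gene is undefined (`NA`) and treated as 0,
  i.e. never redundant.
* `k` larger than the gene count is clamped with a warning.
* Report files format numbers as `%.17g`: byte-stable and round-trip exact.
* Labels are validated to be exactly {0,1} with both classes present;
  missing expression values fail the load unless per-gene mean imputation
  is explicitly requested — silently imputing would hide data problems the
  user should see.

## Problem sizes used by the test suite

Unit tests run on instances of 4–60 samples and 1–200 genes; the
end-to-end checks use the calibrated 60 × 200 regime with 5 swarm runs, 50
generator seeds for filter-recovery rates, and 20 random subsets for the
wrapper-vs-random comparison. These sizes were chosen as the smallest at
which each property is stable across seeds.

## Known limitations

* Binary classes only; no multi-class or probability calibration.
* The histogram MI estimator is for ranking, not unbiased estimation of
  information content.
* The wrapper's accuracy estimates are model-selection quantities;
  reporting LOOCV accuracy of a subset selected on the same samples is
  optimistically biased, as is standard for wrapper methods — an external
  validation set is the only honest generalization estimate.
* No comparison harness against alternative optimizers or classifiers is
  included.
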