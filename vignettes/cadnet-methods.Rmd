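---
title: "Developing and blindly verifying a GA-tuned elastic net for CAD"
author: "cadnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and blindly verifying a GA-tuned elastic net for CAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadnet)
```

## The problem

Patients presenting with stable chest pain are commonly triaged toward
invasive coronary angiography by stress imaging, yet a majority of those
referred turn out not to have obstructive coronary artery disease (CAD).
`cadnet` implements, as a reusable and fully testable pipeline, a machine
learning strategy for screening obstructive CAD from a high-dimensional
vector of resting biosignal features: develop a linear model against an
angiographic gold standard on training and validation cohorts, freeze it,
and report its diagnostic performance on a naïve verification cohort that
the development stage never touched.

The proprietary signal features of the original device are not available,
so the package ships a seeded synthetic cohort generator
(`simulate_cohort()`) that reproduces the *statistical shape* of the
problem — cohort sizes, prevalence, demographics, block-correlated features
with a planted sparse signal, and per-subject acquisition noise — making
every stage of the pipeline exercisable end to end.

## The angiographic gold standard and the training target

A subject is CAD **positive** when any lesion has stenosis ≥ 70%, or a
measured fractional flow reserve (FFR) ≤ 0.80; where FFR was measured it
overrides the visual stenosis (`cad_label()`).

The continuous training target is a worst-case-lesion **modified Gensini
score** (`modified_gensini()`). Each lesion receives a banded severity
score (0/1/2/4/8/16/32 for stenosis bands up to total occlusion) times a
segment location multiplier (left main 5 down to 0.5); only the maximal
product counts. With collaterals present the raw score is dampened by
0.25. Finally

$$\text{modified} = \log(1 + \text{raw})$$

which compresses the exponential severity ladder into a range a linear
model can track. Choices the source method leaves open, resolved here
once:

* natural logarithm with offset 1, so lesion-free subjects map exactly
  to 0;
* dampening applied to the raw product, before the logarithm;
* band edges are lower-closed (stenosis exactly 75 scores 4).

Regressing on this continuous target rather than the binary label lets the
model learn along the disease continuum; the binary label is used only
when evaluating discrimination.

## The model and its loss

`enet_fit()` minimises the weighted elastic-net loss exactly as written,
with no $1/(2n)$ normalisation:

$$L(\alpha, \lambda, W) = \sum_i u_i (y_i - x_i'W - b)^2 +
  \lambda\left(0.5\,(1-\alpha)\|W\|_2^2 + \alpha\|W\|_1\right)$$

by cyclic coordinate descent with exact soft-threshold updates, an
unpenalised intercept, and a glmnet-style active-set strategy (iterate the
nonzero set to stability, then rescan all coordinates). Implications of
the unnormalised form:

* the ridge limit ($\alpha = 0$) satisfies
  $(X'X + 0.5\lambda I)W = X'y$ on centred data — the closed form used as
  a test oracle;
* comparisons against glmnet must rescale the penalty:
  $\lambda_{\text{glmnet}} = \lambda / (2n)$.

Features are standardised to zero weighted mean and unit weighted variance
on the training split before fitting (the shared $\lambda$ is then
meaningful across features); coefficients are reported on the original
scale. Convergence is declared when no coefficient moves by `tol` in a
full sweep; every update is an exact coordinate minimisation, so the
objective is non-increasing — a property the test suite asserts.
Zero-variance features are pinned to zero with a warning. A fit that
exhausts `max_sweeps` raises a classed error carrying the last objective
value.

Per-subject weights implement the *upweighting* hyperparameter:
`apply_upweighting(y, threshold, factor)` gives weight `factor` to
subjects whose modified Gensini score is at or above the threshold,
emphasising severely diseased subjects during training.

## Feature reduction

`reduce_by_correlation()` removes redundancy before fitting: a greedy scan
in ascending column order drops any feature whose absolute Pearson
correlation with an already retained, smaller-index feature exceeds the
threshold. The scan is deterministic (the smaller index always survives),
idempotent, and computed on training rows only, keeping the verification
split blind. Zero-variance columns have undefined correlation; they are
flagged and never dropped for correlation.

## Hyperparameter search

Five hyperparameters are tuned jointly by a genetic algorithm
(`ga_evolve()`): the elastic-net mixing $\alpha \in [0,1]$ and penalty
$\log_{10}\lambda \in [-4, 2]$, the upweight factor $\in [1, 10]$, the
Gensini weighting threshold (spanning the observed target range), and the
correlation reduction threshold $\in [0.80, 1.0]$.

Each genome is scored by running the full inner pipeline — reduction,
upweighting, elastic-net fit on training, continuous predictions on both
development splits — and evaluating

$$\text{Fitness} = -\sum_{i=1}^{5}\left[(1-\mathrm{AUC}(T_i))^2 +
  1.5\,(1-\mathrm{AUC}(V_i))^2\right]$$

over five *nested noise subsets* of the training ($T_i$) and validation
($V_i$) sets. Subset 1 holds everyone; each further subset peels off the
subjects above the next noise-volume threshold, so cleaner acquisitions
are counted up to five times and the search cannot buy fitness on noisy
data alone. The four thresholds sit at the 60/70/80/90th percentiles of
the training noise volumes — a choice of this package, since the source
method does not publish its cutoffs. AUC is the Mann–Whitney rank
statistic (`rank_auc()`, ties counted one half), shared verbatim between
the tuner and the final evaluation, and invariant under monotone
transforms of the model output.

GA mechanics: per-gene mutation with probability 0.33 (half Gaussian
perturbations with sd 10% of the gene range, half uniform replacement,
clipped to range); single-point crossover for half of the offspring;
rank-weighted parent selection with **cubic** rank weights; elitism 2; stop
after 10 consecutive generations without improvement of the best-ever
fitness, with a hard cap (`max_generations`) as a safety net. The cubic
rank weights are this package's choice: on small evaluation budgets
(~100 evaluations of a smooth 2-gene toy problem) linear rank weights beat
an equal-budget uniform random search only ~60% of the time, while cubic
weights with a small population win >90% — the high mutation rate keeps
exploration alive despite the stronger selection pressure. Non-converging
elastic-net fits inside the search score $-\infty$ rather than aborting
the run; the search simply avoids those regions.

The GA inner loop uses a relaxed coordinate-descent tolerance
(`enet_tol = 1e-4`, 1500 sweeps): fitness is rank-based and insensitive to
coefficient changes at that scale. The winning genome is refit once at
`1e-5`/20000 sweeps and becomes the frozen model.

## Decision threshold and blinded verification

The clinical cutoff is selected on the **validation** ROC only
(`select_threshold()`): among operating points with sensitivity at or
above `sens_floor` (default 0.90 — the safety-first rule that a screening
test must miss few true positives), the one maximising specificity wins;
ties break toward higher sensitivity, then the lower threshold. Each
operating point is represented by the midpoint of the score interval that
realises it, the usual ROC-threshold convention, which maximises the
margin to the scores on either side. If no point reaches the floor the
maximal-sensitivity point is returned with a warning flag.

`cadnet_verify()` then touches the verification split exactly once:
continuous scores, classification at the frozen threshold (score below
threshold ⇒ negative; at or above ⇒ positive), the confusion matrix, and
sensitivity/specificity/NPV/PPV/AUC. Metrics with zero denominators are
reported as absent, never as zero.

Confidence intervals are bias-corrected and accelerated (BCa) bootstrap
intervals from subject-level resampling (`bootstrap_ci()`, default 2000
resamples), mirroring the default of the MATLAB interval routine the
original analysis cites. Implementation details that matter:

* the bias-correction quantile counts ties as one half, so a
  zero-variance statistic (e.g. sensitivity with every positive correct)
  collapses the interval onto the point estimate rather than producing
  `NaN`;
* acceleration comes from the jackknife; a zero spread gives $a = 0$;
* resamples on which the metric is undefined (no positives drawn, say)
  are skipped and counted; more than 50% undefined is an error advising a
  larger cohort;
* intervals are widened, if necessary, to contain the point estimate, and
  inherit the metric's natural bounds from the resampled values.

For proportion metrics at small n the BCa interval undercovers slightly
(the test suite measures ~95% coverage at true sensitivity 0.85 with 25
positives; at true values very close to 1 the degenerate-sample collapse
makes nominal coverage unattainable for *any* resampling interval).

Demographics tables compare cohorts with the pooled-variance two-sample
t-test for continuous rows — computable from printed (mean, sd, n)
summaries via `ttest_summary()` — and the Pearson chi-square test on 2×2
counts for categorical rows. Applied to the published development
(61.5 ± 10.7, n = 512) and verification (59.0 ± 9.8, n = 94) age
summaries, the pooled t-test gives p = 0.035, reproducing the printed
two-decimal 0.04.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws, per subject:

* demographics matched to the published development-cohort moments (age
  ~ N(61.5, 10.7²) truncated to [21, 95], 60.2% male, BMI ~ N(31.3, 7.0²)
  truncated at 15, heart rate ~ N(72, 12²));
* a noise volume ~ LogNormal(0, 0.5) — the source method never defines
  this scale, so the unit-median log-normal is a stipulation;
* an angiogram: lesions present with a rate *solved analytically* from
  the target prevalence (default 0.31), then 1 + Poisson(1.5) lesions,
  each critical (stenosis ~ U[70, 100]) with probability 0.35 or
  sub-critical (~ U[20, 65]); FFR is measured with probability 0.5 for
  stenoses in [40, 70) and declines with stenosis, creating
  FFR-borderline cases; collaterals appear with probability 0.2 given any
  lesion ≥ 90%. Segment codes are drawn with weights favouring RCA/LAD
  territory. Because the lesion rate is derived in closed form from the
  per-lesion positive probability, the cohort prevalence tracks
  `prevalence_target` without iterative tuning (measured 0.29–0.34 over
  20 seeds at the default).

Features come in 40 equicorrelated blocks sharing a latent factor per
block (within-block correlation 0.95), guaranteeing pairs above the 0.907
reduction threshold. Ten features — the first of each of the first ten
blocks — carry the standardized modified Gensini score times
`signal_strength` (default 1). Per-subject measurement noise is additive,
with standard deviation proportional to
`(1 + noise_volume * noise_scale)` (`noise_scale` default 0.2), normalised
so the pooled within-block correlation equals the configured 0.95 while
noisier acquisitions still receive strictly larger residual variance.

The generator does **not** emulate raw phase signals or their physics, ECG
waveforms, feature distributions of the real device, or the real
cohort's lesion-location epidemiology (unpublished). Consequently a
passing pipeline demonstrates that the machinery recovers a recoverable
planted signal under realistic correlation and noise structure — it says
nothing about the clinical performance of any real device, and clinically
reported verification figures for such devices are not reproduction
targets here.

## Problem sizes and numerical choices

The package's own study-sized runs use the full 606-subject cohort
(339/173/94 splits, 405 features) with a GA budget of population 30 for at
most 30 generations — about 900 pipeline evaluations, a few minutes of
compute — and 2000 bootstrap resamples for verification intervals. The
fast end-to-end tests use a 220-subject, 60-feature cohort with a small GA
budget; test tolerances follow each property's own sampling noise, e.g.
binomial standard errors for empirical frequencies.

Other fixed numerical choices: coordinate updates cycle in ascending
column index (deterministic runs); score exactly at the decision threshold
classifies positive; stratified split assignment uses largest-remainder
allocation of positives so split sizes are exact; all cohort CSVs are
written with 17 significant digits so read–write round trips are
bit-exact; model JSON carries coefficients at full precision and a feature
hash that `cadnet_verify()` checks before scoring a cohort.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
res <- run_pipeline(dir,
                    config = cohort_config(seed = 42),
                    ga = ga_config(population_size = 30,
                                   max_generations = 30),
                    seed = 42)
print(res$model)
print(res$report)
plot(res$model)
```

## Known limitations

* The elastic-net coordinate descent converges slowly for tiny penalties
  on strongly collinear designs; inside the GA such fits are cut off at
  the sweep budget and scored $-\infty$, which biases the search away
  from the near-unpenalised regime. This is intended behaviour, not a
  silent approximation, but it means the search does not explore
  $\lambda \to 0$ exhaustively.
* BCa intervals for proportions at n below ~30 are approximate; exact
  binomial intervals are the right tool when a single proportion is the
  quantity of interest.
* The GA is single-objective and single-population; no parallel
  evaluation is attempted, only determinism per seed.
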