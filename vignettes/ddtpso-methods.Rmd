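---
title: "Methods: the dynamic DTO/PSO hybrid and its feature-selection wrapper"
author: "ddtpso authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dynamic DTO/PSO hybrid and its feature-selection wrapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddtpso)
```

## The optimization model

`ddtpso` implements a population optimizer for bounded continuous
minimization that alternates between two update families:

* **Particle swarm (PSO).** Each agent keeps a velocity
  $v \leftarrow w(t)\,v + c_1 r_1 \odot (p - x) + c_2 r_2 \odot (g - x)$,
  where $p$ is the agent's personal best, $g$ the global best, and
  $r_1, r_2$ are componentwise uniform draws. The inertia weight decreases
  linearly from `inertia_max` (0.9) to `inertia_min` (0.6) over the run, the
  standard time-varying schedule: early iterations favour momentum
  (exploration), late iterations favour contraction.
* **Dipper-throated (DTO).** Agents are ranked by fitness each iteration.
  The worst `exploration_fraction` of them (default 70%, the conventional
  exploration share for this algorithm family) take a "flying" velocity
  update $v \leftarrow K_3 v + K_4 r_1 \odot (x_{best} - x) + K_5 r_2
  \odot (g - x)$; the rest take the "swimming" contraction
  $x \leftarrow x_{best} - K_1 |K_2\, x_{best} - x|$, with
  $K_1 = 2u_1(1 - t/T)$ and $K_{2..5} = u_{2..5}$, $u_i \sim U(0,1)$ drawn
  per agent per iteration. Several published variants of the dipper-throated
  update coexist; we adopt this canonical two-rule form because it cleanly
  separates an exploratory and an exploitative phase, and we make every
  coefficient overridable so the rules are unit-testable against
  hand-evaluated cases.

The **dynamic controller** starts with DTO and switches to the other
strategy whenever the best-so-far fitness has failed to improve by more than
`swap_tolerance` ($10^{-8}$) for `swap_patience` (5) consecutive iterations,
resetting its counter at each switch or improvement. No textual criterion
for the swap is fixed by the method's originating description, so we chose
stagnation-driven switching: it is simple, deterministic given the seed, and
lets each family rescue the other's stalls, which is the stated motivation
for hybridizing them. Swapping is per-iteration and population-wide, not
per-agent, keeping the two update families' internal assumptions intact.

Defaults are 10 agents and 80 iterations. Acceleration constants default to
$c_1 = c_2 = 2$, the PSO standard; a published bracket of "[2, 12]" for
these constants is ambiguous and we deliberately do not interpret the 12 as
$c_2$ (both constants are configurable). Where iteration/run counts are
quoted inconsistently in the surrounding literature (500 iterations / 30
runs for plain DTO vs 80 iterations / 20 runs for the experiment harness),
the package defaults follow the experiment harness and make the run count an
explicit experiment-level parameter.

Numerical choices: positions are clipped to the box after every move
(velocities are left untouched by clipping); objective values that are not
finite are replaced by $+\infty$ and counted, so a misbehaving objective can
never displace a finite personal best; ties in the global best keep the
incumbent, which makes trajectories stable under seeds.

## Binary feature selection (bDDTPSO)

The wrapper searches the continuous unit box $[0,1]^d$. At evaluation time
each candidate is squashed through the logistic transfer
$F(s) = 1/(1 + e^{-10(s - 0.5)})$ and thresholded inclusively at 0.50 — a
component exactly at the center maps to bit 1. The continuous population is
never overwritten by bits; only evaluations are binarized. The unit box is
used so the sigmoid center 0.5 splits the search volume evenly.

The fitness of a mask is the standard wrapper objective

$$\mathrm{fit}(m) = \alpha\,\mathrm{err}(m) + (1-\alpha)\,\frac{|m|}{d},$$

with $\alpha = 0.99$: classification error dominates, and the size term
breaks ties in favour of smaller subsets. The error is the
misclassification rate of a $k$-nearest-neighbour classifier ($k = 5$, odd
to avoid vote ties; Euclidean distance on features standardized with
training-split statistics only) evaluated on the held-out validation third.
The all-zero mask is given a $+\infty$ sentinel rather than a repaired
random bit, keeping the fitness landscape pure; occurrences are counted in
the run result. The KNN is implemented with a deterministic tie-break (the
tied class owning the nearest neighbour wins) precisely so that whole runs
are bit-reproducible under a seed; it is cross-checked in the tests against
both a brute-force double-loop implementation and `class::knn` in tie-free
settings.

Experiments (`run_fs_experiment`) give every method × run cell a globally
distinct seed derived from a base seed, and the harness reports aggregate
run statistics (mean/best/worst/std of per-run best fitness, mean validation
error, mean selected fraction — subset sizes are always reported as
fractions of $d$ so they are comparable across dimensionalities).

## Splitting, evaluation and tuning

Datasets are split into stratified train/validation/test thirds (equal
within one sample per class); the validation third drives wrapper fitness
and tuning, the test third is only used for final reports. Final
classifiers are also assessed by stratified 10-fold cross-validation;
one-vs-rest confusion counts are summed over classes and folds before
metrics are computed (micro-averaging), matching single-table metric
formulas. Standardization statistics are always fitted on the training
portion of whichever split is in effect.

Hyperparameter tuning reuses the same optimizer over the unit box with a
declarative decode (`hyperparam`/`decode_hyperparameters`): continuous
parameters interpolate linearly or log-linearly, grids and categories bin by
floor-scaling with the right-edge clamped. The bundled tunable classifier
is a single-hidden-layer perceptron (`nnet`), the desk-scale stand-in for a
deep network: its space is hidden width (grid), weight decay
(log-continuous) and the iteration cap (grid). The MLP's weight
initialization is seeded locally and the caller's random stream restored, so
tuning objectives are deterministic per candidate. Training failures score
as worst-possible and are counted, never silently dropped.

## Augmentation

The augmentation stage expands each image class to a fixed quota (default
4000) using only the three label-preserving transforms — horizontal flip,
vertical flip, 90° counter-clockwise rotation — and their compositions.
These generate the 8-element symmetry group of the square; the generator
enumerates the 7 non-identity symmetries in a fixed order (shortest chains
first) and cycles round-robin over source images, so duplicates appear only
after the $7 \times n_{src}$ pool is exhausted, at which point the cycle
restarts with a warning. Every augmented record carries its op chain and
source index, and the tests replay each chain to verify provenance exactly.
Images must be square (the rotation would otherwise change the grid shape).

## What the synthetic generators emulate

`gen_feature_dataset` emulates the structure of deep global-average-pooling
feature tables: an informative block of class-conditional Gaussians (unit
within-class sd, between-class shift `class_separation` per feature, random
sign per column), a redundant block of unit-norm random linear combinations
of the informative block plus Gaussian noise (`redundancy_noise_sd` = 0.1,
small against unit feature variance so redundancy is genuine), and
label-independent standard-normal noise columns, with a recorded column
permutation. The standard validation fixture is 200 samples, 5 informative
+ 3 redundant + 12 noise features, 2 classes, separation 3, seed 7 — small
enough that exhaustive $2^{10}$-mask oracles are affordable on 10-feature
restrictions, hard enough that selection matters.

What it does **not** emulate: real deep features are non-Gaussian,
correlated in blocks, and class boundaries are not axis-aligned mean shifts;
real ultrasound images have speckle, anatomy and acquisition artifacts that
the blob-texture image generator does not attempt. Passing tests therefore
demonstrate the correctness and calibration of the machinery — not clinical
performance on real breast-ultrasound data, which additionally requires the
original images and a trained feature extractor.

A note on reading the harness's numbers at desk scale: with separation 3
the standard fixture is nearly separable, so validation errors near 0 and
very small selected fractions are the expected regime, and informative-set
recall can be well below 1 simply because a couple of informative or
redundant columns already carry the signal and the size penalty prunes the
rest. The recall comparison against random masks of equal size is the
meaningful statement.

## Statistics harness

Classification metrics are the six standard confusion-table formulas
(accuracy, sensitivity, specificity, positive/negative predictive value,
and the F score $TP/(TP + 0.5(FP+FN))$); zero-denominator metrics are
reported as missing, never as 0. Run statistics use the $M-1$ standard
deviation. Descriptive statistics use linear interpolation between order
statistics for quartiles (R type 7), the mainstream convention; under
heavily tied per-run values all conventions collapse to the same numbers.
One-way ANOVA is extracted from `stats::lm`'s decomposition with an explicit
degenerate flag when the residual mean square vanishes. The one-sample
Wilcoxon signed-rank test drops zero differences, midranks ties, and
computes the two-sided $p$ exactly from the signed-rank null distribution
for $n \le 25$ without ties (normal approximation with tie and continuity
correction otherwise). Testing strictly positive per-run errors against a
theoretical median of 0 — as benchmark reports in this literature do — is
statistically vacuous but reproduced as-is, with the forced outcomes
($W^+ = n(n+1)/2$, $p = 2/2^n$) serving as structural checks. The linear
regression report is ordinary least squares with $t$-based 95% intervals
and the slope F-test; a constant response is reported as slope 0 with
$R^2 = 0$.

Calibration is tested, not assumed: the ANOVA type-I error rate is checked
against [0.04, 0.06] over 2000 null simulations of the 12 × 11 design, and
the exact Wilcoxon $p$ is checked for uniformity under random sign flips at
every achievable level ($n = 10$, 10,000 simulations).

## Problem sizes used in validation

The shipped validation runs at deliberate desk scale: 5-dimensional
benchmark objectives with 10 agents × 80 iterations (20 seeds for the
random-search comparison), exhaustive oracles on 10-feature restrictions of
the 200-sample fixture (10 seeds), 10-run selection experiments on the full
20-feature fixture, 32 × 32 synthetic images for the 4000-per-class
augmentation check, and the calibration simulation counts above. These
sizes were chosen so the whole suite exercises every claim in minutes while
keeping the exhaustive and Monte-Carlo oracles exact enough to be
discriminating.

## Known limitations

* The dipper-throated coefficient laws vary across published descriptions;
  ours is one canonical choice, fully parameterized but not the only
  possibility.
* The stagnation-driven swap rule is a design decision; other schedules
  (fixed alternation, per-agent swapping) are plausible and would need only
  a new controller.
* The wrapper's error/size weighting $\alpha$ is a convention; reported
  fitness values are only comparable between methods using the same
  $\alpha$.
* KNN wrapper fitness uses a single train/validation split per run, not
  cross-validated fitness; this matches the harness it reproduces but adds
  split variance to per-run results.
* The MLP stand-in has no learning-rate or batch-size dimension (its
  optimizer is quasi-Newton); the tuning mechanism is identical, but the
  space is not a literal CNN hyperparameter space.
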