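---
title: "Boosted swarm optimization and FKNN wrapper feature selection: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted swarm optimization and FKNN wrapper feature selection: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmsel)
```

## The optimizer

Canonical global-best PSO moves `N` particles through a box-bounded search
space. Particle `i` keeps its best visited position `pB_i`; the swarm keeps
the best overall position `gBest`. Each iteration updates velocities

    V <- omega * V + c1 * r1 * (pB - X) + c2 * r2 * (gBest - X)

with fresh uniform draws `r1`, `r2` per dimension, clamps them to
`[-Vmax, Vmax]`, and advances `X <- X + V` with positions clamped to the
box. Defaults are `N = 30`, `c1 = c2 = 2`, `Vmax = 6`, and a budget of
300,000 objective evaluations — the conventional setting for this family
of benchmarks. Personal and global bests are replaced only on strict
improvement; exact ties keep the incumbent.

`run_srwpso()` adds three independently switchable strategies:

1. **Sobol initialization.** The initial swarm is the first `N` points of
   the unscrambled Sobol sequence mapped affinely onto the box. Low
   discrepancy improves early coverage relative to uniform sampling; the
   gain is front-loaded and fades as the swarm contracts.
2. **Random replacement (RRS).** Before each velocity pass, every personal
   best is hybridized with the global best: per dimension, a standard
   Cauchy draw `C` is compared to the decay factor `a = 1 - FEs/MaxFEs`,
   and the coordinate is replaced by the global best's whenever `a < C`.
   The hybrid is re-evaluated (consuming budget) and *unconditionally*
   becomes the new personal best, so personal bests can worsen — a
   deliberate diversity injection. Only the global best is monotone, and
   the tests assert monotonicity for it alone. Early on (`a` near 1)
   replacement is rare; as the budget depletes the replacement probability
   climbs toward `P(C > 0) = 1/2`, while the Cauchy tail keeps occasional
   replacement possible at any stage.
3. **Adaptive inertia weight (AWS).** Once per iteration the weight is
   `omega = (1 - FEs/MaxFEs)^beta` with `beta = 1 - C1 * S / MaxFEs`, `C1`
   a Cauchy draw. The scalar `S` starts at 0.01, halves whenever an
   evaluation improves the global best, and grows by 1 otherwise, so long
   stagnation amplifies the perturbation around the plain linear decay.

With all three switches off, `run_srwpso()` is step-for-step identical to
`run_pso()` under a shared random stream — the basis of the ablation test
and of the eight named strategy combinations.

### Numerical guards

* `omega` is computed in log space; a zero base (budget exhausted) yields
  `omega = 0` for any exponent, and the weight is capped at 10. The cap is
  a safeguard against overflow from heavy-tailed `beta` draws; the velocity
  clamp bounds the dynamical effect regardless.
* Boundary handling clamps positions to the violated bound (no
  reflection), mirroring the velocity clamp's style. The replacement
  hybrid is clamped the same way before evaluation.
* The inverse-CDF Cauchy sampler redraws on the (measure-zero) tangent
  singularities.
* A run is bit-for-bit reproducible from `(config, seed)`: the seed is
  installed locally and the caller's RNG state restored afterwards.

### Evaluation accounting

Every objective call increments the budget counter exactly once. With RRS
on, an iteration spends `2N` evaluations (replacement pass + update pass);
the trace records `(FEs, best_score)` after every evaluation batch, which
is what the convergence-curve plots consume.

## The binary variant

`run_bsrwpso()` runs the same continuous dynamics on `[0,1]^D` while each
particle carries a persistent bit mask. After every position update, each
bit flips with probability `V(x_d) = |tanh(x_d)|` of its continuous
coordinate — coordinates near 0 freeze their bit, large coordinates churn
it. Fitness is always evaluated on masks; bests store (mask, coordinate)
pairs compared on mask fitness.

Design choices the continuous formulation leaves open:

* **Dual representation.** The V-shaped rule is read as a flip
  *probability* applied to the persistent mask, with `V` evaluated on the
  continuous coordinate. A literal binary-argument reading would make
  `V(0) = 0` absorbing and velocity-free; the dual representation keeps
  both the complement semantics and the swarm dynamics. (Applying `V` to
  the velocity instead, in the style of the older binary-PSO literature,
  is a known alternative we did not adopt.)
* **Replacement in binary mode.** A replaced dimension inherits the
  global best's continuous coordinate *and its bit*; the resulting mask is
  then re-evaluated. An earlier design re-discretized the personal-best
  mask through the flip rule after each replacement pass, but that flips
  mid-range coordinates at up to ~46% per bit per iteration, which
  destroys the personal-best attractor and lets uninformative bits ride
  along in the returned masks. Coordinate-wise inheritance is also the
  more literal binary reading of the replacement rule.
* **Initial masks** threshold the initial coordinates at 0.5, giving an
  unbiased Bernoulli(1/2) start under either initializer.
* **Iteration budget.** Subset-selection runs are iteration-limited
  (default 50 iterations, swarm 20 — the conventional wrapper setting);
  the equivalent evaluation budget `N + iterations * (2N or N)` feeds the
  decay schedules.

## FKNN

The fuzzy K-nearest-neighbor classifier assigns a query membership in
class `i` as the inverse-distance-weighted average of the `k` nearest
training points' memberships, with weights `d^(-2/(m-1))` and Euclidean
`d`. Predictions take the maximal membership; exact ties go to the lowest
class index. Defaults `k = 5`, `m = 2` are the standard choices in the
FKNN literature; the membership initialization defaults to crisp one-hot,
with the Keller-style neighborhood scheme (`0.51 + 0.49 *` same-label
neighbor fraction) available. A query that coincides with training points
returns their averaged membership columns — the limit of the rule as the
distance vanishes. Neighbor ties at the `k`-th distance keep the first
`k` in stable index order.

## The wrapper pipeline

For each outer fold of a stratified k-fold split:

1. A min–max scaler is fitted on the training partition only; both
   partitions are mapped through it (test values clamped to `[0,1]`).
   Clinical tables mix counts, percentages and concentrations, so
   unscaled Euclidean distances would be dominated by the widest-ranged
   feature.
2. A fixed, seeded, stratified inner resampling of the training partition
   defines mask fitness: `0.99 * inner_error + 0.01 * |mask|/D`, with
   the empty mask pinned to the sentinel value 1 so selecting nothing is
   never optimal. The inner error defaults to a 3-fold cross-validation
   estimate — every training point predicted exactly once — because its
   error quantum (one sample in the full training partition) resolves the
   per-feature penalty against real error differences. A single 80/20
   hold-out (`inner_folds = 1`) is cheaper, but its coarser quantum
   leaves many masks tied on fitness, and uninformative features then
   ride along in winning masks: in our recovery experiments the hold-out
   variant returned visibly larger masks with weaker separation between
   planted and noise features. Either way the resampling is fixed per
   outer fold, so fitness is a deterministic function of the mask and can
   be cached across the swarm's revisits.
3. `run_bsrwpso()` searches the mask space; the winning mask's FKNN is
   refitted on the full training partition and scored once on the
   untouched test fold (accuracy, sensitivity, MCC, F-measure, computed
   one-vs-rest for the designated positive class, which is the
   first-appearing label by default).

Outer-test rows never reach a scaler fit or a fitness evaluation; the test
suite enforces this by corrupting test rows and asserting the fold's
search is unchanged. Repeating the whole procedure with derived seeds
(`repeated_selection_counts()`) yields per-feature selection counts over
`repeats x folds` fold-level searches — the stability profile used to
identify reliably informative features.

## The synthetic generator

`generate_synthetic_classification()` emulates a small clinical cohort:
default 300 samples, 36 non-negative right-skewed features (log-normal
with shape 0.5, marginal skewness about 1.75 — strong skew while keeping
sample moments stable enough that the planted standardized effect is
recoverable at cohort size), a balanced binary label, and 4 informative
features shifted
for cases by `effect_size` (default 2) times the feature's own standard
deviation — so the population standardized mean difference equals
`effect_size` exactly, and features remain non-negative for any positive
skew. Noise features are class-independent draws from the same marginal.

What it does *not* emulate: correlated features, mixed scales/units,
missingness, label noise, or class-dependent variance — all present in
real clinical tables. Passing recovery tests on this generator shows the
pipeline finds planted, independent, moderately strong signals; it does
not certify performance on correlated or weak-signal data.

## Statistics harness

Algorithm comparisons use the paired Wilcoxon signed-rank test (two-sided,
zero differences dropped, mid-ranks for ties; exact enumeration of the
sign null for up to 12 nonzero pairs, normal approximation with tie and
continuity corrections beyond), Friedman mean ranks over problems (average
ranks on ties, with an explicit minimize/maximize orientation flag since
benchmark losses and accuracy-like metrics rank in opposite directions),
significance-gated win–tie–loss counts against a reference method, and
per-cell mean/standard-deviation summaries (n−1 denominator). Only mean
ranks are reported for the Friedman procedure — the quantity the
comparison tables actually display.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the optimizer at dimension
10 with a 20,000-evaluation budget over 15 seeds, binary exactness at 8
bits against exhaustive enumeration, and the end-to-end pipeline at 3
repeats of 10-fold selection on the default 300 x 36 generator — sizes
chosen so the full suite completes on a single CPU in minutes while still
exercising every moving part at realistic swarm settings.

## Known limitations

* The Sobol direction numbers cover 64 dimensions; higher-dimensional
  initialization errors out rather than silently degrading.
* The replacement strategy makes personal-best scores non-monotone by
  design; downstream code must not assume otherwise.
* FKNN stores the full training set; prediction is O(n) per query, which
  is fine at cohort scale but not for large n.
* The win–tie–loss gate inherits the Wilcoxon test's low power at small
  run counts; with fewer than ~6 runs per cell everything is a tie.
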