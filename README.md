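# swarmsel

Boosted particle swarm optimization and wrapper feature selection with a
fuzzy K-nearest-neighbor classifier, for tabular (clinical-style) data.

## What problem this solves

Wrapper feature selection asks: *which subset of measured variables lets a
classifier predict the outcome best, at the smallest subset size?* The
subset space is exponential, so a stochastic search has to drive it. This
package implements that stack end to end for practitioners working with
small clinical cohorts (a few hundred patients, a few dozen mixed-unit
laboratory features):

* **SRWPSO** — particle swarm optimization boosted by three cooperating
  strategies: Sobol low-discrepancy initialization (SOB), Cauchy-gated
  random replacement of personal bests (RRS), and an adaptive inertia
  weight (AWS). Each strategy is independently switchable, so all eight
  named ablation variants (PSO, SOBPSO, RRPSO, AWPSO, SRPSO, SWPSO,
  RWPSO, SRWPSO) are available from one driver.
* **bSRWPSO** — the binary variant: the same dynamics on the unit box,
  discretized through the V-shaped transfer `V(x) = |tanh(x)|` into
  per-dimension bit-flip probabilities.
* **FKNN** — fuzzy K-nearest neighbors, predicting graded class
  memberships by inverse-distance weighting with exponent `2/(m-1)`.
* **The wrapper pipeline** — bSRWPSO searches feature masks whose fitness
  is `0.99 * error + 0.01 * |mask|/D` (FKNN hold-out error plus a subset
  penalty), inside stratified cross-validation with strict train/test
  separation, repeated to produce per-feature selection-frequency counts.
* **A benchmark/statistics harness** — analytic benchmark objectives with
  a generic shift/rotate wrapper, a synthetic generator for skewed
  clinical-style tables, and the comparison statistics used in this
  literature (paired Wilcoxon signed-rank, Friedman mean ranks,
  significance-gated win–tie–loss counts, AVG/STD tables).

## The core update rules

Velocities follow the canonical form with clamp `Vmax`:

    V <- omega * V + c1*r1*(pB - X) + c2*r2*(gBest - X)

SRWPSO adds, per iteration: a replacement pass setting `pB[i,j] <- gBest[j]`
wherever `a < C` (with `a = 1 - FEs/MaxFEs` and `C` a fresh standard Cauchy
draw per dimension, `C = tan(pi*(U - 1/2))`), and the adaptive weight
`omega = (1 - FEs/MaxFEs)^beta`, `beta = 1 - C1*S/MaxFEs`, where `S` starts
at 0.01, halves when the global best improves and grows by 1 otherwise.
The binary variant flips bit `d` with probability `|tanh(x_d)|` after each
position update and evaluates fitness on the bit masks.

## Worked example

```r
library(swarmsel)

## optimize a 10-dimensional benchmark with and without the strategies
obj <- make_objective("rastrigin", 10)
cfg_pso <- swarm_config(dim = 10, max_evaluations = 20000, seed = 1,
                        use_sobol = FALSE, use_rrs = FALSE, use_aws = FALSE)
cfg_srw <- swarm_config(dim = 10, max_evaluations = 20000, seed = 1)
run_pso(obj, cfg_pso)
#> <swarm_result> best score 74.1357 after 20000 evaluations
run_srwpso(obj, cfg_srw)
#> <swarm_result> best score 0 after 20000 evaluations

## feature selection on a synthetic clinical-style cohort:
## 300 samples, 36 skewed features, 4 informative
ds <- generate_synthetic_classification(seed = 11)
rep <- run_feature_selection(ds, folds = 10, seed = 5)
rep
#> <selection_report> 1 repeat(s) x 10 folds, 36 features
#> mean accuracy 0.9733; top features: inf_1, inf_2, inf_3, inf_4, noise_10
sort(rep$selection_counts, decreasing = TRUE)[1:6]
#>    inf_1    inf_2    inf_3    inf_4 noise_10 noise_23
#>       10       10       10       10        5        5
```

The optimizer comparison shows what the three strategies buy on a
multimodal benchmark at a 20,000-evaluation budget (on these centered
base functions the Sobol initializer's box-center point already sits on
the optimum, so the boosted variant starts from an excellent position and
the canonical PSO does not). The selection report says the pipeline
classified held-out folds at 97% accuracy and selected every planted
informative feature in all 10 folds, twice as often as the most-selected
of the 32 noise features — the selection-frequency profile is how stably
relevant features are identified on real cohorts.

A command-line front end over the same functions is provided at
`inst/scripts/swarmsel-cli.R` with subcommands `optimize`, `benchmark`,
`synth` and `select`.

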