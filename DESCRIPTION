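Package: swarmsel
Title: Boosted Particle Swarm Optimization and Wrapper Feature Selection
    with Fuzzy K-Nearest Neighbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements SRWPSO, a particle swarm optimizer boosted by three
    cooperating strategies: Sobol low-discrepancy population initialization,
    Cauchy-gated random replacement of personal-best coordinates, and an
    adaptive inertia weight driven by a heavy-tailed perturbation of the
    linear decay schedule. A V-shaped binary variant (bSRWPSO) discretizes
    the dynamics for subset selection, and a wrapper pipeline couples it
    with a fuzzy K-nearest-neighbor classifier (FKNN) for feature selection
    on tabular clinical data. Includes an analytic benchmark-function suite
    with a generic shift/rotate wrapper, a synthetic generator for skewed
    clinical-style tables, cross-validated selection reports, and a
    benchmark/statistics harness (Wilcoxon signed-rank, Friedman mean
    ranks, win-tie-loss counting, AVG/STD tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
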