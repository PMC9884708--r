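test_that("swarm_config validates its invariants", {
  expect_error(swarm_config(dim = 3, population_size = 1), "population_size")
  expect_error(swarm_config(dim = 3, population_size = 10,
                            max_evaluations = 5), "max_evaluations")
  expect_error(swarm_config(dim = 0), "dim")
  expect_error(swarm_config(dim = 3, lower_bound = 1, upper_bound = 1),
               "lower_bound")
})

test_that("uniform initialization fills the box and is seed-deterministic", {
  cfg <- swarm_config(dim = 4, population_size = 50, max_evaluations = 100)
  set.seed(9); a <- init_random_population(cfg)
  set.seed(9); b <- init_random_population(cfg)
  expect_identical(a, b)
  expect_true(all(a >= -100 & a <= 100))
  # degenerate box collapses onto the lower bound
  eps <- 1e-12
  cfg2 <- swarm_config(dim = 2, population_size = 5, max_evaluations = 10,
                       lower_bound = 3, upper_bound = 3 + eps)
  expect_equal(init_random_population(cfg2),
               matrix(3, 5, 2), tolerance = 1e-9)
})

test_that("Cauchy sampler matches the inverse-CDF closed form", {
  expect_equal(swarmsel:::cauchy_from_uniform(0.5), 0)
  expect_equal(swarmsel:::cauchy_from_uniform(0.75), 1)
  expect_equal(swarmsel:::cauchy_from_uniform(0.25), -1)
  set.seed(21)
  x <- cauchy_sample(1e5)
  ks <- max(abs(ecdf(x)(sort(x)) - pcauchy(sort(x))))
  expect_lt(ks, 0.01)
})

test_that("decay factor is the linear schedule with endpoint values", {
  expect_equal(decay_factor(0, 300000), 1)
  expect_equal(decay_factor(300000, 300000), 0)
  expect_equal(decay_factor(150000, 300000), 0.5)
  expect_error(decay_factor(11, 10), "fes")
})

test_that("random replacement gates on the Cauchy draw", {
  g <- c(1, 2, 3)
  # identical vectors: replacement is invisible
  set.seed(2)
  expect_equal(random_replacement(g, g, 0.5), g)
  # a = 1 with all draws <= 1: untouched (tan singularity aside, force
  # the quantiles below 0.75 so every C <= 1)
  set.seed(4)
  p <- c(9, 9, 9)
  out <- replicate(200, random_replacement(p, g, 1))
  frac_rep <- mean(out != 9)
  expect_lt(frac_rep, 0.35)  # P(C > 1) = 0.25
  # a = 0: replacement probability is exactly P(C > 0) = 1/2
  set.seed(6)
  n <- 1e5
  out0 <- random_replacement(rep(9, n), rep(1, n), 0)
  phat <- mean(out0 == 1)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("adaptive parameter S halves on improvement, else increments", {
  expect_equal(update_S(0.01, TRUE), 0.005)
  expect_equal(update_S(0.01, FALSE), 1.01)
  expect_equal(update_S(4, TRUE), 2)
  expect_error(update_S(-1, TRUE), "s > 0")
})

test_that("adaptive weight honors its guards and limits", {
  set.seed(1)
  expect_equal(adaptive_weight(0, 1000, 0.01), 1)      # base 1 -> 1 always
  expect_equal(adaptive_weight(1000, 1000, 0.01), 0)   # base 0 -> 0 guard
  w <- replicate(500, adaptive_weight(400, 1000, 5))
  expect_true(all(w >= 0 & w <= 10))
  # with a tiny S the Cauchy perturbation is negligible: near-linear decay
  w2 <- replicate(50, adaptive_weight(250, 1e6, 1e-6))
  expect_true(all(abs(w2 - (1 - 250 / 1e6)) < 1e-3))
})

test_that("velocity update clamps and loses attraction at the consensus", {
  cfg <- swarm_config(dim = 3, population_size = 5, max_evaluations = 10)
  x <- c(1, 2, 3)
  set.seed(3)
  v <- velocity_update(c(10, -10, 2), x, x, x, omega = 1, cfg)
  expect_equal(v, c(6, -6, 2))  # attraction vanished, clamp at Vmax = 6
  v0 <- velocity_update(c(10, -10, 2), x, x, x, omega = 0, cfg)
  expect_equal(v0, c(0, 0, 0))
})

test_that("position update adds velocity and clamps to the box", {
  cfg <- swarm_config(dim = 1, population_size = 5, max_evaluations = 10)
  expect_equal(position_update(1, 0.5, cfg), 1.5)
  expect_equal(position_update(99, 6, cfg), 100)
  expect_equal(position_update(-99, -6, cfg), -100)
  expect_equal(position_update(42, 0, cfg), 42)
})

test_that("optimizer contracts hold across algorithms, objectives, seeds", {
  for (alg in c("pso", "srwpso")) {
    for (obj_name in c("sphere", "rastrigin")) {
      for (seed in 1:2) {
        obj <- make_objective(obj_name, 5)
        cfg <- swarm_config(dim = 5, population_size = 20,
                            max_evaluations = 1500, seed = seed)
        res <- if (alg == "pso") run_pso(obj, cfg) else run_srwpso(obj, cfg)
        expect_lte(res$evaluations_used, cfg$max_evaluations)
        expect_true(all(diff(res$trace$best_score) <= 0))
        expect_equal(res$trace$best_score[nrow(res$trace)], res$best_score)
        expect_true(all(res$best_position >= -100 & res$best_position <= 100))
        res2 <- if (alg == "pso") run_pso(obj, cfg) else run_srwpso(obj, cfg)
        expect_identical(res, res2)  # bitwise seed reproducibility
      }
    }
  }
})

test_that("canonical PSO solves the 2-d sphere to 1e-2", {
  scores <- sapply(1:10, function(s) {
    cfg <- swarm_config(dim = 2, population_size = 30,
                        max_evaluations = 5000, seed = s,
                        use_sobol = FALSE, use_rrs = FALSE, use_aws = FALSE)
    run_pso(make_objective("sphere", 2), cfg)$best_score
  })
  expect_lt(median(scores), 1e-2)
})

test_that("with all strategies off SRWPSO equals PSO step for step", {
  obj <- make_objective("sphere", 5)
  cfg <- swarm_config(dim = 5, population_size = 20, max_evaluations = 2000,
                      use_sobol = FALSE, use_rrs = FALSE, use_aws = FALSE,
                      seed = 77)
  a <- run_pso(obj, cfg)
  b <- run_srwpso(obj, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
  expect_identical(a$best_score, b$best_score)
})

test_that("the replacement pass doubles the per-iteration evaluations", {
  counter <- local({
    n <- 0L
    list(f = function(x) { n <<- n + 1L; sum(x^2) }, get = function() n)
  })
  obj <- objective_spec("counted", 3, counter$f)
  n_pop <- 10L
  cfg <- swarm_config(dim = 3, population_size = n_pop,
                      max_evaluations = n_pop + 4L * 2L * n_pop,
                      use_sobol = TRUE, use_rrs = TRUE, use_aws = TRUE,
                      seed = 5)
  res <- run_srwpso(obj, cfg)
  expect_equal(counter$get(), cfg$max_evaluations)
  expect_equal(res$evaluations_used, cfg$max_evaluations)
  # trace records a checkpoint after init and after each of the two
  # per-iteration evaluation passes of the replacement variant
  expect_equal(nrow(res$trace), 1L + 2L * 4L)
})

test_that("only the global best is monotone under random replacement", {
  # pB may worsen by design (diversity injection); gBest never does
  obj <- make_objective("rastrigin", 5)
  cfg <- swarm_config(dim = 5, population_size = 15, max_evaluations = 3000,
                      seed = 12)
  res <- run_srwpso(obj, cfg)
  expect_true(all(diff(res$trace$best_score) <= 0))
})
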