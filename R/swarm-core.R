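#' Swarm configuration
#'
#' Collects every run-time constant of the PSO/SRWPSO optimizers. Defaults
#' follow the published experimental setup: population 30, evaluation budget
#' 300,000, velocity clamp 6, learning factors 2/2, adaptive parameter
#' initialized at 0.01, and all three boosting strategies enabled.
#'
#' @param dim problem dimension.
#' @param population_size number of particles `N` (>= 2).
#' @param max_evaluations objective-evaluation budget `MaxFEs` (>= N).
#' @param v_max velocity clamp: every velocity component is kept in
#'   `[-v_max, v_max]`.
#' @param c1,c2 cognitive and social learning factors.
#' @param s_init initial value of the adaptive parameter `S` steering the
#'   inertia-weight perturbation (halved when the global best improves,
#'   incremented by 1 otherwise).
#' @param use_sobol,use_rrs,use_aws strategy switches: Sobol initialization,
#'   random replacement of personal bests, adaptive inertia weight. Turning
#'   all three off recovers canonical PSO dynamics.
#' @param lower_bound,upper_bound search-space box, scalar or per-dimension.
#' @param seed integer seed; identical configurations with identical seeds
#'   reproduce runs exactly.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(dim, population_size = 30, max_evaluations = 300000,
                         v_max = 6, c1 = 2, c2 = 2, s_init = 0.01,
                         use_sobol = TRUE, use_rrs = TRUE, use_aws = TRUE,
                         lower_bound = -100, upper_bound = 100, seed = NULL) {
  dim <- as.integer(dim)
  population_size <- as.integer(population_size)
  max_evaluations <- as.integer(max_evaluations)
  if (is.na(dim) || dim < 1L) stop("'dim' must be >= 1")
  if (is.na(population_size) || population_size < 2L)
    stop("'population_size' must be >= 2")
  if (is.na(max_evaluations) || max_evaluations < population_size)
    stop("'max_evaluations' must be >= population_size")
  stopifnot(v_max > 0, c1 >= 0, c2 >= 0, s_init > 0)
  lb <- rep_len(as.numeric(lower_bound), dim)
  ub <- rep_len(as.numeric(upper_bound), dim)
  if (any(!(lb < ub))) stop("lower_bound must be < upper_bound everywhere")
  structure(
    list(dim = dim, population_size = population_size,
         max_evaluations = max_evaluations, v_max = as.numeric(v_max),
         c1 = as.numeric(c1), c2 = as.numeric(c2), s_init = as.numeric(s_init),
         use_sobol = isTRUE(use_sobol), use_rrs = isTRUE(use_rrs),
         use_aws = isTRUE(use_aws), lower_bound = lb, upper_bound = ub,
         seed = seed),
    class = "swarm_config")
}

#' Uniform random population initialization
#'
#' Each entry is drawn independently and uniformly from the search box.
#'
#' @param config a [swarm_config()].
#' @return `N x dim` matrix of positions.
#' @export
init_random_population <- function(config) {
  n <- config$population_size; d <- config$dim
  u <- matrix(stats::runif(n * d), n, d)
  sweep(sweep(u, 2, config$upper_bound - config$lower_bound, "*"),
        2, config$lower_bound, "+")
}

#' Sobol population initialization
#'
#' Maps the first `N` Sobol points affinely onto the search box,
#' `X_i = lb + S_i * (ub - lb)`, giving a more evenly spread initial
#' population than pseudo-random sampling.
#'
#' @param config a [swarm_config()].
#' @return `N x dim` matrix of positions.
#' @export
init_sobol_population <- function(config) {
  s <- sobol_points(config$population_size, config$dim)
  sweep(sweep(s, 2, config$upper_bound - config$lower_bound, "*"),
        2, config$lower_bound, "+")
}

#' Standard Cauchy variate via the inverse-CDF map
#'
#' Draws `C = tan(pi * (U - 1/2))` with `U ~ Uniform(0,1)`; draws landing
#' exactly on the tangent singularity are redrawn.
#'
#' @param n number of variates.
#' @return Numeric vector of `n` standard Cauchy(0,1) draws.
#' @export
cauchy_sample <- function(n = 1) {
  u <- stats::runif(n)
  bad <- u == 0 | u == 1
  while (any(bad)) {
    u[bad] <- stats::runif(sum(bad))
    bad <- u == 0 | u == 1
  }
  tan(pi * (u - 0.5))
}

# Deterministic core of the sampler, exposed for tests that pin U.
cauchy_from_uniform <- function(u) tan(pi * (u - 0.5))

#' Linear decay factor
#'
#' The replacement-gating probability `a = 1 - FEs/MaxFEs`, decaying
#' linearly from 1 (start of the run) to 0 (budget exhausted).
#'
#' @param fes evaluations used so far.
#' @param max_fes evaluation budget.
#' @return Scalar in `[0, 1]`.
#' @export
decay_factor <- function(fes, max_fes) {
  stopifnot(max_fes > 0)
  if (fes < 0 || fes > max_fes) stop("'fes' must lie in [0, max_fes]")
  1 - fes / max_fes
}

#' Cauchy-gated random replacement of a personal best
#'
#' For each coordinate a fresh standard Cauchy draw `C` is taken; the
#' personal-best coordinate is replaced by the global-best coordinate
#' whenever `a < C`. Early in the run (`a` near 1) replacement is rare;
#' as `a` decays to 0 the replacement probability rises toward 1/2, pulling
#' personal bests toward the incumbent while the heavy Cauchy tail keeps
#' occasional replacement possible at any stage.
#'
#' @param pb_row personal-best position (numeric vector).
#' @param gbest global-best position (same length).
#' @param a decay factor in `[0, 1]` from [decay_factor()].
#' @return The hybridized personal-best vector.
#' @export
random_replacement <- function(pb_row, gbest, a) {
  stopifnot(length(pb_row) == length(gbest), a >= 0, a <= 1)
  cc <- cauchy_sample(length(pb_row))
  ifelse(a < cc, gbest, pb_row)
}

#' Adaptive parameter update
#'
#' The scalar `S` is halved whenever the evaluation just performed improved
#' the global best, and incremented by 1 otherwise. `S` feeds the
#' inertia-weight perturbation: long stagnation grows `S`, amplifying the
#' chance of a non-monotone inertia excursion.
#'
#' @param s current value (> 0).
#' @param improved logical: did the global best strictly improve?
#' @return Updated scalar.
#' @export
update_S <- function(s, improved) {
  stopifnot(s > 0)
  if (isTRUE(improved)) s / 2 else s + 1
}

#' Adaptive inertia weight
#'
#' Computes `omega = (1 - FEs/MaxFEs)^beta` with
#' `beta = 1 - C1 * S / MaxFEs`, `C1` a fresh standard Cauchy draw. With
#' `beta = 1` this is the plain linear decay from 1 to 0; the heavy-tailed
#' perturbation lets `omega` occasionally leave that trajectory. Guards:
#' a zero base (budget exhausted) yields `omega = 0` for any exponent; the
#' weight is computed in log space and capped at 10 so extreme `beta` draws
#' cannot overflow (the velocity clamp bounds their dynamical effect
#' regardless).
#'
#' @param fes evaluations used so far.
#' @param max_fes evaluation budget.
#' @param s current adaptive parameter `S`.
#' @return Scalar inertia weight in `[0, 10]`.
#' @export
adaptive_weight <- function(fes, max_fes, s) {
  stopifnot(s > 0)
  base <- decay_factor(fes, max_fes)
  c1 <- cauchy_sample(1)
  beta <- 1 - c1 * s / max_fes
  if (base == 0) return(0)
  w <- exp(beta * log(base))
  min(w, 10)
}

#' Velocity update
#'
#' `V' = omega * V + c1 * r1 * (pB - X) + c2 * r2 * (gBest - X)` with fresh
#' uniform draws `r1`, `r2` per dimension per term, then clamped to
#' `[-v_max, v_max]`. `omega = 1` recovers the canonical update.
#'
#' @param v_row,x_row,pb_row,gbest numeric vectors of equal length.
#' @param omega inertia weight.
#' @param config a [swarm_config()].
#' @return Updated, clamped velocity vector.
#' @export
velocity_update <- function(v_row, x_row, pb_row, gbest, omega, config) {
  d <- length(v_row)
  r1 <- stats::runif(d); r2 <- stats::runif(d)
  v <- omega * v_row + config$c1 * r1 * (pb_row - x_row) +
    config$c2 * r2 * (gbest - x_row)
  pmin(pmax(v, -config$v_max), config$v_max)
}

#' Position update
#'
#' `X' = X + V`, then clamped to the search box (components that leave the
#' box are set to the violated bound).
#'
#' @param x_row,v_row numeric vectors of equal length.
#' @param config a [swarm_config()].
#' @return Updated, clamped position vector.
#' @export
position_update <- function(x_row, v_row, config) {
  pmin(pmax(x_row + v_row, config$lower_bound), config$upper_bound)
}

# --- internal driver machinery ------------------------------------------

# Matrix-level velocity update sharing velocity_update's semantics: fresh
# r1/r2 per particle per dimension, column-major draw order.
.velocity_update_matrix <- function(V, X, pB, gbest, omega, config) {
  n <- nrow(V); d <- ncol(V)
  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  G <- matrix(gbest, n, d, byrow = TRUE)
  Vn <- omega * V + config$c1 * r1 * (pB - X) + config$c2 * r2 * (G - X)
  pmin(pmax(Vn, -config$v_max), config$v_max)
}

.clamp_rows <- function(X, config) {
  X <- pmax(X, matrix(config$lower_bound, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(config$upper_bound, nrow(X), ncol(X), byrow = TRUE))
}

.new_trace <- function() {
  env <- new.env(parent = emptyenv())
  env$fes <- numeric(0); env$score <- numeric(0)
  env
}

.record <- function(trace, fes, score) {
  trace$fes <- c(trace$fes, fes)
  trace$score <- c(trace$score, score)
}

.as_result <- function(gbest, gbest_score, trace, fes) {
  structure(
    list(best_position = gbest, best_score = gbest_score,
         trace = data.frame(fes = trace$fes, best_score = trace$score),
         evaluations_used = fes),
    class = "swarm_result")
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result> best score %.6g after %d evaluations\n",
              x$best_score, x$evaluations_used))
  invisible(x)
}

#' Canonical particle swarm optimization
#'
#' Runs the classic global-best PSO: a uniformly initialized swarm with zero
#' initial velocities, repeated evaluation of all particles with strict
#' personal/global best updates, then velocity and position updates under
#' the velocity clamp, until the evaluation budget is spent.
#'
#' @param objective an [objective_spec()] with `dim` equal to `config$dim`.
#' @param config a [swarm_config()]; the strategy flags are ignored here.
#' @return A `swarm_result`: best position and score found, a
#'   `(fes, best_score)` trace recorded after every evaluation batch, and
#'   the number of evaluations used.
#' @export
run_pso <- function(objective, config) {
  stopifnot(inherits(objective, "objective_spec"),
            inherits(config, "swarm_config"),
            objective$dim == config$dim)
  with_seed(config$seed, .run_pso_impl(objective, config))
}

.run_pso_impl <- function(objective, config) {
  n <- config$population_size; d <- config$dim
  max_fes <- config$max_evaluations
  X <- init_random_population(config)
  V <- matrix(0, n, d)
  pB <- matrix(0, n, d); pB_score <- rep(Inf, n)
  gbest <- rep(0, d); gbest_score <- Inf
  fes <- 0L
  trace <- .new_trace()
  while (fes < max_fes) {
    X <- .clamp_rows(X, config)
    for (i in seq_len(n)) {
      if (fes >= max_fes) break
      fit <- objective$evaluate(X[i, ])
      fes <- fes + 1L
      if (fit < pB_score[i]) { pB[i, ] <- X[i, ]; pB_score[i] <- fit }
      if (fit < gbest_score) { gbest <- X[i, ]; gbest_score <- fit }
    }
    .record(trace, fes, gbest_score)
    if (fes >= max_fes) break
    V <- .velocity_update_matrix(V, X, pB, gbest, 1, config)
    X <- .clamp_rows(X + V, config)
  }
  .as_result(gbest, gbest_score, trace, fes)
}

#' Boosted particle swarm optimization (SRWPSO)
#'
#' PSO augmented with three independently switchable strategies:
#' \itemize{
#'   \item \strong{Sobol initialization} (`use_sobol`): the initial swarm is a
#'     Sobol point set mapped onto the search box, improving early coverage.
#'   \item \strong{Random replacement} (`use_rrs`): before each velocity
#'     update pass, every personal best is hybridized coordinate-wise with
#'     the global best under a Cauchy-gated, linearly tightening probability,
#'     and the hybrid is (counted) re-evaluated; personal bests may worsen,
#'     which injects diversity — only the global best is monotone.
#'   \item \strong{Adaptive inertia weight} (`use_aws`): the inertia weight
#'     follows a perturbed decay `(1 - FEs/MaxFEs)^beta`, with the exponent
#'     driven by a Cauchy draw scaled by the stagnation counter `S`.
#' }
#' With all three flags off, the dynamics reduce step-for-step to
#' [run_pso()] under a shared random stream.
#'
#' @inheritParams run_pso
#' @return A `swarm_result`, as for [run_pso()].
#' @export
run_srwpso <- function(objective, config) {
  stopifnot(inherits(objective, "objective_spec"),
            inherits(config, "swarm_config"),
            objective$dim == config$dim)
  with_seed(config$seed, .run_srwpso_impl(objective, config))
}

.run_srwpso_impl <- function(objective, config) {
  n <- config$population_size; d <- config$dim
  max_fes <- config$max_evaluations
  X <- if (config$use_sobol) init_sobol_population(config)
       else init_random_population(config)
  V <- matrix(0, n, d)
  pB <- matrix(0, n, d); pB_score <- rep(Inf, n)
  gbest <- rep(0, d); gbest_score <- Inf
  S <- config$s_init
  fes <- 0L
  trace <- .new_trace()
  # initial evaluation pass
  X <- .clamp_rows(X, config)
  for (i in seq_len(n)) {
    if (fes >= max_fes) break
    fit <- objective$evaluate(X[i, ])
    fes <- fes + 1L
    if (fit < pB_score[i]) { pB[i, ] <- X[i, ]; pB_score[i] <- fit }
    if (fit < gbest_score) { gbest <- X[i, ]; gbest_score <- fit }
  }
  .record(trace, fes, gbest_score)
  while (fes < max_fes) {
    if (config$use_rrs) {
      # replacement pass: hybridize each personal best with the global best
      # and re-evaluate it (counted); pB_score may worsen by design.
      for (i in seq_len(n)) {
        if (fes >= max_fes) break
        a <- decay_factor(fes, max_fes)
        cand <- random_replacement(pB[i, ], gbest, a)
        cand <- position_update(cand, 0, config)  # keep in the search space
        fit <- objective$evaluate(cand)
        fes <- fes + 1L
        pB[i, ] <- cand; pB_score[i] <- fit
        if (fit < gbest_score) { gbest <- cand; gbest_score <- fit }
      }
      .record(trace, fes, gbest_score)
      if (fes >= max_fes) break
    }
    omega <- if (config$use_aws) adaptive_weight(fes, max_fes, S) else 1
    V <- .velocity_update_matrix(V, X, pB, gbest, omega, config)
    X <- .clamp_rows(X + V, config)
    for (i in seq_len(n)) {
      if (fes >= max_fes) break
      fit <- objective$evaluate(X[i, ])
      fes <- fes + 1L
      improved <- fit < gbest_score
      if (fit < pB_score[i]) { pB[i, ] <- X[i, ]; pB_score[i] <- fit }
      if (improved) { gbest <- X[i, ]; gbest_score <- fit }
      S <- update_S(S, improved)
    }
    .record(trace, fes, gbest_score)
  }
  .as_result(gbest, gbest_score, trace, fes)
}
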