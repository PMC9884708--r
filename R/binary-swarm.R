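#' V-shaped transfer function
#'
#' `V(x) = |tanh(x)|`, mapping a continuous coordinate to a bit-flip
#' probability in `[0, 1)`. Symmetric about 0 and monotone in `|x|`: a
#' coordinate near 0 leaves its bit alone, a large-magnitude coordinate
#' flips it with probability approaching 1.
#'
#' @param x numeric vector.
#' @return `|tanh(x)|`, elementwise.
#' @export
v_transfer <- function(x) abs(tanh(x))

#' One discretization step
#'
#' Advances a particle's bit mask from its continuous position: per
#' dimension a fresh `r ~ Uniform(0,1)` is drawn and the bit is
#' complemented when `r < V(x_d)`, kept otherwise. The flip probability of
#' dimension `d` is therefore exactly `v_transfer(x_d)`.
#'
#' @param mask integer 0/1 vector.
#' @param continuous_position numeric vector of the same length.
#' @return The advanced 0/1 mask.
#' @export
binarize_step <- function(mask, continuous_position) {
  stopifnot(length(mask) == length(continuous_position),
            all(mask %in% c(0L, 1L)))
  r <- stats::runif(length(mask))
  flip <- r < v_transfer(continuous_position)
  out <- as.integer(mask)
  out[flip] <- 1L - out[flip]
  out
}

#' Binary boosted particle swarm optimization (bSRWPSO)
#'
#' Subset-selection optimizer: the boosted PSO dynamics of [run_srwpso()]
#' run on the continuous box \eqn{[0,1]^D} while each particle carries a
#' persistent bit mask advanced by the V-shaped flip rule
#' ([binarize_step()]) after every position update. Fitness is always
#' evaluated on masks (lower is better); personal and global bests store
#' (mask, continuous position) pairs and are compared on mask fitness. The
#' random-replacement pass acts coordinate-wise on both representations of
#' the personal bests: a replaced dimension inherits the global best's
#' continuous coordinate and its bit, and the resulting mask is (counted)
#' re-evaluated.
#'
#' Runs are iteration-limited, as is conventional for wrapper feature
#' selection; the evaluation budget implied by
#' `population_size` and `iterations` drives the decay schedules.
#'
#' @param fitness function taking a 0/1 integer vector of length `d` and
#'   returning a finite scalar; lower is better.
#' @param d number of bits (problem dimension).
#' @param population_size swarm size (default 20).
#' @param iterations number of iterations (default 50).
#' @param v_max velocity clamp.
#' @param c1,c2 learning factors.
#' @param s_init initial adaptive parameter.
#' @param use_sobol,use_rrs,use_aws strategy switches, as in [swarm_config()].
#' @param seed integer seed for exact reproducibility.
#' @return A `binary_result`: `best_mask`, `best_fitness`, `selected_count`
#'   (number of set bits), a `(fes, best_fitness)` trace, and
#'   `evaluations_used`.
#' @export
run_bsrwpso <- function(fitness, d, population_size = 20, iterations = 50,
                        v_max = 6, c1 = 2, c2 = 2, s_init = 0.01,
                        use_sobol = TRUE, use_rrs = TRUE, use_aws = TRUE,
                        seed = NULL) {
  stopifnot(is.function(fitness))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("'d' must be >= 1")
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  per_iter <- if (isTRUE(use_rrs)) 2L * population_size else population_size
  config <- swarm_config(
    dim = d, population_size = population_size,
    max_evaluations = population_size + iterations * per_iter,
    v_max = v_max, c1 = c1, c2 = c2, s_init = s_init,
    use_sobol = use_sobol, use_rrs = use_rrs, use_aws = use_aws,
    lower_bound = 0, upper_bound = 1, seed = NULL)
  with_seed(seed, .run_bsrwpso_impl(fitness, config, iterations))
}

.run_bsrwpso_impl <- function(fitness, config, iterations) {
  n <- config$population_size; d <- config$dim
  max_fes <- config$max_evaluations
  X <- if (config$use_sobol) init_sobol_population(config)
       else init_random_population(config)
  V <- matrix(0, n, d)
  # initial masks: threshold the initial continuous coordinates
  M <- matrix(as.integer(X > 0.5), n, d)
  pB <- X; pB_mask <- M; pB_score <- rep(Inf, n)
  g_pos <- rep(0, d); g_mask <- rep(0L, d); g_score <- Inf
  S <- config$s_init
  fes <- 0L
  trace <- .new_trace()
  eval_mask <- function(i) {
    fit <- fitness(M[i, ])
    fes <<- fes + 1L
    improved <- fit < g_score
    if (fit < pB_score[i]) {
      pB[i, ] <<- X[i, ]; pB_mask[i, ] <<- M[i, ]; pB_score[i] <<- fit
    }
    if (improved) { g_pos <<- X[i, ]; g_mask <<- M[i, ]; g_score <<- fit }
    improved
  }
  for (i in seq_len(n)) eval_mask(i)
  .record(trace, fes, g_score)
  for (t in seq_len(iterations)) {
    if (config$use_rrs) {
      for (i in seq_len(n)) {
        a <- decay_factor(min(fes, max_fes), max_fes)
        # coordinate-wise replacement applied to both representations: a
        # replaced dimension inherits the global best's continuous
        # coordinate and its bit
        cc <- cauchy_sample(d)
        repl <- a < cc
        cand <- ifelse(repl, g_pos, pB[i, ])
        cand <- position_update(cand, 0, config)
        cand_mask <- ifelse(repl, g_mask, pB_mask[i, ])
        fit <- fitness(cand_mask)
        fes <- fes + 1L
        pB[i, ] <- cand; pB_mask[i, ] <- cand_mask; pB_score[i] <- fit
        if (fit < g_score) { g_pos <- cand; g_mask <- cand_mask; g_score <- fit }
      }
      .record(trace, fes, g_score)
    }
    omega <- if (config$use_aws) adaptive_weight(min(fes, max_fes), max_fes, S)
             else 1
    V <- .velocity_update_matrix(V, X, pB, g_pos, omega, config)
    X <- .clamp_rows(X + V, config)
    for (i in seq_len(n)) M[i, ] <- binarize_step(M[i, ], X[i, ])
    for (i in seq_len(n)) {
      improved <- eval_mask(i)
      S <- update_S(S, improved)
    }
    .record(trace, fes, g_score)
  }
  structure(
    list(best_mask = as.integer(g_mask), best_fitness = g_score,
         selected_count = sum(g_mask),
         trace = data.frame(fes = trace$fes, best_fitness = trace$score),
         evaluations_used = fes),
    class = "binary_result")
}

#' @export
print.binary_result <- function(x, ...) {
  cat(sprintf("<binary_result> best fitness %.6g, %d/%d bits set, %d evaluations\n",
              x$best_fitness, x$selected_count, length(x$best_mask),
              x$evaluations_used))
  invisible(x)
}
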