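#' Bounded continuous objective specification
#'
#' An `objective_spec` bundles a scalar-valued objective with its dimension,
#' box bounds, and (when known) the value of its global minimum. It is the
#' contract consumed by [run_pso()] and [run_srwpso()]; users can build their
#' own with [objective_spec()] to plug in arbitrary bounded functions.
#'
#' @param name identifier for the objective.
#' @param dim positive integer dimension.
#' @param evaluate function mapping a numeric vector of length `dim` to a
#'   single finite numeric value. Must be deterministic.
#' @param lower_bound,upper_bound scalar or length-`dim` numeric bounds;
#'   `lower_bound < upper_bound` componentwise.
#' @param known_optimum optional numeric: the global minimum of `evaluate`
#'   (before `bias`), used by tests and reporting; `NA` if unknown.
#' @param bias constant offset already included in `evaluate`'s output.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(name, dim, evaluate, lower_bound = -100,
                           upper_bound = 100, known_optimum = NA_real_,
                           bias = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("'dim' must be a positive integer")
  stopifnot(is.function(evaluate))
  lb <- rep_len(as.numeric(lower_bound), dim)
  ub <- rep_len(as.numeric(upper_bound), dim)
  if (any(!(lb < ub))) stop("lower_bound must be < upper_bound in every dimension")
  structure(
    list(name = name, dim = dim, evaluate = evaluate,
         lower_bound = lb, upper_bound = ub,
         known_optimum = as.numeric(known_optimum), bias = as.numeric(bias)),
    class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("<objective_spec> %s, dim = %d, bounds [%g, %g]",
              x$name, x$dim, x$lower_bound[1], x$upper_bound[1]))
  if (!is.na(x$known_optimum))
    cat(sprintf(", known optimum %g", x$known_optimum + x$bias))
  cat("\n")
  invisible(x)
}

# Analytic base forms underlying the common shifted/rotated benchmark
# families. All attain 0 at the origin (all-ones for rosenbrock).
.objective_registry <- list(
  sphere = function(x) sum(x^2),
  elliptic = function(x) {
    d <- length(x)
    # exponent (i-1)/(d-1); at d = 1 the 0/0 case is defined as weight 1
    w <- if (d == 1L) 1 else 1e6^((seq_len(d) - 1) / (d - 1))
    sum(w * x^2)
  },
  bent_cigar = function(x) x[1]^2 + 1e6 * sum(x[-1]^2),
  discus = function(x) 1e6 * x[1]^2 + sum(x[-1]^2),
  rosenbrock = function(x) {
    if (length(x) == 1L) return((x - 1)^2)
    d <- length(x)
    sum(100 * (x[-d]^2 - x[-1])^2 + (x[-d] - 1)^2)
  },
  ackley = function(x) {
    d <- length(x)
    -20 * exp(-0.2 * sqrt(sum(x^2) / d)) - exp(sum(cos(2 * pi * x)) / d) +
      20 + exp(1)
  },
  rastrigin = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
  griewank = function(x) {
    sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
  },
  # Schwefel 2.26 recentred so the minimum sits at the origin with value 0
  # (arguments shifted by the usual optimizer location 420.9687...).
  schwefel = function(x) {
    z <- x + 420.968746227722
    418.9828872724339 * length(x) - sum(z * sin(sqrt(abs(z))))
  }
)

#' Built-in analytic benchmark objectives
#'
#' Construct one of the analytic base functions the standard shifted/rotated
#' benchmark families are built from: `sphere`, `elliptic`, `bent_cigar`,
#' `discus`, `rosenbrock`, `ackley`, `rastrigin`, `griewank`, `schwefel`.
#' Every built-in has bounds \eqn{[-100, 100]^d} and known global minimum 0
#' (at the origin; at the all-ones point for `rosenbrock`).
#'
#' @param name one of the built-in names above.
#' @param dim positive integer dimension.
#' @return An [objective_spec()].
#' @examples
#' f <- make_objective("rastrigin", 2)
#' f$evaluate(c(1, 1))  # 2
#' @export
make_objective <- function(name, dim) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.objective_registry))
    stop("unknown objective '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(.objective_registry), collapse = ", "))
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("'dim' must be >= 1")
  objective_spec(name, dim, .objective_registry[[name]],
                 lower_bound = -100, upper_bound = 100, known_optimum = 0)
}

#' Shifted/rotated wrapper around a base objective
#'
#' Builds the composite \eqn{f(M (x - o)) + bias} used to derive shifted and
#' rotated benchmark instances from an analytic base form. The official
#' competition shift/rotation data files are not bundled; callers supply the
#' shift vector `o` and matrix `M` themselves (e.g. a random orthogonal
#' matrix).
#'
#' @param base an [objective_spec()].
#' @param shift numeric vector of length `base$dim`.
#' @param rotation `dim x dim` numeric matrix.
#' @param bias scalar offset added to the value.
#' @return A new [objective_spec()]; its `known_optimum` carries over
#'   (plus `bias`) when `rotation` is orthogonal, otherwise `NA`.
#' @export
shift_rotate <- function(base, shift, rotation, bias = 0) {
  stopifnot(inherits(base, "objective_spec"))
  d <- base$dim
  shift <- as.numeric(shift)
  if (length(shift) != d) stop("'shift' must have length ", d)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(d, d)))
    stop("'rotation' must be a ", d, "x", d, " matrix")
  orth <- max(abs(crossprod(rotation) - diag(d))) < 1e-8
  inner <- base$evaluate
  objective_spec(
    name = paste0(base$name, "_sr"), dim = d,
    evaluate = function(x) inner(drop(rotation %*% (x - shift))) + bias,
    lower_bound = base$lower_bound, upper_bound = base$upper_bound,
    known_optimum = if (orth) base$known_optimum else NA_real_,
    bias = base$bias + bias)
}

#' Names of the built-in benchmark objectives
#' @return Character vector of valid `name` arguments for [make_objective()].
#' @export
objective_names <- function() names(.objective_registry)
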