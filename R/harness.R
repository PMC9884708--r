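#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test as used for algorithm comparison:
#' zero differences are dropped, tied absolute differences receive
#' mid-ranks, and the p-value comes from exhaustive enumeration of all
#' sign assignments when at most 12 nonzero pairs remain (exact even under
#' ties), falling back to the normal approximation with tie correction and
#' continuity correction otherwise. If every difference is zero the
#' p-value is defined as 1.
#'
#' @param a,b paired numeric vectors of equal length (>= 5).
#' @return `list(statistic = W, p_value = p, n_nonzero = ...)` where `W` is
#'   the positive-rank sum after dropping zeros.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L))
  r <- rank(abs(d))  # mid-ranks for ties
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12) {
    # exact null: W under all 2^n equiprobable sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- drop(signs %*% r)
    p <- mean(abs(w_null - mu) >= abs(w - mu) - 1e-12)
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = w, p_value = p, n_nonzero = as.integer(n))
}

#' Benchmark comparison table
#'
#' Container for `methods x problems x runs` results from repeated
#' optimization runs; the unit consumed by [friedman_mean_ranks()],
#' [win_tie_loss()] and [summarize_avg_std()].
#'
#' @param results 3-d numeric array with `dimnames` for methods (1) and
#'   problems (2); the third extent is the per-cell run count.
#' @return An object of class `comparison_table`.
#' @export
comparison_table <- function(results) {
  results <- as.array(results)
  if (length(dim(results)) != 3L)
    stop("'results' must be a methods x problems x runs array")
  if (anyNA(results)) stop("'results' must be complete (no missing cells)")
  if (is.null(dimnames(results)[[1]]))
    dimnames(results)[[1]] <- paste0("method_", seq_len(dim(results)[1]))
  if (is.null(dimnames(results)[[2]]))
    dimnames(results)[[2]] <- paste0("problem_", seq_len(dim(results)[2]))
  structure(list(results = results,
                 methods = dimnames(results)[[1]],
                 problems = dimnames(results)[[2]],
                 runs = dim(results)[3]),
            class = "comparison_table")
}

#' Friedman mean ranks
#'
#' Ranks the methods within each problem by their mean over runs (ties get
#' average ranks) and returns each method's mean rank across problems.
#' Rank 1 is best; for `minimize = TRUE` lower values rank better, for
#' accuracy-like metrics use `minimize = FALSE`.
#'
#' @param table a [comparison_table()].
#' @param minimize logical orientation flag.
#' @return Named numeric vector of per-method mean ranks.
#' @export
friedman_mean_ranks <- function(table, minimize = TRUE) {
  stopifnot(inherits(table, "comparison_table"))
  res <- table$results
  if (dim(res)[1] < 2L || dim(res)[2] < 2L)
    stop("need at least 2 methods and 2 problems")
  means <- apply(res, c(1, 2), mean)
  ranks <- apply(means, 2, function(col) rank(if (minimize) col else -col))
  out <- rowMeans(ranks)
  names(out) <- table$methods
  out
}

#' Win–tie–loss counts against a reference method
#'
#' For each competitor and each problem, the reference wins (`+`) when its
#' run mean is better and the paired Wilcoxon signed-rank p-value over runs
#' is below `alpha`; loses (`-`) when its mean is worse with p below
#' `alpha`; otherwise the problem is a tie (`=`). Counts are summed over
#' problems.
#'
#' @param table a [comparison_table()].
#' @param reference method name used as the reference.
#' @param alpha significance level (default 0.05).
#' @param minimize logical: are smaller values better?
#' @return Data frame with columns `method`, `win`, `tie`, `loss`.
#' @export
win_tie_loss <- function(table, reference, alpha = 0.05, minimize = TRUE) {
  stopifnot(inherits(table, "comparison_table"))
  if (!reference %in% table$methods) stop("unknown reference method")
  res <- table$results
  comp <- setdiff(table$methods, reference)
  out <- lapply(comp, function(mth) {
    wins <- ties <- losses <- 0L
    for (p in table$problems) {
      ra <- res[reference, p, ]; rb <- res[mth, p, ]
      pv <- wilcoxon_signed_rank(ra, rb)$p_value
      better <- if (minimize) mean(ra) < mean(rb) else mean(ra) > mean(rb)
      worse <- if (minimize) mean(ra) > mean(rb) else mean(ra) < mean(rb)
      if (pv < alpha && better) wins <- wins + 1L
      else if (pv < alpha && worse) losses <- losses + 1L
      else ties <- ties + 1L
    }
    data.frame(method = mth, win = wins, tie = ties, loss = losses)
  })
  do.call(rbind, out)
}

#' Per-cell mean and standard deviation
#'
#' The AVG/STD summary of a benchmark table: sample mean and sample
#' standard deviation (n-1 denominator) of the runs in every
#' (method, problem) cell.
#'
#' @param table a [comparison_table()].
#' @return Data frame with columns `method`, `problem`, `avg`, `std`.
#' @export
summarize_avg_std <- function(table) {
  stopifnot(inherits(table, "comparison_table"))
  res <- table$results
  grid <- expand.grid(method = table$methods, problem = table$problems,
                      stringsAsFactors = FALSE)
  grid$avg <- mapply(function(m, p) mean(res[m, p, ]),
                     grid$method, grid$problem)
  grid$std <- mapply(function(m, p) stats::sd(res[m, p, ]),
                     grid$method, grid$problem)
  grid
}

#' Synthetic clinical-style classification data
#'
#' Generates a tabular dataset emulating a small clinical cohort: `n`
#' samples, `D` non-negative continuous features with heavy right skew
#' (log-normal), a binary class label, and a planted subset of informative
#' features. Informative features are shifted for one class by
#' `effect_size` times their own standard deviation, so the population
#' standardized mean difference equals `effect_size` exactly; the
#' remaining features are class-independent noise.
#'
#' @param n_samples number of rows (default 300).
#' @param n_features number of features (default 36).
#' @param n_informative number of class-informative features (default 4);
#'   these are the first `n_informative` columns, named `inf_*`.
#' @param effect_size class-mean shift in SD units (default 2).
#' @param skew log-normal shape: features are `exp(skew * Z)` with
#'   `Z ~ N(0,1)` (default 0.5, strong right skew — marginal skewness
#'   about 1.75 — while keeping sample moments stable enough that the
#'   planted standardized effect is recoverable at cohort size).
#'   `skew = 0` yields standard-normal features (then possibly negative).
#' @param class_balance probability of class `"case"` (default 0.5).
#' @param seed integer seed.
#' @return A [feature_dataset()] with labels `"case"` / `"control"`
#'   (`"case"` is the first-appearing, positive class) and feature names
#'   `inf_1..` / `noise_1..`.
#' @export
generate_synthetic_classification <- function(n_samples = 300,
                                              n_features = 36,
                                              n_informative = 4,
                                              effect_size = 2,
                                              skew = 0.5,
                                              class_balance = 0.5,
                                              seed = NULL) {
  stopifnot(n_samples >= 4, n_features >= 1,
            n_informative >= 0, n_informative <= n_features,
            skew >= 0, class_balance > 0, class_balance < 1)
  with_seed(seed, {
    y <- stats::rbinom(n_samples, 1, class_balance)  # 1 = case
    z <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    x <- if (skew > 0) exp(skew * z) else z
    pop_sd <- if (skew > 0) sqrt((exp(skew^2) - 1) * exp(skew^2)) else 1
    if (n_informative > 0) {
      shift <- effect_size * pop_sd
      x[y == 1, seq_len(n_informative)] <-
        x[y == 1, seq_len(n_informative), drop = FALSE] + shift
    }
    nm <- c(if (n_informative > 0) paste0("inf_", seq_len(n_informative)),
            if (n_features > n_informative)
              paste0("noise_", seq_len(n_features - n_informative)))
    labels <- ifelse(y == 1, "case", "control")
    # ensure "case" appears first so it is class index 1 (the positive class)
    first_case <- which(y == 1)[1]
    if (is.na(first_case)) stop("degenerate draw: a single class; reseed")
    if (first_case != 1) {
      ord <- c(first_case, setdiff(seq_len(n_samples), first_case))
      x <- x[ord, , drop = FALSE]; labels <- labels[ord]
    }
    feature_dataset(x, labels, feature_names = nm)
  })
}

#' Load a classification dataset from CSV
#'
#' Reads a header-ed CSV whose columns are numeric features plus one label
#' column. Labels are mapped to class indices in first-appearance order;
#' missing values and non-numeric feature cells are rejected with an error
#' naming the offending column.
#'
#' @param path CSV file path.
#' @param label_column name of the label column (default: last column).
#' @return A [feature_dataset()].
#' @export
load_dataset_csv <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("need at least one feature column plus a label")
  if (is.null(label_column)) label_column <- names(df)[ncol(df)]
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not present")
  labels <- df[[label_column]]
  feats <- df[names(df) != label_column]
  for (nm in names(feats)) {
    v <- feats[[nm]]
    if (anyNA(v)) stop("missing value in column '", nm, "' (row ",
                       which(is.na(v))[1], ")")
    if (!is.numeric(v)) stop("non-numeric feature column '", nm, "'")
  }
  if (anyNA(labels)) stop("missing value in label column")
  feature_dataset(as.matrix(feats), labels, feature_names = names(feats))
}

#' Run a PSO-vs-SRWPSO benchmark
#'
#' Convenience driver: runs each requested algorithm on each named built-in
#' objective for `runs` seeded repetitions and returns the final scores as
#' a [comparison_table()] (plus the traces).
#'
#' @param objectives character vector of [make_objective()] names.
#' @param algorithms subset of `c("pso", "srwpso")`.
#' @param dim problem dimension.
#' @param runs seeded repetitions per cell.
#' @param max_fes evaluation budget per run.
#' @param population_size swarm size.
#' @param seed master seed; run `r` of each cell uses a derived stream.
#' @return `list(table = comparison_table, traces = nested list)`.
#' @export
run_benchmark <- function(objectives, algorithms = c("pso", "srwpso"),
                          dim = 10, runs = 15, max_fes = 20000,
                          population_size = 30, seed = 1) {
  algorithms <- match.arg(algorithms, c("pso", "srwpso"), several.ok = TRUE)
  res <- array(NA_real_, c(length(algorithms), length(objectives), runs),
               dimnames = list(algorithms, objectives, NULL))
  traces <- list()
  for (ai in seq_along(algorithms)) {
    for (oi in seq_along(objectives)) {
      obj <- make_objective(objectives[oi], dim)
      for (r in seq_len(runs)) {
        cfg <- swarm_config(
          dim = dim, population_size = population_size,
          max_evaluations = max_fes,
          use_sobol = algorithms[ai] == "srwpso",
          use_rrs = algorithms[ai] == "srwpso",
          use_aws = algorithms[ai] == "srwpso",
          seed = derive_seed(seed, (ai * 1000L + oi) * 100L + r))
        out <- if (algorithms[ai] == "pso") run_pso(obj, cfg)
               else run_srwpso(obj, cfg)
        res[ai, oi, r] <- out$best_score
        traces[[paste(algorithms[ai], objectives[oi], r, sep = "_")]] <-
          out$trace
      }
    }
  }
  list(table = comparison_table(res), traces = traces)
}
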