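#' Tabular classification dataset container
#'
#' @param features `n x D` numeric matrix (no missing values).
#' @param labels length-`n` class labels; stored as integer indices `1..C`
#'   in first-appearance order, with the original values kept in `classes`.
#' @param feature_names optional length-`D` character vector.
#' @return An object of class `feature_dataset`.
#' @export
feature_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features)) stop("'features' contains missing values")
  n <- nrow(features)
  if (length(labels) != n) stop("'labels' length must match nrow(features)")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names))
      feature_names <- paste0("feature_", seq_len(ncol(features)))
  }
  stopifnot(length(feature_names) == ncol(features))
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = match(labels, classes),
         classes = classes, feature_names = feature_names),
    class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> n = %d, D = %d, %d classes\n",
              nrow(x$features), ncol(x$features), length(x$classes)))
  invisible(x)
}

#' Wrapper feature-selection fitness
#'
#' `Fitness = alpha * Error + beta * R / D` with `beta = 1 - alpha` and
#' `alpha = 0.99` by default: classification error dominates, with a small
#' penalty proportional to the fraction of retained features. An empty
#' subset (`R = 0`) returns the sentinel value 1 — the worst attainable
#' fitness — so the optimizer can never settle on selecting nothing.
#'
#' @param error_rate classification error in `[0, 1]`.
#' @param r number of selected features, `0 <= r <= d`.
#' @param d total number of candidate features.
#' @param alpha weight of the error term (default 0.99).
#' @return Scalar fitness; lower is better.
#' @export
fitness_eval <- function(error_rate, r, d, alpha = 0.99) {
  stopifnot(d >= 1, alpha >= 0, alpha <= 1)
  if (is.na(error_rate) || error_rate < 0 || error_rate > 1)
    stop("'error_rate' must lie in [0, 1]")
  if (r < 0 || r > d) stop("'r' must lie in [0, d]")
  if (r == 0) return(1)
  alpha * error_rate + (1 - alpha) * r / d
}

#' Classification metrics from a confusion matrix
#'
#' Computes Accuracy, Sensitivity (recall of the positive class), the
#' Matthews correlation coefficient, and the F-measure
#' `TP / (TP + (FN + FP)/2)` from binary confusion counts. An MCC whose
#' denominator vanishes (a degenerate margin) is defined as 0; Sensitivity
#' and F-measure with zero denominators are likewise 0.
#'
#' @param tp,fp,fn,tn non-negative integer counts, not all zero.
#' @return A `metrics_report` list: `accuracy`, `sensitivity`, `mcc`,
#'   `f_measure`, and `confusion = c(tp, fp, fn, tn)`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop("confusion counts are all zero")
  tp <- as.double(tp); fp <- as.double(fp)
  fn <- as.double(fn); tn <- as.double(tn)
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  f_den <- tp + (fn + fp) / 2
  f_measure <- if (f_den > 0) tp / f_den else 0
  structure(
    list(accuracy = accuracy, sensitivity = sensitivity, mcc = mcc,
         f_measure = f_measure, confusion = counts),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.4f, sensitivity %.4f, MCC %.4f, F %.4f\n",
    x$accuracy, x$sensitivity, x$mcc, x$f_measure))
  invisible(x)
}

#' Stratified k-fold split
#'
#' Splits indices into `folds` disjoint test sets covering all samples,
#' with each class's members spread so per-class counts differ by at most
#' one across folds.
#'
#' @param labels class labels (any type).
#' @param folds number of folds.
#' @param seed integer seed for the within-class shuffles.
#' @return List of `folds` elements, each `list(train = ..., test = ...)`
#'   of integer indices.
#' @export
stratified_kfold <- function(labels, folds, seed = NULL) {
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  y <- match(labels, unique(labels))
  sizes <- tabulate(y)
  if (any(sizes < folds))
    stop("every class needs at least ", folds, " members; smallest has ",
         min(sizes))
  with_seed(seed, {
    assign_fold <- integer(length(y))
    for (c in seq_along(sizes)) {
      idx <- sample(which(y == c))
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    lapply(seq_len(folds), function(f) {
      test <- which(assign_fold == f)
      list(train = setdiff(seq_along(y), test), test = test)
    })
  })
}

# Min-max scaler fitted on training rows only; constant columns map to 0.
.fit_scaler <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

.apply_scaler <- function(scaler, x) {
  pmin(pmax(sweep(sweep(x, 2, scaler$lo, "-"), 2, scaler$rng, "/"), 0), 1)
}

# Batch FKNN class prediction (internal fast path for the pipeline).
.fknn_predict_batch <- function(model, queries) {
  Xt <- model$train_points
  d2 <- outer(rowSums(queries^2), rowSums(Xt^2), "+") -
    2 * queries %*% t(Xt)
  d2[d2 < 0] <- 0
  mem <- model$memberships
  k <- model$k
  expo <- -1 / (model$m - 1)
  out <- integer(nrow(queries))
  for (q in seq_len(nrow(queries))) {
    dq <- d2[q, ]
    exact <- which(dq == 0)
    if (length(exact) > 0) {
      mu <- rowMeans(mem[, exact, drop = FALSE])
    } else {
      nb <- order(dq)[seq_len(k)]
      w <- dq[nb]^expo
      if (any(!is.finite(w))) w <- as.numeric(!is.finite(w))
      mu <- drop(mem[, nb, drop = FALSE] %*% w) / sum(w)
    }
    out[q] <- which.max(mu)
  }
  out
}

# Misclassification count of a crisp FKNN over fixed inner splits on the
# masked feature columns. Identical predictions to fknn_fit +
# .fknn_predict_batch with crisp memberships, but fully vectorized: one
# GEMM per split for the masked distances (cost scales with |mask|, not D)
# and k passes of max.col for the neighbor extraction, so wrapper fitness
# evaluation stays cheap. Queries with exact matches or non-finite weights
# fall back to the per-query path.
.inner_cv_error <- function(X, cols, splits, y, k, m, n_classes) {
  expo <- -1 / (m - 1)
  wrong <- 0L; total <- 0L
  for (sp in splits) {
    A <- X[sp$test, cols, drop = FALSE]
    B <- X[sp$train, cols, drop = FALSE]
    D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    D2[D2 < 0] <- 0
    ylab <- y[sp$train]; yte <- y[sp$test]
    nq <- nrow(D2); kk <- min(k, ncol(D2))
    rows <- seq_len(nq)
    has_zero <- rowSums(D2 == 0) > 0
    W <- D2
    idxs <- matrix(0L, nq, kk); wts <- matrix(0, nq, kk)
    for (j in seq_len(kk)) {
      idx <- max.col(-W, ties.method = "first")  # stable nearest-first
      idxs[, j] <- idx
      wts[, j] <- W[cbind(rows, idx)]^expo
      W[cbind(rows, idx)] <- Inf
    }
    bad <- has_zero | rowSums(!is.finite(wts)) > 0
    ok <- which(!bad)
    pred <- integer(nq)
    if (length(ok)) {
      scores <- matrix(0, length(ok), n_classes)
      oi <- seq_along(ok)
      for (j in seq_len(kk)) {
        cls <- ylab[idxs[ok, j]]
        ij <- cbind(oi, cls)
        scores[ij] <- scores[ij] + wts[ok, j]
      }
      pred[ok] <- max.col(scores, ties.method = "first")
    }
    for (q in which(bad)) {
      dq <- D2[q, ]
      sc <- numeric(n_classes)
      if (any(dq == 0)) {
        tb <- tabulate(ylab[dq == 0], nbins = n_classes)
        sc <- tb / sum(tb)
      } else {
        nb <- order(dq)[seq_len(kk)]
        w <- dq[nb]^expo
        if (any(!is.finite(w))) w <- as.numeric(!is.finite(w))
        for (j in seq_len(kk)) sc[ylab[nb[j]]] <- sc[ylab[nb[j]]] + w[j]
      }
      pred[q] <- which.max(sc)
    }
    wrong <- wrong + sum(pred != yte)
    total <- total + nq
  }
  wrong / total
}

# One-vs-rest confusion counts for the designated positive class.
.confusion_counts <- function(truth, pred, positive) {
  c(tp = sum(pred == positive & truth == positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive),
    tn = sum(pred != positive & truth != positive))
}

#' Wrapper feature selection with bSRWPSO and FKNN (one repeat)
#'
#' For each outer cross-validation fold: a min–max scaler is fitted on the
#' training partition only; a fixed, seeded inner resampling of the
#' training partition defines the fitness of a mask as
#' `fitness_eval(inner error of FKNN on the masked features, |mask|, D)`;
#' [run_bsrwpso()] searches the mask space; the winning mask's FKNN is
#' refitted on the full training partition and scored once on the untouched
#' outer test fold. Outer-test rows never reach any fitness evaluation or
#' scaler fit.
#'
#' The inner error is a stratified `inner_folds`-fold cross-validation
#' estimate (every training point predicted exactly once), which resolves
#' error differences at the granularity of single samples; with
#' `inner_folds = 1` a single stratified hold-out of `holdout_fraction` is
#' used instead — cheaper, but its coarser error quantum leaves more
#' fitness ties, which lets uninformative features ride along in winning
#' masks.
#'
#' @param dataset a [feature_dataset()].
#' @param folds number of outer folds (default 10).
#' @param population_size,iterations swarm settings (defaults 20 / 50).
#' @param k,m FKNN neighbor count and fuzzy strength (defaults 5 / 2).
#' @param alpha fitness weight of the error term (default 0.99).
#' @param inner_folds folds of the inner cross-validated error estimate
#'   (default 3); `1` switches to a single stratified hold-out.
#' @param holdout_fraction inner hold-out fraction when `inner_folds = 1`
#'   (default 0.2).
#' @param positive_class index (in first-appearance order) of the class
#'   treated as positive for sensitivity/MCC/F-measure (default 1).
#' @param use_sobol,use_rrs,use_aws strategy switches for the swarm.
#' @param seed integer seed; the per-fold searches and splits derive their
#'   streams from it.
#' @return A `selection_report`: `selection_counts` (per-feature selection
#'   counts), `per_fold_masks` (`folds x D` 0/1 matrix), `per_fold_metrics`
#'   (data frame with one row per fold), `repeats = 1`, `folds`,
#'   `feature_names`.
#' @export
run_feature_selection <- function(dataset, folds = 10, population_size = 20,
                                  iterations = 50, k = 5, m = 2,
                                  alpha = 0.99, inner_folds = 3,
                                  holdout_fraction = 0.2,
                                  positive_class = 1L,
                                  use_sobol = TRUE, use_rrs = TRUE,
                                  use_aws = TRUE, seed = NULL) {
  inner_folds <- as.integer(inner_folds)
  stopifnot(inner_folds >= 1L)
  stopifnot(inherits(dataset, "feature_dataset"))
  X <- dataset$features; y <- dataset$labels
  D <- ncol(X)
  splits <- stratified_kfold(y, folds, seed = derive_seed(seed %||% 0, 1L))
  masks <- matrix(0L, folds, D, dimnames = list(NULL, dataset$feature_names))
  metrics <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- splits[[f]]$train; te <- splits[[f]]$test
    scaler <- .fit_scaler(X[tr, , drop = FALSE])
    Xtr <- .apply_scaler(scaler, X[tr, , drop = FALSE])
    Xte <- .apply_scaler(scaler, X[te, , drop = FALSE])
    ytr <- y[tr]; yte <- y[te]
    # fixed, seeded inner resampling of the training partition
    inner_seed <- derive_seed(seed %||% 0, 100L + f)
    if (inner_folds >= 2L) {
      inner_splits <- stratified_kfold(ytr, inner_folds, seed = inner_seed)
    } else {
      hold <- with_seed(inner_seed, {
        unlist(lapply(unique(ytr), function(cl) {
          idx <- which(ytr == cl)
          sample(idx, max(1L, round(holdout_fraction * length(idx))))
        }))
      })
      inner_splits <- list(list(train = setdiff(seq_along(ytr), hold),
                                test = hold))
    }
    n_classes <- length(unique(y))
    cache <- new.env(parent = emptyenv())
    fitness <- function(mask) {
      r <- sum(mask)
      if (r == 0) return(fitness_eval(1, 0L, D, alpha))
      key <- paste(mask, collapse = "")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      err <- .inner_cv_error(Xtr, which(mask == 1L), inner_splits, ytr,
                             k, m, n_classes)
      val <- fitness_eval(err, r, D, alpha)
      cache[[key]] <- val
      val
    }
    res <- run_bsrwpso(fitness, D, population_size = population_size,
                       iterations = iterations,
                       use_sobol = use_sobol, use_rrs = use_rrs,
                       use_aws = use_aws,
                       seed = derive_seed(seed %||% 0, 200L + f))
    masks[f, ] <- res$best_mask
    cols <- which(res$best_mask == 1L)
    mod <- fknn_fit(Xtr[, cols, drop = FALSE], ytr, k = min(k, nrow(Xtr)),
                    m = m)
    pred <- mod$classes[.fknn_predict_batch(mod, Xte[, cols, drop = FALSE])]
    cm <- .confusion_counts(yte, pred, positive_class)
    mr <- confusion_metrics(cm["tp"], cm["fp"], cm["fn"], cm["tn"])
    metrics[[f]] <- data.frame(
      fold = f, accuracy = mr$accuracy, sensitivity = mr$sensitivity,
      mcc = mr$mcc, f_measure = mr$f_measure,
      n_selected = length(cols), fitness = res$best_fitness)
  }
  structure(
    list(selection_counts = colSums(masks), per_fold_masks = masks,
         per_fold_metrics = do.call(rbind, metrics), repeats = 1L,
         folds = folds, feature_names = dataset$feature_names),
    class = "selection_report")
}

#' Repeated cross-validated feature-selection counts
#'
#' Repeats [run_feature_selection()] with reseeded streams and aggregates:
#' `selection_counts[d]` is the number of the `repeats * folds` fold-level
#' searches whose winning mask included feature `d` — the selection-
#' frequency profile used to identify stably informative features.
#'
#' @param dataset a [feature_dataset()].
#' @param repeats number of repeats (default 10).
#' @param seed integer master seed.
#' @param ... further arguments passed to [run_feature_selection()].
#' @return A `selection_report` aggregated over all repeats; the metrics
#'   data frame gains a `repeat.` column.
#' @export
repeated_selection_counts <- function(dataset, repeats = 10, seed = NULL,
                                      ...) {
  repeats <- as.integer(repeats)
  stopifnot(repeats >= 1L)
  reports <- lapply(seq_len(repeats), function(r) {
    run_feature_selection(dataset, seed = derive_seed(seed %||% 0, 7000L + r),
                          ...)
  })
  masks <- do.call(rbind, lapply(reports, `[[`, "per_fold_masks"))
  metrics <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    cbind(repeat. = r, reports[[r]]$per_fold_metrics)
  }))
  structure(
    list(selection_counts = colSums(masks), per_fold_masks = masks,
         per_fold_metrics = metrics, repeats = repeats,
         folds = reports[[1]]$folds, feature_names = dataset$feature_names),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d repeat(s) x %d folds, %d features\n",
              x$repeats, x$folds, length(x$selection_counts)))
  cat(sprintf("mean accuracy %.4f; top features: %s\n",
              mean(x$per_fold_metrics$accuracy),
              paste(names(sort(x$selection_counts, decreasing = TRUE))[1:min(5, length(x$selection_counts))],
                    collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
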