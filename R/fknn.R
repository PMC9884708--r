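#' Fit a fuzzy K-nearest-neighbor classifier
#'
#' FKNN generalizes KNN by giving every training point a membership degree
#' in each class and predicting graded memberships for queries. Two
#' initialization schemes are offered: `"crisp"` (one-hot by label) and
#' `"neighborhood"` (Keller-style: a point's own-class membership is
#' `0.51 + 0.49 * f`, where `f` is the fraction of its `k` nearest
#' training neighbors sharing its label, and each other class gets
#' `0.49 *` its neighbor fraction).
#'
#' @param points `n x D` numeric matrix of training features.
#' @param labels length-`n` vector of class labels; coerced to integer
#'   indices `1..C` in first-appearance order.
#' @param k number of neighbors, `1 <= k <= n`.
#' @param m fuzzy strength, `m > 1`; larger `m` flattens the
#'   inverse-distance weights (exponent `2/(m-1)`).
#' @param init_scheme `"crisp"` or `"neighborhood"`.
#' @return An object of class `fknn` with fields `train_points`,
#'   `train_labels`, `memberships` (`C x n`, columns sum to 1), `k`, `m`,
#'   and `classes` (the original label values).
#' @export
fknn_fit <- function(points, labels, k = 5, m = 2,
                     init_scheme = c("crisp", "neighborhood")) {
  init_scheme <- match.arg(init_scheme)
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(labels) != n) stop("'labels' length must match nrow(points)")
  classes <- unique(labels)
  y <- match(labels, classes)
  C <- length(classes)
  if (C < 2L) stop("need at least 2 classes")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1")
  if (k > n) stop("'k' (", k, ") exceeds the number of training points (", n, ")")
  if (!(m > 1)) stop("'m' must be > 1")
  mem <- matrix(0, C, n)
  if (init_scheme == "crisp") {
    mem[cbind(y, seq_len(n))] <- 1
  } else {
    dd <- as.matrix(stats::dist(points))
    diag(dd) <- Inf  # a point is not its own neighbor
    kk <- min(k, n - 1L)
    for (j in seq_len(n)) {
      nb <- order(dd[, j])[seq_len(kk)]  # stable order breaks distance ties
      frac <- tabulate(y[nb], nbins = C) / kk
      mem[, j] <- 0.49 * frac
      mem[y[j], j] <- mem[y[j], j] + 0.51
    }
    mem <- sweep(mem, 2, colSums(mem), "/")
  }
  structure(
    list(train_points = points, train_labels = y, memberships = mem,
         k = k, m = m, classes = classes),
    class = "fknn")
}

#' Predict class memberships for a query point
#'
#' Implements the fuzzy membership rule: the query's membership in class
#' `i` is the inverse-distance-weighted average of its `k` nearest
#' training points' memberships,
#' \deqn{\mu_i(x) = \frac{\sum_{j=1}^{k} \mu_{ij} \, \|x - x_j\|^{-2/(m-1)}}
#'                       {\sum_{j=1}^{k} \|x - x_j\|^{-2/(m-1)}},}
#' with Euclidean distances. If the query coincides exactly with one or
#' more training points, their membership columns are averaged and
#' returned (the zero-distance limit concentrates all weight there).
#'
#' @param model an [fknn_fit()] object.
#' @param query numeric vector of length `D`.
#' @return Numeric membership vector of length `C`, summing to 1.
#' @export
fknn_memberships <- function(model, query) {
  stopifnot(inherits(model, "fknn"))
  query <- as.numeric(query)
  if (length(query) != ncol(model$train_points))
    stop("'query' must have length ", ncol(model$train_points))
  dd <- sqrt(colSums((t(model$train_points) - query)^2))
  exact <- which(dd == 0)
  if (length(exact) > 0)
    return(rowMeans(model$memberships[, exact, drop = FALSE]))
  nb <- order(dd)[seq_len(model$k)]  # stable tie-break at the k-th distance
  w <- dd[nb]^(-2 / (model$m - 1))
  if (any(!is.finite(w))) {  # astronomically close neighbors: hard limit
    w <- as.numeric(!is.finite(w))
  }
  drop(model$memberships[, nb, drop = FALSE] %*% w) / sum(w)
}

#' Predict the class of query points
#'
#' Assigns each query the class with maximal fuzzy membership; exact ties
#' go to the lowest class index (first-appearance order of the training
#' labels).
#'
#' @param object an [fknn_fit()] model.
#' @param newdata numeric vector (one query) or matrix (one query per row).
#' @param type `"class"` for labels (original values), `"membership"` for
#'   the membership matrix (one row per query).
#' @param ... unused.
#' @return Predicted labels, or a memberships matrix.
#' @export
predict.fknn <- function(object, newdata, type = c("class", "membership"),
                         ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  mem <- t(apply(newdata, 1, function(q) fknn_memberships(object, q)))
  if (type == "membership") return(mem)
  idx <- apply(mem, 1, which.max)  # which.max takes the first maximum
  object$classes[idx]
}

#' @export
print.fknn <- function(x, ...) {
  cat(sprintf("<fknn> n = %d, D = %d, C = %d classes, k = %d, m = %g\n",
              nrow(x$train_points), ncol(x$train_points),
              length(x$classes), x$k, x$m))
  invisible(x)
}
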