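# Independent oracles used across the suite. These deliberately use naive
# loop-based formulations, separate from the package's vectorized paths.

# Direct loop evaluation of the fuzzy membership rule: inverse-distance
# weights with exponent 2/(m-1) over the k nearest training points.
oracle_fknn_memberships <- function(train, labels, k, m, query) {
  n <- nrow(train)
  C <- max(labels)
  d <- numeric(n)
  for (j in seq_len(n)) d[j] <- sqrt(sum((query - train[j, ])^2))
  nb <- order(d)[seq_len(k)]
  num <- numeric(C); den <- 0
  for (j in nb) {
    w <- 1 / d[j]^(2 / (m - 1))
    mem <- as.numeric(seq_len(C) == labels[j])  # crisp memberships
    num <- num + mem * w
    den <- den + w
  }
  num / den
}

oracle_1nn <- function(train, labels, query) {
  d <- apply(train, 1, function(r) sqrt(sum((r - query)^2)))
  labels[which.min(d)]
}

# Exhaustive-enumeration null for the paired signed-rank statistic.
oracle_wilcoxon_exact <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  total <- 2^n
  count <- 0
  for (bits in 0:(total - 1)) {
    signs <- as.integer(intToBits(bits))[1:n]
    wn <- sum(r[signs == 1])
    if (abs(wn - mu) >= abs(w - mu) - 1e-12) count <- count + 1
  }
  count / total
}

# Straight transcription of the metric formulas.
oracle_metrics <- function(tp, fp, fn, tn) {
  acc <- (tp + tn) / (tp + fp + fn + tn)
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  fd <- tp + (fn + fp) / 2
  f1 <- if (fd > 0) tp / fd else 0
  list(accuracy = acc, sensitivity = sen, mcc = mcc, f_measure = f1)
}

# Random orthogonal matrix via QR of a Gaussian matrix.
random_orthogonal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}
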