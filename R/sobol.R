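# Sobol low-discrepancy sequence (Gray-code construction).
#
# Direction numbers are the first 64 dimensions of the Joe & Kuo (2008)
# table of primitive polynomials and initial values m_i (the standard
# "new-joe-kuo-6" parametrization). `poly` holds the full binary encoding of
# each primitive polynomial over GF(2) (e.g. 7 = x^2 + x + 1); `minit` the
# initial odd direction integers. Dimension 1 (poly = 1) is the van der
# Corput sequence in base 2.

.sobol_poly <- c(
  1, 3, 7, 11, 13, 19, 25, 37, 41, 47, 55, 59, 61, 67, 91, 97, 103, 109,
  115, 131, 137, 143, 145, 157, 167, 171, 185, 191, 193, 203, 211, 213,
  229, 239, 241, 247, 253, 285, 299, 301, 333, 351, 355, 357, 361, 369,
  391, 397, 425, 451, 463, 487, 501, 529, 539, 545, 557, 563, 601, 607,
  617, 623, 631, 637)

.sobol_minit <- list(
  c(1), c(1), c(1, 3), c(1, 3, 1), c(1, 1, 1), c(1, 1, 3, 3),
  c(1, 3, 5, 13), c(1, 1, 5, 5, 17), c(1, 1, 5, 5, 5), c(1, 1, 7, 11, 19),
  c(1, 1, 5, 1, 1), c(1, 1, 1, 3, 11), c(1, 3, 5, 5, 31),
  c(1, 3, 3, 9, 7, 49), c(1, 1, 1, 15, 21, 21), c(1, 3, 1, 13, 27, 49),
  c(1, 1, 1, 15, 7, 5), c(1, 3, 1, 15, 13, 25), c(1, 1, 5, 5, 19, 61),
  c(1, 3, 7, 11, 23, 15, 103), c(1, 3, 7, 13, 13, 15, 69),
  c(1, 1, 3, 13, 7, 35, 63), c(1, 3, 5, 9, 1, 25, 53),
  c(1, 3, 1, 13, 9, 35, 107), c(1, 3, 1, 5, 27, 61, 31),
  c(1, 1, 5, 11, 19, 41, 61), c(1, 3, 5, 3, 3, 13, 69),
  c(1, 1, 7, 13, 1, 19, 1), c(1, 3, 7, 5, 13, 19, 59),
  c(1, 1, 3, 9, 25, 29, 41), c(1, 3, 5, 13, 23, 1, 55),
  c(1, 3, 7, 3, 13, 59, 17), c(1, 3, 1, 3, 5, 53, 69),
  c(1, 1, 5, 5, 23, 33, 13), c(1, 1, 7, 7, 1, 61, 123),
  c(1, 1, 7, 9, 13, 61, 49), c(1, 3, 3, 5, 3, 55, 33),
  c(1, 3, 1, 15, 31, 13, 49, 245), c(1, 3, 5, 15, 31, 59, 63, 97),
  c(1, 3, 1, 11, 11, 11, 77, 249), c(1, 3, 1, 11, 27, 43, 71, 9),
  c(1, 1, 7, 15, 21, 11, 81, 45), c(1, 3, 7, 3, 25, 31, 65, 79),
  c(1, 3, 1, 1, 19, 11, 3, 205), c(1, 1, 5, 9, 19, 21, 29, 157),
  c(1, 3, 7, 11, 1, 33, 89, 185), c(1, 3, 3, 3, 15, 9, 79, 71),
  c(1, 3, 7, 11, 15, 39, 119, 27), c(1, 1, 3, 1, 11, 31, 97, 225),
  c(1, 1, 1, 3, 23, 43, 57, 177), c(1, 3, 7, 7, 17, 17, 37, 71),
  c(1, 3, 1, 5, 27, 63, 123, 213), c(1, 1, 3, 5, 11, 43, 53, 133),
  c(1, 3, 5, 5, 29, 17, 47, 173, 479), c(1, 3, 3, 11, 3, 1, 109, 9, 69),
  c(1, 1, 1, 5, 17, 39, 23, 5, 343), c(1, 3, 1, 5, 25, 15, 31, 103, 499),
  c(1, 1, 1, 11, 11, 17, 63, 105, 183), c(1, 1, 5, 11, 9, 29, 97, 231, 363),
  c(1, 1, 5, 15, 19, 45, 41, 7, 383), c(1, 3, 7, 7, 31, 19, 83, 137, 221),
  c(1, 1, 1, 3, 23, 15, 111, 223, 83), c(1, 1, 5, 13, 31, 15, 55, 25, 161),
  c(1, 1, 3, 13, 25, 47, 39, 87, 257))

# Direction numbers v_{k} (as integers scaled by 2^bits) for one dimension.
.sobol_directions <- function(dimension, bits) {
  p <- .sobol_poly[dimension]
  m <- .sobol_minit[[dimension]]
  # polynomial degree s and inner coefficient bits a_1..a_{s-1}
  s <- floor(log2(p))
  v <- numeric(bits)
  if (s == 0L) {  # dimension 1: van der Corput
    v[] <- 2^(bits - seq_len(bits))
    return(v)
  }
  a <- bitwAnd(p %/% 2L, 2^(s - 1) - 1)  # strip leading and trailing 1 bits
  mm <- numeric(bits)
  mm[seq_len(min(s, bits))] <- m[seq_len(min(s, bits))]
  if (bits > s) {
    for (k in (s + 1):bits) {
      val <- bitwXor(as.integer(mm[k - s]),
                     as.integer(mm[k - s]) * as.integer(2^s))
      for (j in seq_len(s - 1)) {
        if (bitwAnd(a, bitwShiftL(1L, s - 1L - j)) != 0L)
          val <- bitwXor(val, as.integer(mm[k - j] * 2^j))
      }
      mm[k] <- val
    }
  }
  v <- mm[seq_len(bits)] * 2^(bits - seq_len(bits))
  v
}

#' Sobol low-discrepancy point set
#'
#' Generates the first `n` points of the (unscrambled) Sobol sequence in
#' \eqn{[0,1)^{dim}} by the Gray-code construction, using the Joe–Kuo
#' direction numbers. The sequence starts at the origin (point index 0),
#' matching the canonical definition.
#'
#' @param n number of points (rows).
#' @param dim dimension, at most 64 with the bundled direction numbers.
#' @return An `n x dim` numeric matrix with entries in \eqn{[0,1)}.
#' @examples
#' sobol_points(4, 2)
#' @export
sobol_points <- function(n, dim) {
  n <- as.integer(n); dim <- as.integer(dim)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  if (is.na(dim) || dim < 1L) stop("'dim' must be >= 1")
  if (dim > length(.sobol_poly))
    stop("'dim' exceeds the bundled direction-number table (max ",
         length(.sobol_poly), ")")
  bits <- max(1L, ceiling(log2(n + 1)))
  out <- matrix(0, n, dim)
  scale <- 2^bits
  for (d in seq_len(dim)) {
    v <- .sobol_directions(d, bits)
    x <- 0
    # Gray-code update: point i differs from i-1 in direction number of the
    # lowest zero bit of i-1.
    for (i in seq_len(n - 1L)) {
      j <- 1L
      ii <- i - 1L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); j <- j + 1L }
      x <- bitwXor(as.integer(x), as.integer(v[j]))
      out[i + 1L, d] <- x / scale
    }
  }
  out
}

#' Centered L2 discrepancy of a point set
#'
#' Computes the centered L2 discrepancy (Hickernell's closed form) of a
#' point set in the unit hypercube: a scalar uniformity measure where lower
#' values mean more even coverage. Used to quantify the advantage of Sobol
#' initialization over pseudo-random initialization.
#'
#' @param x `n x d` matrix with entries in \eqn{[0,1]}.
#' @return Non-negative scalar discrepancy.
#' @export
centered_l2_discrepancy <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  stopifnot(n >= 1, d >= 1, all(x >= 0), all(x <= 1))
  z <- abs(x - 0.5)
  term1 <- (13 / 12)^d
  prod2 <- apply(1 + 0.5 * z - 0.5 * z^2, 1, prod)
  term2 <- (2 / n) * sum(prod2)
  # pairwise product term
  s3 <- 0
  for (i in seq_len(n)) {
    zi <- z[i, , drop = TRUE]
    m <- 1 + 0.5 * sweep(z, 2, zi, "+") -
      0.5 * abs(sweep(x, 2, x[i, , drop = TRUE], "-"))
    s3 <- s3 + sum(apply(m, 1, prod))
  }
  term3 <- s3 / n^2
  sqrt(term1 - term2 + term3)
}
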