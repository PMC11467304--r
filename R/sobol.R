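# Sobol low-discrepancy sequence, Gray-code construction with Joe-Kuo
# direction numbers (new-joe-kuo-6) for up to 10 dimensions. 30 bits are
# used so all integer arithmetic stays inside R's 32-bit signed range.

SOBOL_MAXBIT <- 30L

# rows: dimension index (>= 2), columns: s (degree), a (coefficients),
# then the initial direction integers m
.jk <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 3L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L)))

# direction integers V[bit] for one dimension, already shifted to maxbit
sobolDirections <- function(dim) {
  mb <- SOBOL_MAXBIT
  if (dim == 1L) return(bitwShiftL(1L, mb - seq_len(mb)))
  p <- .jk[[dim - 1L]]
  s <- p$s; a <- p$a
  m <- c(p$m, integer(mb - s))
  if (mb > s) for (i in (s + 1L):mb) {
    mi <- bitwXor(m[i - s], bitwShiftL(m[i - s], s))
    if (s > 1L) for (k in seq_len(s - 1L))
      if (bitwAnd(bitwShiftR(a, s - 1L - k), 1L) == 1L)
        mi <- bitwXor(mi, bitwShiftL(m[i - k], k))
    m[i] <- mi
  }
  vapply(seq_len(mb), function(i) bitwShiftL(m[i], mb - i), integer(1))
}

#' Sobol low-discrepancy points
#'
#' Gray-code Sobol sequence (Joe-Kuo direction numbers, up to 10
#' dimensions). With a `seed`, a seeded random digital shift (bitwise XOR
#' with one 30-bit integer per dimension) scrambles the sequence while
#' preserving its low discrepancy; the result is deterministic for a fixed
#' seed.
#'
#' @param n number of points.
#' @param d dimension (<= 10).
#' @param seed optional integer seed for the digital shift; `NULL` gives the
#'   unscrambled sequence.
#' @return an `n x d` matrix of points in `[0, 1)`.
#' @export
sobolPoints <- function(n, d, seed = NULL) {
  stopIfNot(d >= 1 && d <= 10, "sobolPoints supports 1-10 dimensions")
  stopIfNot(n >= 1, "n must be positive")
  V <- vapply(seq_len(d), sobolDirections, integer(SOBOL_MAXBIT))
  X <- matrix(0L, n, d)
  x <- integer(d)
  # point i uses the lowest zero bit of i-1 (Gray code ordering)
  for (i in seq_len(n)) {
    if (i > 1L) {
      c0 <- 1L; v <- i - 2L
      while (bitwAnd(v, 1L) == 1L) { v <- bitwShiftR(v, 1L); c0 <- c0 + 1L }
      x <- bitwXor(x, V[c0, ])
    }
    X[i, ] <- x
  }
  if (!is.null(seed)) {
    shift <- withSeed(seed,
      as.integer(floor(stats::runif(d) * 2^SOBOL_MAXBIT)))
    # bitwXor drops dims; recycle the d shifts down the transposed matrix
    X <- t(matrix(bitwXor(as.integer(t(X)), shift), nrow = d))
  }
  X / 2^SOBOL_MAXBIT
}

#' Build a Saltelli cross-sampling design
#'
#' Generates `base_n` Sobol points in `2D` dimensions, splits them into the
#' base matrices `A` and `B`, and forms the `D` cross matrices `AB_i` (`A`
#' with column `i` taken from `B`). Evaluating the model on all rows costs
#' `base_n * (D + 2)` runs and yields the first-order Sobol index of every
#' input.
#'
#' @param n_members number of ensemble members spanned by the first input.
#' @param bundle_size number of impact functions spanned by the third input.
#' @param scale_range numeric length-2 range of the exposure scaling factor.
#' @param base_n base sample count; must be a power of two.
#' @param seed integer seed for the scrambled Sobol sequence.
#' @return list of class `saltelliDesign` with matrices `A`, `B` (rows in
#'   `[0,1)^D`), `AB` (array `base_n x D x D`), `base_n`, `total_runs`, and
#'   the input `space`.
#' @export
buildDesign <- function(n_members = 51, bundle_size = 1,
                        scale_range = c(0.8, 1.2), base_n = 2048,
                        seed = 42) {
  stopIfNot(base_n >= 2 && bitwAnd(base_n, base_n - 1L) == 0,
            "base_n must be a power of two")
  stopIfNot(scale_range[1L] < scale_range[2L], "invalid scale_range")
  stopIfNot(n_members >= 1 && bundle_size >= 1, "empty input space")
  D <- 3L
  pts <- sobolPoints(base_n, 2L * D, seed = seed)
  A <- pts[, 1:D, drop = FALSE]
  B <- pts[, (D + 1):(2 * D), drop = FALSE]
  AB <- array(NA_real_, c(base_n, D, D))
  for (i in seq_len(D)) {
    M <- A
    M[, i] <- B[, i]
    AB[, , i] <- M
  }
  structure(list(A = A, B = B, AB = AB, base_n = as.integer(base_n),
                 total_runs = as.integer(base_n) * (D + 2L),
                 space = list(n_members = n_members,
                              bundle_size = bundle_size,
                              scale_range = scale_range),
                 inputs = c("member", "scale", "function")),
            class = "saltelliDesign")
}

#' Map unit-cube design points to model inputs
#'
#' `member = floor(u1 * n_members)` (0-based, clamped), `scale` uniform on
#' `scale_range`, `fun = floor(u3 * bundle_size)` (0-based, clamped).
#'
#' @param u matrix (or vector) of points in `[0,1)^3`.
#' @param space the `space` element of a `saltelliDesign`.
#' @return data.frame with 0-based `member`, numeric `scale`, 0-based `fun`.
#' @export
mapUnits <- function(u, space) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  lo <- space$scale_range[1L]; hi <- space$scale_range[2L]
  data.frame(
    member = pmin(floor(u[, 1L] * space$n_members), space$n_members - 1L),
    scale = lo + (hi - lo) * u[, 2L],
    fun = pmin(floor(u[, 3L] * space$bundle_size), space$bundle_size - 1L))
}

#' First-order Sobol indices from a Saltelli design
#'
#' Saltelli (2010) estimator `S_i = mean(f_B * (f_ABi - f_A)) / Var(Y)` with
#' `Var(Y)` over the pooled `A` and `B` outputs. Confidence intervals come
#' from a bootstrap over design rows (the same resampled rows are used in
#' `f_A`, `f_B` and every `f_ABi`, preserving the cross structure). A
#' zero-variance output yields all indices 0 by convention. Negative point
#' estimates are reported as-is.
#'
#' @param fA,fB numeric outputs on the `A` and `B` rows.
#' @param fAB numeric matrix `base_n x D` of outputs on the `AB_i` rows.
#' @param inputs character input names.
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param conf confidence level (default 0.95, percentile interval).
#' @param seed integer seed for the bootstrap resampling.
#' @return data.frame of class `sensitivityResult` with columns `input`,
#'   `S1`, `ci_low`, `ci_high`; attributes `mean`, `variance`.
#' @export
sobolFirstOrder <- function(fA, fB, fAB,
                            inputs = c("member", "scale", "function"),
                            n_boot = 1000, conf = 0.95, seed = 42) {
  fAB <- as.matrix(fAB)
  n <- length(fA)
  stopIfNot(length(fB) == n && nrow(fAB) == n,
            "output lengths do not match the design")
  D <- ncol(fAB)
  est <- function(a, b, ab) {
    y <- c(a, b)
    v <- stats::var(y)
    if (!is.finite(v) || v < 1e-24) return(rep(0, D))
    colMeans(b * (ab - a)) / v
  }
  S <- est(fA, fB, fAB)
  ci <- matrix(NA_real_, D, 2L)
  if (n_boot > 0) {
    boot <- withSeed(seed, {
      out <- matrix(NA_real_, n_boot, D)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        out[b, ] <- est(fA[idx], fB[idx], fAB[idx, , drop = FALSE])
      }
      out
    })
    alpha <- (1 - conf) / 2
    ci <- t(apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                  names = FALSE))
  }
  out <- data.frame(input = inputs[seq_len(D)], S1 = S,
                    ci_low = ci[, 1L], ci_high = ci[, 2L])
  attr(out, "mean") <- mean(c(fA, fB))
  attr(out, "variance") <- stats::var(c(fA, fB))
  class(out) <- c("sensitivityResult", "data.frame")
  out
}
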