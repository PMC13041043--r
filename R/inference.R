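#' Mann-Whitney U test (implemented from first principles)
#'
#' Computes the Mann-Whitney U statistic of `x` (the number of (x, y) pairs
#' with x > y, counting ties as 1/2) from midrank sums.  The two-sided
#' p-value is exact — from the full null distribution of U obtained by
#' dynamic programming over rank partitions — when `n1 + n2 <= exact_limit`
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_limit switch point on `n1 + n2` between the exact and the
#'   approximate p-value; default 12.
#' @return list of class `"mwu_test"` with `u_statistic`, `p`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal"`), `direction` (`"x"`, `"y"` or
#'   `"none"`, whichever sample tends larger) and `degenerate` (all values
#'   identical).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1 (exact)
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  all_v <- c(x, y)
  r <- rank(all_v)                    # midranks
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2        # pairs with x > y (+ half ties)
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  degenerate <- length(ties) == 1L

  if (degenerate) {
    p <- 1
    method <- "degenerate"
  } else if (!has_ties && (n1 + n2) <= exact_limit) {
    pu <- mwu_null_distribution(n1, n2)     # P(U = 0..n1*n2)
    u_min <- min(u, n1 * n2 - u)
    p <- min(1, 2 * sum(pu[seq_len(u_min + 1)]))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    s2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (s2 <= 0) {
      p <- 1
      method <- "degenerate"
      degenerate <- TRUE
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(s2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "normal"
    }
  }
  direction <- if (u > n1 * n2 / 2) "x" else if (u < n1 * n2 / 2) "y"
               else "none"
  structure(list(u_statistic = u, p = p, n1 = n1, n2 = n2,
                 method = method, direction = direction,
                 degenerate = degenerate),
            class = "mwu_test")
}

# exact null pmf of U for tie-free data, via the recurrence on the largest
# rank: with i x's and j y's placed, f(i, j, u) = f(i, j-1, u) [largest is a
# y] + f(i-1, j, u-j) [largest is an x, beating all j y's]
mwu_null_distribution <- function(n1, n2) {
  umax <- n1 * n2
  # f[i+1, u+1] = number of arrangements of i x's (and the current j y's)
  f <- matrix(0, nrow = n1 + 1, ncol = umax + 1)
  f[, 1] <- 1                                   # j = 0: U is always 0
  for (j in seq_len(n2)) {
    for (i in seq_len(n1)) {
      shifted <- c(rep(0, j), f[i, ])[seq_len(umax + 1)]
      f[i + 1, ] <- f[i + 1, ] + shifted        # f[i, ] is already at j
    }
  }
  f[n1 + 1, ] / choose(n1 + n2, n1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts the p-values ascending, applies the step-up rule
#' \eqn{adj_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)} and returns the
#' adjusted values in the original order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]; `NA`s are carried
#'   through and excluded from `m`.
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.04, 0.03, 0.02))  # all 0.04
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m > 0) {
    o <- order(p)
    ranked <- pmin(1, p[o] * m / seq_len(m))
    adj <- rev(cummin(rev(ranked)))
    out[ok][o] <- adj
  }
  out
}

#' Percentile bootstrap confidence interval for the mean
#'
#' Resamples `values` with replacement `b` times, takes the mean of each
#' resample, and returns the percentile interval at the requested level.
#' The RNG state of the caller is untouched; the same seed always yields the
#' same interval.
#'
#' @param values numeric vector; `NA`s dropped.
#' @param b number of bootstrap resamples (default 9999).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (default 20160725).
#' @return named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, b = 9999, level = 0.95, seed = 20160725) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no non-missing values to bootstrap", call. = FALSE)
  if (n == 1) {
    warning("single observation: degenerate interval")
    return(c(low = values, high = values))
  }
  if (b < 200) stop("b must be at least 200", call. = FALSE)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  alpha <- (1 - level) / 2
  qs <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
  c(low = qs[1], high = qs[2])
}
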