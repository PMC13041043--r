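#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration whose inter-point distances
#' reproduce the rank order of the input dissimilarities, by alternating
#' (a) monotone regression of configuration distances on dissimilarity
#' rank (pool-adjacent-violators) to obtain disparities \eqn{\hat d}, and
#' (b) a Guttman majorization step moving the configuration towards the
#' disparities.  The criterion is Kruskal stress-1,
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}}.  Ties in the
#' dissimilarities are treated as primary ("weak"): tied pairs may take
#' different disparities.  The search runs from a principal-coordinates
#' start plus `n_restarts` random starts; the best configuration is
#' returned centred and rotated to its principal axes.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param k target dimensionality (default 2).
#' @param seed integer seed for the random restarts.
#' @param max_iter maximum iterations per start (default 300).
#' @param n_restarts random starts in addition to the PCoA start
#'   (default 20).
#' @param tol stop when the stress improvement falls below this
#'   (default 1e-6).
#' @return list of class `"nmds_fit"`: `coordinates` (n x k), `stress`,
#'   `converged`, `iterations`, `stress_sequence` (non-increasing, from the
#'   best start).
#' @export
nmds <- function(d, k = 2, seed = 42, max_iter = 300, n_restarts = 20,
                 tol = 1e-6) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  }
  if (n < 3 || k >= n) stop("need n >= 3 and k < n", call. = FALSE)

  lower <- which(lower.tri(d))
  delta <- d[lower]
  starts <- with_seed(seed, {
    rnd <- lapply(seq_len(n_restarts),
                  function(i) matrix(rnorm(n * k), n, k))
    c(list(pcoa_coords(d, k)), rnd)
  })
  best <- NULL
  for (x0 in starts) {
    run <- nmds_single(x0, delta, lower, n, k, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  x <- scale(best$x, center = TRUE, scale = FALSE)
  rot <- eigen(crossprod(x), symmetric = TRUE)$vectors
  coords <- x %*% rot
  dimnames(coords) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(coordinates = coords, stress = best$stress,
                 converged = best$converged, iterations = best$iterations,
                 stress_sequence = best$stress_sequence),
            class = "nmds_fit")
}

# one SMACOF/PAVA descent from a fixed start; accepts only improving steps
nmds_single <- function(x, delta, lower, n, k, max_iter, tol) {
  config_dist <- function(x) as.matrix(dist(x))[lower]
  dvec <- config_dist(x)
  stress_of <- function(dvec) {
    dhat <- disparities(delta, dvec)
    list(stress = sqrt(sum((dvec - dhat)^2) / sum(dvec^2)), dhat = dhat)
  }
  cur <- stress_of(dvec)
  seq_stress <- cur$stress
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    x_new <- guttman_step(x, cur$dhat, dvec, lower, n)
    dvec_new <- config_dist(x_new)
    nxt <- stress_of(dvec_new)
    if (nxt$stress > cur$stress + 1e-15) break   # keep best-so-far
    improvement <- cur$stress - nxt$stress
    x <- x_new; dvec <- dvec_new; cur <- nxt
    seq_stress <- c(seq_stress, cur$stress)
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(x = x, stress = cur$stress, converged = converged,
       iterations = iter, stress_sequence = seq_stress)
}

# monotone (primary-tie) disparities: PAVA of config distances ordered by
# dissimilarity, ties broken by current distance (weak tie treatment)
disparities <- function(delta, dvec) {
  ord <- order(delta, dvec)
  fit <- pava(dvec[ord])
  out <- numeric(length(dvec))
  out[ord] <- fit
  out
}

# pool-adjacent-violators for a nondecreasing fit, unit weights
pava <- function(y) {
  n <- length(y)
  val <- y
  w <- rep(1, n)
  len <- 0L
  vals <- numeric(n); wts <- numeric(n); counts <- integer(n)
  for (i in seq_len(n)) {
    len <- len + 1L
    vals[len] <- y[i]; wts[len] <- 1; counts[len] <- 1L
    while (len > 1L && vals[len - 1L] > vals[len]) {
      tw <- wts[len - 1L] + wts[len]
      vals[len - 1L] <- (vals[len - 1L] * wts[len - 1L] +
                           vals[len] * wts[len]) / tw
      wts[len - 1L] <- tw
      counts[len - 1L] <- counts[len - 1L] + counts[len]
      len <- len - 1L
    }
  }
  rep(vals[seq_len(len)], counts[seq_len(len)])
}

# Guttman transform: x_new = (1/n) B x with b_ij = -dhat_ij / d_ij
guttman_step <- function(x, dhat, dvec, lower, n) {
  B <- matrix(0, n, n)
  ratio <- ifelse(dvec > 0, dhat / dvec, 0)
  B[lower] <- -ratio
  B <- B + t(B)
  diag(B) <- -rowSums(B)
  (B %*% x) / n
}

# classical principal coordinates of a distance matrix (top k real axes)
pcoa_coords <- function(d, k) {
  n <- nrow(d)
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  pos <- pmax(e$values[seq_len(k)], 0)
  e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k)
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("nMDS: %d points in %d dims, stress = %.4g (%s, %d iterations)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}
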