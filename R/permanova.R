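#' Permutational multivariate analysis of variance (one factor)
#'
#' The pseudo-F statistic is computed directly from the distance matrix:
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2}, within-group sums of
#' squares analogously within each group scaled by group size, and
#' \eqn{F = \frac{SS_{between}/(a-1)}{SS_{within}/(N-a)}}.  The p-value
#' permutes the group labels freely; when the number of distinct
#' relabelings of the label multiset is at most `n_perm` the null
#' distribution is enumerated exhaustively (p = proportion of labelings
#' with \eqn{F \ge F_{obs}}, the observed one included), otherwise Monte
#' Carlo with \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param d symmetric dissimilarity matrix.
#' @param grouping vector of group labels, length `nrow(d)`; at least two
#'   groups, each non-empty.
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed integer seed for the permutations.
#' @return list of class `"permanova_result"`: `pseudo_f`, `r_squared`,
#'   `p`, `n_permutations`, `exhaustive`, `df_between`, `df_within`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 42) {
  d <- as.matrix(d)
  grouping <- as.character(grouping)
  n <- nrow(d)
  if (length(grouping) != n) {
    stop("one group label per sample is required", call. = FALSE)
  }
  groups <- unique(grouping)
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  d2 <- d^2
  f_obs <- permanova_f(d2, grouping)
  n_distinct <- distinct_relabelings(table(grouping))
  if (n_distinct <= n_perm) {
    labelings <- multiset_permutations(grouping)
    f_all <- vapply(labelings, function(g) permanova_f(d2, g), numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- length(labelings)
    exhaustive <- TRUE
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, grouping[sample.int(n)])
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
    exhaustive <- FALSE
  }
  a <- length(groups)
  ss <- permanova_ss(d2, grouping)
  structure(list(pseudo_f = f_obs,
                 r_squared = (ss$total - ss$within) / ss$total,
                 p = p, n_permutations = n_used, exhaustive = exhaustive,
                 df_between = a - 1, df_within = n - a),
            class = "permanova_result")
}

permanova_ss <- function(d2, grouping) {
  n <- nrow(d2)
  total <- sum(d2) / (2 * n)
  within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    within <- within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  list(total = total, within = within)
}

permanova_f <- function(d2, grouping) {
  ss <- permanova_ss(d2, grouping)
  a <- length(unique(grouping))
  n <- nrow(d2)
  between <- ss$total - ss$within
  if (ss$within <= 0) return(Inf)
  (between / (a - 1)) / (ss$within / (n - a))
}

# number of distinct orderings of a label multiset
distinct_relabelings <- function(tab) {
  exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

# all distinct permutations of a label vector (used only when few)
multiset_permutations <- function(labels) {
  rec <- function(remaining) {
    if (length(remaining) == 1) return(list(remaining))
    out <- list()
    for (u in unique(remaining)) {
      first <- which(remaining == u)[1]
      for (tail in rec(remaining[-first])) {
        out[[length(out) + 1]] <- c(u, tail)
      }
    }
    out
  }
  rec(labels)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.3f, p = %.4g (%s, %d)\n",
    x$pseudo_f, x$df_between, x$df_within, x$r_squared, x$p,
    if (x$exhaustive) "exhaustive" else "permutations", x$n_permutations))
  invisible(x)
}

#' Homogeneity of multivariate group dispersions
#'
#' Embeds the distance matrix by principal-coordinates analysis, keeping
#' both positive- and negative-eigenvalue axes; the distance of a sample to
#' its group centroid combines the two sets by difference of squares
#' (\eqn{z^2 = \|x^{real} - c^{real}\|^2 - \|x^{imag} - c^{imag}\|^2},
#' truncated at zero), the usual contract for semi-metric dissimilarities.
#' Group effect on these centroid distances is tested with a one-way
#' F statistic whose null distribution comes from permuting the centroid
#' distances across samples.
#'
#' @inheritParams permanova
#' @return list of class `"permanova_result"` with the same fields, plus
#'   `centroid_distances`.
#' @export
dispersion_homogeneity <- function(d, grouping, n_perm = 999, seed = 42) {
  d <- as.matrix(d)
  grouping <- as.character(grouping)
  n <- nrow(d)
  if (length(grouping) != n) {
    stop("one group label per sample is required", call. = FALSE)
  }
  if (length(unique(grouping)) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  e <- eigen(gower_center(d), symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  vals <- e$values[keep]
  axes <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(vals)),
                                                   sum(keep))
  pos <- vals > 0
  z <- numeric(n)
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    cen <- colMeans(axes[idx, , drop = FALSE])
    for (i in idx) {
      dif2 <- (axes[i, ] - cen)^2
      z[i] <- sqrt(max(0, sum(dif2[pos]) - sum(dif2[!pos])))
    }
  }
  f_of <- function(zv, grp) {
    mg <- tapply(zv, grp, mean)
    ng <- tapply(zv, grp, length)
    a <- length(mg)
    ss_b <- sum(ng * (mg - mean(zv))^2)
    ss_w <- sum((zv - mg[grp])^2)
    eps <- 1e-12 * (sum(zv^2) + 1e-300)   # guard exact-tie degeneracies
    if (ss_w <= eps) return(if (ss_b <= eps) 0 else Inf)
    (ss_b / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(z, grouping)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    f_of(z[sample.int(n)], grouping)
  }, numeric(1)))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  structure(list(pseudo_f = f_obs, r_squared = NA_real_, p = p,
                 n_permutations = n_perm, exhaustive = FALSE,
                 df_between = length(unique(grouping)) - 1,
                 df_within = n - length(unique(grouping)),
                 centroid_distances = setNames(z, rownames(d))),
            class = "permanova_result")
}
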