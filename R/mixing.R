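#' Standardized major axis (Model II) regression
#'
#' The SMA slope is `sign(r) * sd(y) / sd(x)`; the intercept puts the line
#' through the centroid.  The p-value is the two-sided test of zero Pearson
#' correlation (t with n - 2 degrees of freedom), which is also the test of
#' the SMA slope differing from zero.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list of class `"model2_fit"`: `slope`, `intercept`, `r`, `p`,
#'   `n`, `method = "SMA"`.
#' @export
sma_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  sdx <- sd(x); sdy <- sd(y)
  if (sdx == 0) stop("x has zero variance", call. = FALSE)
  if (sdy == 0) stop("y has zero variance", call. = FALSE)
  r <- cor(x, y)
  slope <- sign(if (r == 0) 1 else r) * sdy / sdx
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 r = r, p = cor_test_p(r, n), n = n, method = "SMA"),
            class = "model2_fit")
}

#' Deming (errors-in-both-variables) regression
#'
#' With error-variance ratio `lambda` the slope is
#' \deqn{\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}}.}
#' For `lambda = 1` (both variables equally uncertain) this is the major
#' axis: the first principal axis of the 2x2 covariance matrix.  The
#' significance test is the two-sided test of zero Pearson correlation; the
#' slope's standard error is estimated by leave-one-out jackknife.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param lambda ratio of error variances var(err_y)/var(err_x); default 1.
#' @return list of class `"model2_fit"`: `slope`, `intercept`, `r`, `p`,
#'   `n`, `slope_se` (jackknife), `method = "Deming"`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  slope <- deming_slope(x, y, lambda)
  jack <- vapply(seq_len(n),
                 function(i) deming_slope(x[-i], y[-i], lambda), numeric(1))
  slope_se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  r <- cor(x, y)
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 r = r, p = cor_test_p(r, n), n = n,
                 slope_se = slope_se, method = "Deming"),
            class = "model2_fit")
}

deming_slope <- function(x, y, lambda) {
  sxx <- sum((x - mean(x))^2) / (length(x) - 1)
  syy <- sum((y - mean(y))^2) / (length(x) - 1)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  if (sxy == 0) {
    if (syy == lambda * sxx) {
      stop("orientation undefined: zero covariance and equal variances",
           call. = FALSE)
    }
    # degenerate but orientable: axis is vertical or horizontal
    return(if (syy > lambda * sxx) Inf else 0)
  }
  d <- syy - lambda * sxx
  (d + sqrt(d^2 + 4 * lambda * sxy^2)) / (2 * sxy)
}

cor_test_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("%s regression: y = %.4g + %.4g x (r = %.3f, p = %.3g, n = %d)\n",
              x$method, x$intercept, x$slope, x$r, x$p, x$n))
  invisible(x)
}

#' Fit salinity-nutrient mixing diagrams per stratum
#'
#' One Model II regression of concentration on salinity per (region, year,
#' analyte, water mass) stratum present in the data.  Strata with fewer than
#' `min_n` complete pairs or zero variance on either axis are reported with
#' `NA` fit fields rather than dropped, so the count of attempted diagrams
#' is auditable.  p-values are Benjamini-Hochberg corrected across all
#' strata actually fitted.
#'
#' @param samples nutrient table with `region`, `year`, `sal` and analyte
#'   columns plus a `water_mass` column (e.g. merged from [classify_ctd()]).
#' @param analytes analyte columns to use.
#' @param method `"SMA"` or `"Deming"`.
#' @param min_n minimum complete pairs per stratum (default 3).
#' @return data frame with one row per stratum: grouping columns, `n`,
#'   `slope`, `intercept`, `r`, `p`, `p_corr`.
#' @export
mixing_diagrams <- function(samples,
                            analytes = intersect(.analytes, names(samples)),
                            method = c("SMA", "Deming"), min_n = 3) {
  method <- match.arg(method)
  fit_fun <- if (method == "SMA") sma_fit else deming_fit
  if (!"water_mass" %in% names(samples)) {
    stop("samples need a water_mass column", call. = FALSE)
  }
  samples <- samples[samples$water_mass != "Unclassified", , drop = FALSE]
  strata <- unique(samples[, c("region", "year", "water_mass")])
  rows <- list()
  for (k in seq_len(nrow(strata))) {
    sel <- samples$region == strata$region[k] &
      samples$year == strata$year[k] &
      samples$water_mass == strata$water_mass[k]
    for (a in analytes) {
      xy <- samples[sel, c("sal", a)]
      xy <- xy[complete.cases(xy), ]
      fit <- NULL
      if (nrow(xy) >= min_n && sd(xy$sal) > 0 && sd(xy[[a]]) > 0) {
        fit <- fit_fun(xy$sal, xy[[a]])
      }
      rows[[length(rows) + 1]] <- data.frame(
        region = strata$region[k], year = strata$year[k],
        water_mass = strata$water_mass[k], analyte = a, n = nrow(xy),
        slope = if (is.null(fit)) NA_real_ else fit$slope,
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        r = if (is.null(fit)) NA_real_ else fit$r,
        p = if (is.null(fit)) NA_real_ else fit$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_corr <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}
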