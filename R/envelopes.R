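#' Define a water-mass envelope
#'
#' An envelope is an axis-aligned box in temperature-salinity space, with an
#' optional upper bound on the potential density anomaly \eqn{\sigma_\theta}
#' (used for the Atlantic-derived classes).  Unbounded edges are `-Inf` /
#' `Inf`.  By default lower bounds are closed and upper bounds open, so that
#' adjacent envelopes partition the plane without double-matching; the
#' `closed` flags override this per edge.
#'
#' @param label water-mass label, one of `"SW"`, `"IW"`, `"AW"`, `"TAW"`,
#'   `"ArW"`, `"LW"`, `"WCW"`.
#' @param t_min,t_max temperature bounds (degrees C).
#' @param s_min,s_max salinity bounds.
#' @param sigma_max optional strict upper bound on \eqn{\sigma_\theta}
#'   (kg m\eqn{^{-3}}); `NA` for none.
#' @param closed named logical vector with any of `t_min`, `t_max`, `s_min`,
#'   `s_max`; `TRUE` means the bound is attained.
#' @return an object of class `"wm_envelope"`.
#' @export
water_mass_envelope <- function(label, t_min = -Inf, t_max = Inf,
                                s_min = -Inf, s_max = Inf, sigma_max = NA,
                                closed = NULL) {
  label <- match.arg(label, setdiff(.wm_levels, "Unclassified"))
  if (is.finite(t_min) && is.finite(t_max) && t_min > t_max) {
    stop("t_min > t_max in envelope ", label, call. = FALSE)
  }
  if (is.finite(s_min) && is.finite(s_max) && s_min > s_max) {
    stop("s_min > s_max in envelope ", label, call. = FALSE)
  }
  cl <- c(t_min = TRUE, t_max = FALSE, s_min = TRUE, s_max = FALSE)
  if (!is.null(closed)) {
    bad <- setdiff(names(closed), names(cl))
    if (length(bad)) stop("unknown closedness flag: ", bad[1], call. = FALSE)
    cl[names(closed)] <- closed
  }
  structure(list(label = label, t_min = t_min, t_max = t_max,
                 s_min = s_min, s_max = s_max,
                 sigma_max = if (is.null(sigma_max)) NA_real_
                             else as.numeric(sigma_max),
                 closed = cl),
            class = "wm_envelope")
}

#' Assemble an envelope table
#'
#' Bundles a set of envelopes with the tie-break `precedence` order and the
#' global density threshold used by the Atlantic-water exception rule.
#' The default precedence puts the coldest, most specific classes first
#' (WCW, ArW, LW, SW, IW, TAW, AW), because the Arctic-type envelopes
#' (ArW/LW/WCW) partially overlap and a deterministic resolution order is
#' required.
#'
#' @param envelopes list of [water_mass_envelope()] objects.
#' @param precedence character vector, a permutation of the envelope labels;
#'   a record matching several envelopes takes the first label listed here.
#' @param sigma_threshold density threshold (kg m\eqn{^{-3}}) for the
#'   AW/TAW fallback rule; default 27.92.
#' @return an object of class `"envelope_table"`.
#' @export
envelope_table <- function(envelopes,
                           precedence = NULL,
                           sigma_threshold = 27.92) {
  labels <- vapply(envelopes, function(e) e$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate envelope label: ", labels[duplicated(labels)][1],
         call. = FALSE)
  }
  if (is.null(precedence)) {
    default_order <- c("WCW", "ArW", "LW", "SW", "IW", "TAW", "AW")
    precedence <- default_order[default_order %in% labels]
  }
  if (!setequal(precedence, labels) || length(precedence) != length(labels)) {
    stop("precedence must be a permutation of the envelope labels",
         call. = FALSE)
  }
  if (!is.numeric(sigma_threshold) || sigma_threshold <= 0) {
    stop("sigma_threshold must be positive", call. = FALSE)
  }
  names(envelopes) <- labels
  structure(list(envelopes = envelopes, precedence = precedence,
                 sigma_threshold = sigma_threshold),
            class = "envelope_table")
}

#' @export
print.envelope_table <- function(x, ...) {
  cat("Water-mass envelope table (", length(x$envelopes), " envelopes, ",
      "sigma threshold ", x$sigma_threshold, " kg m^-3)\n", sep = "")
  for (e in x$envelopes[x$precedence]) {
    cat(sprintf("  %-4s T [%s, %s)  S [%s, %s)%s\n", e$label,
                format(e$t_min), format(e$t_max),
                format(e$s_min), format(e$s_max),
                if (is.na(e$sigma_max)) ""
                else sprintf("  sigma < %s", format(e$sigma_max))))
  }
  invisible(x)
}

#' Read an envelope table from a YAML configuration file
#'
#' The file carries one mapping per label with keys `t_min`, `t_max`,
#' `s_min`, `s_max`, `sigma_max` (all optional) plus optional per-edge
#' closedness flags (`t_min_closed` etc.), a global `sigma_threshold`, and a
#' `precedence` list.  See the file returned by
#' `system.file("extdata", "envelopes.yaml", package = "fjordflux")` for the
#' shipped default.
#'
#' @param path path to a YAML file.
#' @return an `"envelope_table"`.
#' @export
read_envelope_config <- function(path) {
  if (!file.exists(path)) stop("envelope config not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$envelopes)) stop("envelope config lacks 'envelopes' block",
                                   call. = FALSE)
  envs <- lapply(names(cfg$envelopes), function(lab) {
    e <- cfg$envelopes[[lab]]
    flags <- e[grepl("_closed$", names(e))]
    closed <- NULL
    if (length(flags)) {
      closed <- setNames(as.logical(unlist(flags)),
                         sub("_closed$", "", names(flags)))
    }
    water_mass_envelope(
      label = lab,
      t_min = if (is.null(e$t_min)) -Inf else e$t_min,
      t_max = if (is.null(e$t_max)) Inf else e$t_max,
      s_min = if (is.null(e$s_min)) -Inf else e$s_min,
      s_max = if (is.null(e$s_max)) Inf else e$s_max,
      sigma_max = if (is.null(e$sigma_max)) NA else e$sigma_max,
      closed = closed)
  })
  envelope_table(envs,
                 precedence = cfg$precedence,
                 sigma_threshold = if (is.null(cfg$sigma_threshold)) 27.92
                                   else cfg$sigma_threshold)
}

#' The default Svalbard-type envelope table
#'
#' Bounds transcribed from the standard Svalbard fjord water-mass scheme of
#' Cottier et al. (2005, J. Geophys. Res. 110, C12005): Surface Water (SW),
#' Intermediate Water (IW), Atlantic Water (AW), Transformed Atlantic Water
#' (TAW), Arctic Water (ArW), Local Water (LW) and Winter-cooled Water
#' (WCW).  AW and TAW additionally require \eqn{\sigma_\theta} < 27.92
#' kg m\eqn{^{-3}}.  The numbers are configuration data, not constants in
#' code: edit a copy of the shipped YAML to change them.
#'
#' @return an `"envelope_table"`.
#' @export
default_envelope_table <- function() {
  read_envelope_config(system.file("extdata", "envelopes.yaml",
                                   package = "fjordflux", mustWork = TRUE))
}

# vectorized containment of (t, s, sigma) in one envelope; sigma ignored
# when use_sigma = FALSE (the T-S-box test of the fallback rule)
env_contains <- function(e, t, s, sigma = NULL, use_sigma = TRUE) {
  cl <- e$closed
  ok <- (if (cl[["t_min"]]) t >= e$t_min else t > e$t_min) &
        (if (cl[["t_max"]]) t <= e$t_max else t < e$t_max) &
        (if (cl[["s_min"]]) s >= e$s_min else s > e$s_min) &
        (if (cl[["s_max"]]) s <= e$s_max else s < e$s_max)
  if (use_sigma && !is.na(e$sigma_max)) {
    ok <- ok & (sigma < e$sigma_max)
  }
  ok
}
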