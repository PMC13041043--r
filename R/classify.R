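#' Classify hydrographic records into water masses
#'
#' Applies the decision ladder to each (temperature, salinity,
#' \eqn{\sigma_\theta}) record:
#'
#' 1. collect all envelopes whose full constraints (T, S, and density where
#'    defined) contain the record;
#' 2. exactly one match: that label;
#' 3. several matches: the first matching label in the table's `precedence`;
#' 4. no match, but the record sits inside the AW or TAW T-S limits with
#'    \eqn{\sigma_\theta \ge} `sigma_threshold`: AW (checked first) or TAW —
#'    dense but otherwise Atlantic-like water keeps its Atlantic label;
#' 5. no match, but salinity below the ArW lower salinity limit and
#'    temperature below the LW lower temperature limit: ArW (cold fresh
#'    polar water outside every box);
#' 6. otherwise `Unclassified` (retained, never dropped).
#'
#' Classification is a pure element-wise function: the label of one record
#' never depends on its neighbours.
#'
#' @param temperature,salinity numeric vectors (recycled to common length).
#' @param sigma_theta optional \eqn{\sigma_\theta} (kg m\eqn{^{-3}});
#'   computed with [compute_sigma_theta()] where `NA` or missing.
#' @param env an [envelope_table()].
#' @return factor of labels with levels `SW, IW, AW, TAW, ArW, LW, WCW,
#'   Unclassified`; attribute `"ambiguous"` holds the indices of records that
#'   matched more than one envelope (resolved by precedence).
#' @seealso [classify_record()] for a single record, [classify_ctd()] for a
#'   whole CTD table.
#' @export
classify_records <- function(temperature, salinity, sigma_theta = NULL,
                             env = default_envelope_table()) {
  if (!inherits(env, "envelope_table")) {
    stop("env must be an envelope_table", call. = FALSE)
  }
  n <- max(length(temperature), length(salinity))
  t <- rep_len(as.numeric(temperature), n)
  s <- rep_len(as.numeric(salinity), n)
  if (n == 0) {
    return(factor(character(0), levels = .wm_levels))
  }
  if (any(!is.finite(t)) || any(!is.finite(s))) {
    stop("temperature and salinity must be finite", call. = FALSE)
  }
  if (is.null(sigma_theta)) sigma_theta <- rep(NA_real_, n)
  sig <- rep_len(as.numeric(sigma_theta), n)
  miss <- is.na(sig)
  if (any(miss)) sig[miss] <- compute_sigma_theta(s[miss], t[miss])
  if (any(sig <= -5 | sig >= 50)) {
    stop("sigma_theta outside plausible range (-5, 50)", call. = FALSE)
  }

  envs <- env$envelopes[env$precedence]     # precedence order
  m <- vapply(envs, env_contains, logical(n), t = t, s = s, sigma = sig)
  m <- matrix(m, nrow = n)                  # n x k even when n == 1
  nmatch <- rowSums(m)

  lab <- rep("Unclassified", n)
  any_match <- nmatch >= 1
  if (any(any_match)) {
    first <- apply(m[any_match, , drop = FALSE], 1, which.max)
    lab[any_match] <- env$precedence[first]
  }

  none <- !any_match
  if (any(none)) {
    # rule 4: Atlantic-box records denser than the sigma threshold
    for (atl in c("AW", "TAW")) {
      e <- env$envelopes[[atl]]
      if (is.null(e)) next
      hit <- none & lab == "Unclassified" &
        env_contains(e, t, s, use_sigma = FALSE) &
        sig >= env$sigma_threshold
      lab[hit] <- atl
    }
    # rule 5: fresher than ArW and colder than LW
    arw <- env$envelopes[["ArW"]]
    lw <- env$envelopes[["LW"]]
    if (!is.null(arw) && !is.null(lw)) {
      hit <- none & lab == "Unclassified" & s < arw$s_min & t < lw$t_min
      lab[hit] <- "ArW"
    }
  }

  out <- factor(lab, levels = .wm_levels)
  attr(out, "ambiguous") <- which(nmatch > 1)
  out
}

#' Classify a single hydrographic record
#'
#' @param temperature,salinity scalars.
#' @param sigma_theta optional scalar \eqn{\sigma_\theta}; computed when
#'   missing.
#' @inheritParams classify_records
#' @return a single character label.
#' @examples
#' toy <- envelope_table(list(
#'   water_mass_envelope("AW", t_min = 3, s_min = 34.9, sigma_max = 27.92),
#'   water_mass_envelope("TAW", t_min = 1, t_max = 3, s_min = 34.7,
#'                       sigma_max = 27.92)))
#' classify_record(4, 35.1, 27.5, toy)   # "AW"
#' @export
classify_record <- function(temperature, salinity, sigma_theta = NA,
                            env = default_envelope_table()) {
  as.character(classify_records(temperature, salinity, sigma_theta, env))
}

#' Classify an ordered profile of records
#'
#' Element-wise application of the decision ladder to a data frame holding
#' one row per depth; input order is preserved.
#'
#' @param profile data frame with columns `temp_c`, `sal` and optionally
#'   `sigma_theta`.
#' @inheritParams classify_records
#' @return `profile` with a `water_mass` factor column appended.
#' @export
classify_profile <- function(profile, env = default_envelope_table()) {
  if (nrow(profile) == 0) {
    profile$water_mass <- factor(character(0), levels = .wm_levels)
    return(profile)
  }
  sig <- if ("sigma_theta" %in% names(profile)) profile$sigma_theta else NULL
  profile$water_mass <- classify_records(profile$temp_c, profile$sal, sig, env)
  profile
}

#' Classify a CTD table and audit the result
#'
#' @param ctd data frame with columns `station_id`, `region`, `year`,
#'   `depth_m`, `temp_c`, `sal`, optionally `sigma_theta`.
#' @inheritParams classify_records
#' @return the input with `sigma_theta` (filled where missing) and
#'   `water_mass` columns; attributes `n_unclassified` and `n_ambiguous`
#'   carry audit counts.
#' @export
classify_ctd <- function(ctd, env = default_envelope_table()) {
  req <- c("station_id", "region", "year", "depth_m", "temp_c", "sal")
  missing_cols <- setdiff(req, names(ctd))
  if (length(missing_cols)) {
    stop("CTD table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"sigma_theta" %in% names(ctd)) ctd$sigma_theta <- NA_real_
  fill <- is.na(ctd$sigma_theta)
  ctd$sigma_theta[fill] <- compute_sigma_theta(ctd$sal[fill], ctd$temp_c[fill])
  wm <- classify_records(ctd$temp_c, ctd$sal, ctd$sigma_theta, env)
  ctd$water_mass <- wm
  attr(ctd, "n_unclassified") <- sum(wm == "Unclassified")
  attr(ctd, "n_ambiguous") <- length(attr(wm, "ambiguous"))
  ctd
}
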