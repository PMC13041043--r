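#' Analyte names handled by the nutrient tables
#' @keywords internal
.analytes <- c("ammonium", "nitrate_nitrite", "nitrite", "phosphate",
               "silicic_acid", "chl_a")

#' Default analytical detection limits
#'
#' Limits in mmol m\eqn{^{-3}} for the spectrophotometric determinations:
#' 0.5 for nitrate (applied to the combined nitrate + nitrite channel),
#' 0.06 for nitrite and phosphate, 0.7 for silicic acid and 0.09 for
#' ammonium.
#'
#' @return named numeric vector of limits.
#' @export
default_detection_limits <- function() {
  c(nitrate_nitrite = 0.5, nitrite = 0.06, phosphate = 0.06,
    silicic_acid = 0.7, ammonium = 0.09)
}

#' Flag values below the analytical detection limit
#'
#' Values are flagged, never substituted: a measured 0.3 with a limit of 0.5
#' is kept at 0.3 with `bd_<analyte> = TRUE`.  The flag is strict
#' (`value < limit`); a value exactly at the limit is not flagged.  Missing
#' values get a missing flag.
#'
#' @param samples nutrient data frame with analyte columns (see
#'   [nutrient_schema()]).
#' @param limits named vector of per-analyte limits; defaults to
#'   [default_detection_limits()].
#' @return `samples` with logical `bd_<analyte>` columns appended.
#' @export
flag_below_detection <- function(samples, limits = default_detection_limits()) {
  if (any(limits <= 0, na.rm = TRUE)) {
    stop("detection limits must be positive", call. = FALSE)
  }
  for (a in intersect(names(limits), names(samples))) {
    samples[[paste0("bd_", a)]] <- samples[[a]] < limits[[a]]
  }
  samples
}

#' Aggregate bottle samples to station-level medians
#'
#' Measurements taken at multiple depths within one station are vertically
#' autocorrelated, so they are collapsed to one median per (region, year,
#' water mass, station) cell; those cells are then treated as independent
#' observations by the downstream tests.  `Unclassified` samples are
#' excluded.  Medians are computed per analyte over the non-missing values.
#'
#' @param samples nutrient data frame with `station_id`, `region`, `year`,
#'   `depth_m` and analyte columns.
#' @param water_mass vector of water-mass labels, one per row of `samples`
#'   (or a `water_mass` column already present).
#' @return data frame with one row per cell: `region`, `year`, `water_mass`,
#'   `station_id`, `n_samples`, and one median column per analyte.
#' @export
aggregate_station_medians <- function(samples, water_mass = samples$water_mass) {
  if (is.null(water_mass)) {
    stop("water_mass labels are required (argument or column)", call. = FALSE)
  }
  if (length(water_mass) != nrow(samples)) {
    stop("one water-mass label per sample is required", call. = FALSE)
  }
  keep <- !is.na(water_mass) & water_mass != "Unclassified"
  samples <- samples[keep, , drop = FALSE]
  wm <- as.character(water_mass)[keep]
  if (nrow(samples) == 0) {
    out <- data.frame(region = character(0), year = integer(0),
                      water_mass = character(0), station_id = character(0),
                      n_samples = integer(0))
    for (a in .analytes) out[[a]] <- numeric(0)
    return(out)
  }
  key <- interaction(samples$region, samples$year, wm, samples$station_id,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(samples)), key)
  rows <- lapply(idx, function(i) {
    cell <- data.frame(region = samples$region[i[1]],
                       year = samples$year[i[1]],
                       water_mass = wm[i[1]],
                       station_id = samples$station_id[i[1]],
                       n_samples = length(i),
                       stringsAsFactors = FALSE)
    for (a in intersect(.analytes, names(samples))) {
      v <- samples[[a]][i]
      cell[[a]] <- if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
    }
    cell
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics for one analyte in one water mass
#'
#' Median, quartiles (type-7 linear interpolation of order statistics),
#' arithmetic mean and a percentile-bootstrap confidence interval for the
#' mean, over station-level median cells.
#'
#' @param cells output of [aggregate_station_medians()] (already filtered to
#'   one water mass / group of interest).
#' @param analyte analyte column name.
#' @param b,level,seed passed to [bootstrap_ci()].
#' @return one-row data frame: `analyte`, `n`, `median`, `q25`, `q75`,
#'   `mean`, `ci_low`, `ci_high`.
#' @export
summarize_water_mass <- function(cells, analyte, b = 9999, level = 0.95,
                                 seed = 20160725) {
  v <- cells[[analyte]]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no data for analyte ", analyte, call. = FALSE)
  ci <- if (length(v) == 1) c(low = v, high = v)
        else suppressWarnings(bootstrap_ci(v, b = b, level = level,
                                           seed = seed))
  qs <- unname(quantile(v, c(0.25, 0.75), type = 7))
  data.frame(analyte = analyte, n = length(v),
             median = median(v), q25 = qs[1], q75 = qs[2],
             mean = mean(v), ci_low = unname(ci["low"]),
             ci_high = unname(ci["high"]))
}

#' Stoichiometric nutrient ratios
#'
#' DIN (dissolved inorganic nitrogen) is the nitrate + nitrite channel plus
#' ammonium.  Returns DIN:P (against phosphate) and DIN:Si (against silicic
#' acid), plus a flag for DIN:P exceeding the canonical Redfield N:P atom
#' ratio of 16.  A zero or missing denominator yields a missing ratio and a
#' `ratio_undefined` flag.
#'
#' @param samples data frame with `nitrate_nitrite`, `ammonium`,
#'   `phosphate`, `silicic_acid` columns.
#' @return data frame with `din`, `din_p`, `din_si`, `redfield_excess`,
#'   `din_p_undefined`, `din_si_undefined`.
#' @export
stoichiometric_ratios <- function(samples) {
  din <- samples$nitrate_nitrite + samples$ammonium
  p <- samples$phosphate
  si <- samples$silicic_acid
  din_p <- ifelse(!is.na(p) & p > 0, din / p, NA_real_)
  din_si <- ifelse(!is.na(si) & si > 0, din / si, NA_real_)
  data.frame(din = din,
             din_p = din_p,
             din_si = din_si,
             redfield_excess = ifelse(is.na(din_p), NA, din_p > 16),
             din_p_undefined = is.na(din_p),
             din_si_undefined = is.na(din_si))
}

#' Attach water-mass labels (and bottle salinity) to a nutrient table
#'
#' Merges the `water_mass` column — and `sal`, if the nutrient table lacks
#' one — from a classified CTD table ([classify_ctd()]) by
#' (station, region, year, depth).
#'
#' @param nutrients nutrient data frame.
#' @param ctd classified CTD data frame with a `water_mass` column.
#' @return `nutrients` with `water_mass` (and possibly `sal`) appended;
#'   rows without a matching CTD record get `NA`.
#' @export
attach_water_mass <- function(nutrients, ctd) {
  key <- function(df) paste(df$station_id, df$region, df$year, df$depth_m,
                            sep = "\r")
  idx <- match(key(nutrients), key(ctd))
  nutrients$water_mass <- as.character(ctd$water_mass)[idx]
  if (!"sal" %in% names(nutrients)) nutrients$sal <- ctd$sal[idx]
  nutrients
}

#' Compare analyte concentrations between two regions per water mass
#'
#' For every analyte and every water mass present in both regions (with at
#' least one station cell on each side), runs [mann_whitney_u()] on the
#' station-level medians and applies [benjamini_hochberg()] across all tests
#' performed.  Water masses present in only one region are skipped, matching
#' the dashes of a two-fjord summary table.
#'
#' @param cells output of [aggregate_station_medians()] covering both
#'   regions (station filtering, e.g. fjord-only rosters, is the caller's
#'   responsibility).
#' @param region_a,region_b the two region names to compare.
#' @param analytes analyte columns to test; defaults to all present.
#' @return data frame with one row per (analyte, water mass) tested:
#'   `analyte`, `water_mass`, `n1`, `n2`, `u_statistic`, `p`, `p_corr`,
#'   `direction` (region name of the larger sample or `"none"`).
#' @export
compare_fjords <- function(cells, region_a, region_b,
                           analytes = intersect(.analytes, names(cells))) {
  rows <- list()
  for (a in analytes) {
    for (wm in unique(cells$water_mass)) {
      va <- cells[[a]][cells$region == region_a & cells$water_mass == wm]
      vb <- cells[[a]][cells$region == region_b & cells$water_mass == wm]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) == 0 || length(vb) == 0) next
      tst <- mann_whitney_u(va, vb)
      rows[[length(rows) + 1]] <- data.frame(
        analyte = a, water_mass = wm,
        n1 = tst$n1, n2 = tst$n2,
        u_statistic = tst$u_statistic, p = tst$p,
        direction = switch(tst$direction, x = region_a, y = region_b,
                           none = "none"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(analyte = character(0), water_mass = character(0),
                      n1 = integer(0), n2 = integer(0),
                      u_statistic = numeric(0), p = numeric(0),
                      p_corr = numeric(0), direction = character(0)))
  }
  out <- do.call(rbind, rows)
  out$p_corr <- benjamini_hochberg(out$p)
  out[, c("analyte", "water_mass", "n1", "n2", "u_statistic", "p", "p_corr",
          "direction")]
}
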