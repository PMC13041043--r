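#' Two-endmember conservative mixing source/sink estimator
#'
#' An observed fjord concentration is compared with the concentration
#' expected if the fjord water were a purely conservative blend of the
#' marine (shelf) water and a freshwater endmember:
#' \deqn{Sources - Sinks = C_{fjord} - \left[C_0 + (S_{fjord} - S_0)
#'   \frac{C_{shelf} - C_0}{S_{shelf} - S_0}\right]}
#' where the subscript 0 marks the freshwater endmember.  Negative values
#' indicate a biogeochemical sink, positive a source.  With the default
#' zero-salinity, zero-concentration freshwater endmember the dilution
#' effect of freshwater is biased positively, making sinks conservative
#' (harder to detect), not spurious.
#'
#' @param c_fjord,s_fjord mean concentration and salinity on the fjord side.
#' @param c_shelf,s_shelf mean concentration and salinity on the shelf side.
#' @param s0,c0 freshwater endmember salinity and concentration (default 0).
#' @return the source-minus-sink estimate, in the concentration units of the
#'   inputs (mmol m\eqn{^{-3}} numerically \eqn{\approx} \eqn{\mu}mol
#'   kg\eqn{^{-1}} for seawater).
#' @examples
#' source_sink(c_fjord = 5, s_fjord = 34, c_shelf = 8, s_shelf = 35) # -2.771
#' @export
source_sink <- function(c_fjord, s_fjord, c_shelf, s_shelf,
                        s0 = 0, c0 = 0) {
  if (any(s_shelf == s0)) {
    stop("shelf salinity equals the freshwater endmember salinity: ",
         "dilution line undefined", call. = FALSE)
  }
  c_cons <- c0 + (s_fjord - s0) * (c_shelf - c0) / (s_shelf - s0)
  c_fjord - c_cons
}

#' Side means entering the source/sink estimator
#'
#' Arithmetic means of salinity and of one analyte over all bottle samples
#' that (a) belong to the stated station roster, (b) were classified into
#' the stated water mass, and (c) lie at or above the depth cutoff
#' (default 100 m).
#'
#' @param samples nutrient table with `station_id`, `depth_m`, `sal`,
#'   analyte columns and a `water_mass` column.
#' @param shelf_stations,fjord_stations character vectors of station ids.
#' @param shelf_wm,fjord_wm water-mass label required on each side.
#' @param analyte analyte column name.
#' @param depth_cutoff maximum depth in metres (default 100).
#' @return list with `c_fjord`, `s_fjord`, `c_shelf`, `s_shelf`,
#'   `n_fjord`, `n_shelf`, `shelf_wm`, `fjord_wm`, `analyte`.
#' @export
compute_pair_means <- function(samples, shelf_stations, fjord_stations,
                               shelf_wm, fjord_wm, analyte,
                               depth_cutoff = 100) {
  if (depth_cutoff <= 0) stop("depth_cutoff must be positive", call. = FALSE)
  side <- function(stations, wm, side_name) {
    sel <- samples$station_id %in% stations &
      samples$water_mass == wm &
      samples$depth_m <= depth_cutoff &
      !is.na(samples[[analyte]]) & !is.na(samples$sal)
    if (!any(sel)) {
      stop(sprintf("no qualifying %s samples (water mass %s, analyte %s)",
                   side_name, wm, analyte), call. = FALSE)
    }
    list(c = mean(samples[[analyte]][sel]), s = mean(samples$sal[sel]),
         n = sum(sel))
  }
  sh <- side(shelf_stations, shelf_wm, "shelf")
  fj <- side(fjord_stations, fjord_wm, "fjord")
  list(c_fjord = fj$c, s_fjord = fj$s, c_shelf = sh$c, s_shelf = sh$s,
       n_fjord = fj$n, n_shelf = sh$n,
       shelf_wm = shelf_wm, fjord_wm = fjord_wm, analyte = analyte)
}

#' Source/sink table over a station-role configuration
#'
#' Evaluates [source_sink()] for every (region, year, water-mass pair)
#' requested in a station-role configuration (see [read_station_roles()]),
#' producing a table shaped like a per-analyte budget: one row per pair.
#' Pairs whose sides have no qualifying samples are reported with `NA`.
#'
#' @param samples nutrient table with a `water_mass` column (already
#'   classified).
#' @param roles station-role configuration list: per region, `shelf` and
#'   `fjord` station vectors and a `pairs` list of
#'   `(year, shelf_wm, fjord_wm)` entries.
#' @param analyte analyte column.
#' @param depth_cutoff maximum depth (m), default 100.
#' @param s0,c0 freshwater endmember, default (0, 0).
#' @return data frame: `region`, `year`, `shelf_wm`, `fjord_wm`, `analyte`,
#'   `s_shelf`, `c_shelf`, `s_fjord`, `c_fjord`, `n_shelf`, `n_fjord`,
#'   `source_sink`.
#' @export
source_sink_table <- function(samples, roles, analyte, depth_cutoff = 100,
                              s0 = 0, c0 = 0) {
  rows <- list()
  for (region in names(roles)) {
    rg <- roles[[region]]
    for (pair in rg$pairs) {
      sel_year <- samples$year == pair$year
      pm <- tryCatch(
        compute_pair_means(samples[sel_year, , drop = FALSE],
                           shelf_stations = rg$shelf,
                           fjord_stations = rg$fjord,
                           shelf_wm = pair$shelf_wm,
                           fjord_wm = pair$fjord_wm,
                           analyte = analyte, depth_cutoff = depth_cutoff),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        region = region, year = pair$year,
        shelf_wm = pair$shelf_wm, fjord_wm = pair$fjord_wm,
        analyte = analyte,
        s_shelf = if (is.null(pm)) NA_real_ else pm$s_shelf,
        c_shelf = if (is.null(pm)) NA_real_ else pm$c_shelf,
        s_fjord = if (is.null(pm)) NA_real_ else pm$s_fjord,
        c_fjord = if (is.null(pm)) NA_real_ else pm$c_fjord,
        n_shelf = if (is.null(pm)) NA_integer_ else pm$n_shelf,
        n_fjord = if (is.null(pm)) NA_integer_ else pm$n_fjord,
        source_sink = if (is.null(pm)) NA_real_ else
          source_sink(pm$c_fjord, pm$s_fjord, pm$c_shelf, pm$s_shelf,
                      s0 = s0, c0 = c0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
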