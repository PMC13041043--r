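#' Transect simulation configuration
#'
#' Describes a two-region, two-year study in which every water property is
#' a two-endmember blend: salinity and each nutrient follow
#' `C = f * C_marine + (1 - f) * C_fresh` with mixing fraction `f` set by
#' the layer's target salinity.  Fjord stations are slightly fresher than
#' shelf stations in the upper layers, and a uniform biogeochemical sink
#' `sink_delta` is subtracted from fjord-side nutrient concentrations in
#' the top 100 m.  The default layer structure covers all seven water-mass
#' envelopes across the two regions.
#'
#' @param sink_delta imposed uniform sink (concentration units) on fjord
#'   upper-100 m nutrients; default 0.
#' @param noise_sd per-analyte Gaussian noise standard deviation (truncated
#'   at zero); default 0 for all analytes.
#' @param ts_noise_sd noise on temperature and salinity; default 0.
#' @param marine,fresh endmember lists with `S` and per-analyte `C`.
#' @param year_t_offset temperature offset applied in the second year
#'   (default 0.3 degrees C — a warm anomaly that keeps all layers inside
#'   their envelopes).
#' @param seed integer seed.
#' @return list of class `"transect_config"`.
#' @export
transect_config <- function(sink_delta = 0, noise_sd = NULL,
                            ts_noise_sd = 0,
                            marine = NULL, fresh = NULL,
                            year_t_offset = 0.3, seed = 1) {
  analytes <- setdiff(.analytes, "chl_a")
  if (is.null(marine)) {
    marine <- list(S = 35, C = c(ammonium = 0.6, nitrate_nitrite = 9,
                                 nitrite = 0.15, phosphate = 0.8,
                                 silicic_acid = 6))
  }
  if (is.null(fresh)) {
    fresh <- list(S = 0, C = setNames(rep(0, length(analytes)), analytes))
  }
  nz <- setNames(rep(0, length(analytes)), analytes)
  if (!is.null(noise_sd)) nz[names(noise_sd)] <- noise_sd
  if (sink_delta < 0) stop("sink_delta must be >= 0", call. = FALSE)
  structure(list(sink_delta = sink_delta, noise_sd = nz,
                 ts_noise_sd = ts_noise_sd, marine = marine, fresh = fresh,
                 year_t_offset = year_t_offset, seed = seed,
                 analytes = analytes),
            class = "transect_config")
}

# layer tables: depth (m), temperature, target salinity on the shelf and in
# the fjord, and the water mass the layer is designed to classify as under
# the default envelopes
transect_layers <- function() {
  k <- data.frame(
    depth_m = c(5, 20, 30, 50, 75, 100, 150, 500),
    temp_c = c(3.5, 3.5, 2.0, 2.0, 4.0, 4.0, 2.0, -1.0),
    s_shelf = c(33.8, 33.9, 34.4, 34.5, 35.0, 35.0, 34.8, 34.9),
    s_fjord = c(33.0, 33.2, 34.2, 34.3, 34.95, 34.95, 34.8, 34.9),
    target_wm = c("SW", "SW", "IW", "IW", "AW", "AW", "TAW", "WCW"))
  r <- data.frame(
    depth_m = c(5, 20, 30, 50, 75, 100, 150, 500),
    temp_c = c(1.5, 1.5, 0.0, 0.0, 0.2, 0.2, 0.5, -1.0),
    s_shelf = c(33.5, 33.8, 34.5, 34.55, 34.6, 34.6, 34.85, 34.9),
    s_fjord = c(33.0, 33.3, 34.42, 34.45, 34.5, 34.5, 34.85, 34.9),
    target_wm = c("SW", "SW", "ArW", "ArW", "ArW", "ArW", "LW", "WCW"))
  list(Kongsfjorden = k, Rijpfjorden = r)
}

transect_stations <- function() {
  list(Kongsfjorden = list(fjord = paste0("Kb", 0:5),
                           shelf = c("V10", "V12", "V14")),
       Rijpfjorden = list(fjord = paste0("R", 1:3),
                          shelf = c("R4", "R5", "R6", "R6-b", "R7", "R7-b")))
}

#' Generate synthetic CTD and nutrient tables
#'
#' @param cfg a [transect_config()].
#' @param years years simulated (default 2016:2017).
#' @return list with `ctd` (station/depth/T/S/sigma table), `nutrients`
#'   (same grid with bottle salinity and analyte concentrations) and
#'   `truth` (endmembers, sink, per-row mixing fraction and intended water
#'   mass).
#' @export
generate_profiles <- function(cfg = transect_config(), years = 2016:2017) {
  layers <- transect_layers()
  stations <- transect_stations()
  rows <- list()
  for (region in names(layers)) {
    lay <- layers[[region]]
    for (year in years) {
      t_off <- if (year == max(years) && length(years) > 1)
        cfg$year_t_offset else 0
      for (role in c("fjord", "shelf")) {
        for (st in stations[[region]][[role]]) {
          s <- if (role == "fjord") lay$s_fjord else lay$s_shelf
          rows[[length(rows) + 1]] <- data.frame(
            station_id = st, region = region, year = year, role = role,
            depth_m = lay$depth_m, temp_c = lay$temp_c + t_off,
            sal = s, target_wm = lay$target_wm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  f <- (grid$sal - cfg$fresh$S) / (cfg$marine$S - cfg$fresh$S)

  out <- with_seed(cfg$seed, {
    if (cfg$ts_noise_sd > 0) {
      grid$temp_c <- grid$temp_c + rnorm(nrow(grid), 0, cfg$ts_noise_sd)
      grid$sal <- pmax(0, grid$sal + rnorm(nrow(grid), 0, cfg$ts_noise_sd))
    }
    nutrients <- grid[, c("station_id", "region", "year", "depth_m", "sal")]
    for (a in cfg$analytes) {
      conc <- f * cfg$marine$C[[a]] + (1 - f) * cfg$fresh$C[[a]]
      sink <- grid$role == "fjord" & grid$depth_m <= 100
      conc[sink] <- pmax(0, conc[sink] - cfg$sink_delta)
      if (cfg$noise_sd[[a]] > 0) {
        conc <- pmax(0, conc + rnorm(length(conc), 0, cfg$noise_sd[[a]]))
      }
      nutrients[[a]] <- conc
    }
    # chlorophyll: surface-peaked, independent of the mixing structure
    nutrients$chl_a <- round(1.2 * exp(-grid$depth_m / 40) + 0.05, 4)
    list(grid = grid, nutrients = nutrients)
  })
  ctd <- out$grid[, c("station_id", "region", "year", "depth_m",
                      "temp_c", "sal")]
  ctd$sigma_theta <- compute_sigma_theta(ctd$sal, ctd$temp_c)
  truth <- list(marine = cfg$marine, fresh = cfg$fresh,
                sink_delta = cfg$sink_delta,
                mixing_fraction = f,
                target_wm = out$grid$target_wm,
                role = out$grid$role)
  list(ctd = ctd, nutrients = out$nutrients, truth = truth)
}

#' Community simulation configuration
#'
#' Water-mass-specific Dirichlet-multinomial compositions with a nitrifier
#' fraction that grows with depth: sample proportions are
#' `(1 - g) * base(wm) + g * nitrifier_mix` with
#' `g = g_max * depth / (depth + half_sat)`, then Dirichlet-perturbed with
#' the given concentration parameter and sampled multinomially at the given
#' sequencing depth.
#'
#' @param concentration Dirichlet concentration (default 200; larger =
#'   closer to the mean composition).
#' @param seq_depth reads per sample (default 50000).
#' @param g_max maximal nitrifier fraction at depth (default 0.3).
#' @param half_sat depth (m) at which half of `g_max` is reached
#'   (default 150).
#' @param n_base number of non-nitrifier ASVs (default 49, seven blocks of
#'   seven, one block favoured per water mass).
#' @param wm_means optional named list overriding the per-water-mass mean
#'   composition: one probability vector of length `n_base` per water-mass
#'   label (normalized internally).  Default: block structure with an
#'   8:1 weight on the water mass's own block.
#' @param seed integer seed.
#' @return list of class `"community_config"`.
#' @export
community_config <- function(concentration = 200, seq_depth = 50000,
                             g_max = 0.3, half_sat = 150, n_base = 49,
                             wm_means = NULL, seed = 1) {
  if (!is.null(wm_means)) {
    if (any(vapply(wm_means, length, 1L) != n_base)) {
      stop("each wm_means entry must have length n_base", call. = FALSE)
    }
    wm_means <- lapply(wm_means, function(p) p / sum(p))
  }
  structure(list(concentration = concentration, seq_depth = seq_depth,
                 g_max = g_max, half_sat = half_sat, n_base = n_base,
                 wm_means = wm_means, seed = seed),
            class = "community_config")
}

synthetic_taxonomy <- function(n_base) {
  phyla <- c("Proteobacteria", "Bacteroidota", "Verrucomicrobiota",
             "Actinobacteriota", "Planctomycetota", "Chloroflexi",
             "Firmicutes")
  base <- data.frame(
    asv_id = sprintf("asv%03d", seq_len(n_base)),
    domain = "Bacteria",
    phylum = phyla[(seq_len(n_base) - 1) %% length(phyla) + 1],
    class = NA_character_, order = NA_character_,
    family = NA_character_, genus = NA_character_,
    stringsAsFactors = FALSE)
  nitr <- data.frame(
    asv_id = c("aoa1", "aoa2", "aoa3", "aob1", "aob2", "aob3",
               "nob1", "nob2", "nob3"),
    domain = c(rep("Archaea", 3), rep("Bacteria", 6)),
    phylum = c(rep("Thermoproteota", 3), rep("Proteobacteria", 3),
               "Nitrospinota", "Nitrospirota", "Proteobacteria"),
    class = c(rep("Nitrososphaeria", 3), rep("Gammaproteobacteria", 3),
              NA, NA, "Alphaproteobacteria"),
    order = NA_character_,
    family = c(rep(NA, 3), "Nitrosomonadaceae", "Nitrosomonadaceae",
               NA, NA, NA, NA),
    genus = c("Nitrosopumilus", "Nitrosopelagicus", NA, NA, NA,
              "Nitrosococcus", NA, NA, "Nitrobacter"),
    stringsAsFactors = FALSE)
  rbind(base, nitr)
}

#' Generate a synthetic taxa table
#'
#' @param cfg a [community_config()].
#' @param meta sample metadata data frame with `sample_id`, `region`,
#'   `year`, `depth_m`, `water_mass`.
#' @return a [taxa_table()]; the attribute `"truth"` stores the expected
#'   (noise-free) composition per sample and the nitrifier fraction.
#' @export
generate_taxa_table <- function(cfg = community_config(), meta) {
  tax <- synthetic_taxonomy(cfg$n_base)
  n_asv <- nrow(tax)
  is_nitr <- grepl("^(aoa|aob|nob)", tax$asv_id)
  wms <- setdiff(.wm_levels, "Unclassified")
  n_blocks <- length(wms)
  block <- ((seq_len(cfg$n_base) - 1) %/%
              ceiling(cfg$n_base / n_blocks)) + 1
  if (is.null(cfg$wm_means)) {
    base_means <- lapply(seq_along(wms), function(w) {
      wt <- ifelse(block == ((w - 1) %% max(block)) + 1, 8, 1)
      wt / sum(wt)
    })
    names(base_means) <- wms
  } else {
    base_means <- cfg$wm_means
  }
  nitr_mix <- c(0.30, 0.20, 0.10, 0.12, 0.08, 0.05, 0.06, 0.05, 0.04)
  nitr_mix <- nitr_mix / sum(nitr_mix)

  expected <- matrix(0, nrow(meta), n_asv,
                     dimnames = list(meta$sample_id, tax$asv_id))
  g_all <- numeric(nrow(meta))
  counts <- with_seed(cfg$seed, {
    m <- matrix(0L, nrow(meta), n_asv,
                dimnames = list(meta$sample_id, tax$asv_id))
    for (i in seq_len(nrow(meta))) {
      wm <- as.character(meta$water_mass[i])
      if (!wm %in% names(base_means)) {
        stop("no configured composition for water mass ", wm, call. = FALSE)
      }
      g <- cfg$g_max * meta$depth_m[i] / (meta$depth_m[i] + cfg$half_sat)
      g_all[i] <- g
      p <- numeric(n_asv)
      p[!is_nitr] <- (1 - g) * base_means[[wm]]
      p[is_nitr] <- g * nitr_mix
      expected[i, ] <- p
      alpha <- cfg$concentration * p
      gam <- rgamma(n_asv, shape = pmax(alpha, 1e-8))
      m[i, ] <- as.integer(rmultinom(1, cfg$seq_depth, gam / sum(gam)))
    }
    m
  })
  tt <- taxa_table(counts, tax, meta)
  attr(tt, "truth") <- list(expected = expected,
                            nitrifier_fraction = setNames(g_all,
                                                          meta$sample_id))
  tt
}

#' Gene count simulation configuration
#'
#' @param copy_numbers named vector of true per-genome copy numbers for the
#'   panel genes (reference genes are fixed at 1).
#' @param ref_coverage reference single-copy coverage in reads per bp
#'   (default 2).
#' @param scale multiplier on expected reads (sequencing depth knob,
#'   default 1).
#' @param seed integer seed.
#' @return list of class `"genesim_config"`.
#' @export
genesim_config <- function(copy_numbers = NULL, ref_coverage = 2, scale = 1,
                           seed = 1) {
  if (is.null(copy_numbers)) {
    panel <- default_gene_panel()
    copy_numbers <- setNames(
      c(0.05, 0.5, 0.4, 0.3, 0.1, 0.15, 0.12, 0.02, 0.2, 0.25, 0.05, 0.08),
      names(panel$processes))
  }
  structure(list(copy_numbers = copy_numbers, ref_coverage = ref_coverage,
                 scale = scale, seed = seed),
            class = "genesim_config")
}

.gene_lengths <- c(
  nifH = 870, amoA = 750, amoB = 630, hao = 1710, nosZ = 1900, nirK = 1130,
  norB = 1390, hdh = 1600, napA = 2500, nirD = 340, narB = 2200,
  nasA = 2400, recA = 1060, gyrB = 2420, rpoB = 4100)

#' Generate a synthetic gene count table
#'
#' Mapped reads are Poisson with mean
#' `copy_number * ref_coverage * gene_length * scale`; the three reference
#' genes are generated at copy number 1, so the true ACN of each panel gene
#' equals its configured copy number.
#'
#' @param cfg a [genesim_config()].
#' @param sample_ids character vector of sample names.
#' @return data frame with `sample_id`, `gene_symbol`, `contig_id`,
#'   `mapped_reads`, `gene_length_bp`; attribute `"truth"` holds the copy
#'   numbers.
#' @export
generate_gene_counts <- function(cfg = genesim_config(),
                                 sample_ids = paste0("S", 1:4)) {
  cn <- c(cfg$copy_numbers,
          setNames(rep(1, 3), c("recA", "gyrB", "rpoB")))
  genes <- names(cn)
  lens <- .gene_lengths[genes]
  rows <- with_seed(cfg$seed, {
    do.call(rbind, lapply(sample_ids, function(sid) {
      mu <- cn * cfg$ref_coverage * lens * cfg$scale
      data.frame(sample_id = sid, gene_symbol = genes,
                 contig_id = paste0(sid, "_", genes, "_c1"),
                 mapped_reads = rpois(length(mu), mu),
                 gene_length_bp = unname(lens), stringsAsFactors = FALSE)
    }))
  })
  rownames(rows) <- NULL
  attr(rows, "truth") <- cn
  rows
}

#' Write a complete coherent synthetic study to a directory
#'
#' Generates CTD, nutrient, taxa and gene tables for a two-region,
#' two-year study, together with the envelope, station-role and gene-panel
#' configuration files, so that every command-line entry point runs on the
#' directory unmodified.  All randomness derives from `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param sink_delta imposed fjord upper-100 m nutrient sink (default 1).
#' @param noise_sd optional named per-analyte noise SDs.
#' @return invisibly, a named list of the file paths written plus the truth
#'   records (also serialized to `truth.json`).
#' @export
generate_full_study <- function(out_dir, seed = 1, sink_delta = 1,
                                noise_sd = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- transect_config(sink_delta = sink_delta, noise_sd = noise_sd,
                         seed = seed)
  prof <- generate_profiles(cfg)

  # community samples: three depths per fjord station plus deep stations
  ctd <- prof$ctd
  sel <- ctd$depth_m %in% c(5, 50, 500)
  meta <- data.frame(
    sample_id = sprintf("%s_%d_%dm", ctd$station_id[sel], ctd$year[sel],
                        ctd$depth_m[sel]),
    region = ctd$region[sel], year = ctd$year[sel],
    depth_m = ctd$depth_m[sel],
    water_mass = as.character(
      classify_records(ctd$temp_c[sel], ctd$sal[sel],
                       ctd$sigma_theta[sel])),
    stringsAsFactors = FALSE)
  meta <- meta[meta$water_mass != "Unclassified", , drop = FALSE]
  tt <- generate_taxa_table(community_config(seed = seed + 1), meta)
  genes <- generate_gene_counts(genesim_config(seed = seed + 2),
                                sample_ids = meta$sample_id[
                                  meta$depth_m %in% c(5, 500)])

  paths <- list(
    ctd = file.path(out_dir, "ctd.csv"),
    nutrients = file.path(out_dir, "nutrients.csv"),
    taxa_counts = file.path(out_dir, "taxa_counts.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    sample_meta = file.path(out_dir, "sample_meta.tsv"),
    gene_counts = file.path(out_dir, "gene_counts.tsv"),
    envelopes = file.path(out_dir, "envelopes.yaml"),
    station_roles = file.path(out_dir, "station_roles.yaml"),
    gene_panel = file.path(out_dir, "gene_panel.yaml"),
    truth = file.path(out_dir, "truth.json"))

  write_table(prof$ctd, paths$ctd)
  write_table(prof$nutrients, paths$nutrients)
  counts_out <- data.frame(asv_id = colnames(tt$counts),
                           t(tt$counts), check.names = FALSE)
  write_table(counts_out, paths$taxa_counts)
  write_table(tt$taxonomy, paths$taxonomy)
  write_table(tt$meta, paths$sample_meta)
  write_table(genes, paths$gene_counts)
  file.copy(system.file("extdata", "envelopes.yaml", package = "fjordflux",
                        mustWork = TRUE), paths$envelopes, overwrite = TRUE)
  file.copy(system.file("extdata", "station_roles.yaml",
                        package = "fjordflux", mustWork = TRUE),
            paths$station_roles, overwrite = TRUE)
  file.copy(system.file("extdata", "gene_panel.yaml", package = "fjordflux",
                        mustWork = TRUE), paths$gene_panel, overwrite = TRUE)
  truth <- list(profiles = prof$truth[c("marine", "fresh", "sink_delta")],
                gene_copy_numbers = as.list(attr(genes, "truth")),
                seed = seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth_record = truth)))
}
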