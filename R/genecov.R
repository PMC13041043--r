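#' Default nitrogen-cycle gene panel
#'
#' Maps marker genes to nitrogen-cycle processes: nifH (nitrogen fixation);
#' amoA, amoB, hao (nitrification); nosZ, nirK, norB (denitrification); hdh
#' (anammox); napA, nirD (dissimilatory nitrate/nitrite reduction); narB,
#' nasA (assimilatory nitrate reduction).  Reference single-copy genes for
#' normalization are recA, gyrB and rpoB; they are not panel members.
#'
#' @return list with `processes` (named character vector gene -> process)
#'   and `reference` (character vector).
#' @export
default_gene_panel <- function() {
  list(
    processes = c(
      nifH = "nitrogen_fixation",
      amoA = "nitrification", amoB = "nitrification", hao = "nitrification",
      nosZ = "denitrification", nirK = "denitrification",
      norB = "denitrification",
      hdh = "anammox",
      napA = "nitrate_nitrite_reduction", nirD = "nitrate_nitrite_reduction",
      narB = "assimilatory_nitrate_reduction",
      nasA = "assimilatory_nitrate_reduction"),
    reference = c("recA", "gyrB", "rpoB")
  )
}

#' Read a gene panel from YAML
#'
#' Expected keys: `processes` (mapping gene -> process name) and
#' `reference` (list of single-copy reference genes).
#'
#' @param path YAML file path.
#' @return panel list as from [default_gene_panel()].
#' @export
read_gene_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$processes) || is.null(cfg$reference)) {
    stop("gene panel needs 'processes' and 'reference' blocks", call. = FALSE)
  }
  panel <- list(processes = unlist(cfg$processes),
                reference = as.character(unlist(cfg$reference)))
  clash <- intersect(tolower(names(panel$processes)),
                     tolower(panel$reference))
  if (length(clash)) {
    stop("reference gene also in process panel: ", clash[1], call. = FALSE)
  }
  panel
}

#' Per-gene coverage from mapped-read counts
#'
#' Coverage is mapped reads divided by gene length (reads per bp).  When a
#' gene is annotated on several contigs in one sample the default pools
#' them as total reads over total length (length-weighted); `pool = "mean"`
#' instead averages the per-contig coverages.
#'
#' @param counts data frame with `sample_id`, `gene_symbol`,
#'   `mapped_reads`, `gene_length_bp` and optionally `contig_id`.
#' @param pool `"length_weighted"` (default) or `"mean"`.
#' @return data frame with one row per (sample, gene): `sample_id`,
#'   `gene_symbol`, `coverage`.
#' @export
gene_coverage <- function(counts, pool = c("length_weighted", "mean")) {
  pool <- match.arg(pool)
  if (any(counts$gene_length_bp <= 0)) {
    stop("gene_length_bp must be positive", call. = FALSE)
  }
  if (any(counts$mapped_reads < 0)) {
    stop("mapped_reads must be non-negative", call. = FALSE)
  }
  key <- interaction(counts$sample_id, counts$gene_symbol, drop = TRUE)
  idx <- split(seq_len(nrow(counts)), key)
  rows <- lapply(idx, function(i) {
    cov <- if (pool == "length_weighted") {
      sum(counts$mapped_reads[i]) / sum(counts$gene_length_bp[i])
    } else {
      mean(counts$mapped_reads[i] / counts$gene_length_bp[i])
    }
    data.frame(sample_id = counts$sample_id[i[1]],
               gene_symbol = counts$gene_symbol[i[1]],
               coverage = cov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average Genomic Copy Number normalization
#'
#' Divides each gene's coverage by the mean coverage of the single-copy
#' reference genes detected in the same sample, yielding copies per genome
#' equivalent.  The normalization uses whichever of the reference genes are
#' present (at least one with positive coverage); the number used is
#' reported per sample.  Samples without any positive-coverage reference
#' gene get `NA` ACNs and are flagged.  Gene symbols are matched
#' case-insensitively.
#'
#' @param coverage output of [gene_coverage()].
#' @param panel gene panel, default [default_gene_panel()].
#' @return data frame with `sample_id`, `gene_symbol`, `coverage`, `acn`,
#'   `process` (`NA` for genes outside the panel, `"reference"` for the
#'   reference genes), `n_reference_used`; attribute `"flagged_samples"`.
#' @export
normalize_acn <- function(coverage, panel = default_gene_panel()) {
  ref_lc <- tolower(panel$reference)
  proc_map <- setNames(panel$processes, tolower(names(panel$processes)))
  out <- coverage
  glc <- tolower(out$gene_symbol)
  out$process <- unname(proc_map[glc])
  out$process[glc %in% ref_lc] <- "reference"
  out$acn <- NA_real_
  out$n_reference_used <- 0L
  flagged <- character(0)
  for (sid in unique(out$sample_id)) {
    rows <- which(out$sample_id == sid)
    is_ref <- glc[rows] %in% ref_lc & out$coverage[rows] > 0
    if (!any(is_ref)) {
      flagged <- c(flagged, sid)
      next
    }
    ref_mean <- mean(out$coverage[rows][is_ref])
    out$acn[rows] <- out$coverage[rows] / ref_mean
    out$n_reference_used[rows] <- sum(is_ref)
  }
  attr(out, "flagged_samples") <- flagged
  out
}

#' Sum ACN by nitrogen-cycle process
#'
#' @param acn output of [normalize_acn()].
#' @param panel gene panel, default [default_gene_panel()].
#' @return data frame with `sample_id`, `process`, `acn` (summed); the
#'   attribute `"n_outside_panel"` counts (sample, gene) rows that belong
#'   to neither the panel nor the reference set.
#' @export
aggregate_process <- function(acn, panel = default_gene_panel()) {
  in_panel <- !is.na(acn$process) & acn$process != "reference"
  n_outside <- sum(is.na(acn$process))
  sub <- acn[in_panel & !is.na(acn$acn), , drop = FALSE]
  if (nrow(sub) == 0) {
    out <- data.frame(sample_id = character(0), process = character(0),
                      acn = numeric(0))
  } else {
    agg <- aggregate(acn ~ sample_id + process, data = sub, FUN = sum)
    out <- agg[order(agg$sample_id, agg$process), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_outside_panel") <- n_outside
  out
}
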