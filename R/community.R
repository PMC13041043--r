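.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a taxa table
#'
#' Bundles a samples x ASVs count matrix with per-ASV taxonomic lineages and
#' per-sample metadata.
#'
#' @param counts non-negative integer matrix, rows = samples, columns =
#'   ASVs; dimnames required.
#' @param taxonomy data frame with `asv_id` and rank columns `domain`,
#'   `phylum`, `class`, `order`, `family`, `genus` (missing ranks as `NA`);
#'   every ASV needs at least a domain.
#' @param meta data frame with `sample_id`, `region`, `year`, `depth_m`,
#'   `water_mass`; one row per sample.
#' @return object of class `"taxa_table"`.
#' @export
taxa_table <- function(counts, taxonomy, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs sample and ASV dimnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$asv_id), , drop = FALSE]
  if (any(is.na(taxonomy$asv_id))) {
    stop("taxonomy missing for some ASVs", call. = FALSE)
  }
  if (any(is.na(taxonomy$domain) | taxonomy$domain == "")) {
    stop("every ASV needs at least a domain assignment", call. = FALSE)
  }
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) {
    stop("metadata missing for some samples", call. = FALSE)
  }
  structure(list(counts = counts, taxonomy = taxonomy, meta = meta),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat("taxa_table:", nrow(x$counts), "samples x", ncol(x$counts), "ASVs\n")
  invisible(x)
}

#' Relative abundance aggregated at a taxonomic rank
#'
#' ASV counts are summed by their name at `rank`; ASVs unassigned at that
#' rank are pooled as `Unclassified_<parent name>` using the nearest
#' assigned parent rank.  Per-sample proportions sum to one.  Samples with
#' zero total counts are excluded and listed in the `"excluded"` attribute.
#'
#' @param tt a [taxa_table()].
#' @param rank one of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`; `"asv"` keeps ASV resolution.
#' @return samples x taxa matrix of proportions.
#' @export
relative_abundance <- function(tt, rank = "phylum") {
  counts <- tt$counts
  if (rank != "asv") {
    rank <- match.arg(rank, .tax_ranks)
    ri <- match(rank, .tax_ranks)
    grp <- tt$taxonomy[[rank]]
    unassigned <- is.na(grp) | grp == ""
    if (any(unassigned)) {
      parent <- rep("Unknown", sum(unassigned))
      if (ri > 1) {
        above <- tt$taxonomy[unassigned, rev(.tax_ranks[seq_len(ri - 1)]),
                             drop = FALSE]
        for (j in seq_len(ncol(above))) {
          use <- parent == "Unknown" & !is.na(above[[j]]) & above[[j]] != ""
          parent[use] <- above[[j]][use]
        }
      }
      grp[unassigned] <- paste0("Unclassified_", parent)
    }
    counts <- t(rowsum(t(counts), group = grp))
  }
  totals <- rowSums(counts)
  empty <- totals == 0
  prop <- counts[!empty, , drop = FALSE] / totals[!empty]
  attr(prop, "excluded") <- rownames(tt$counts)[empty]
  prop
}

#' Default nitrifier guild definitions
#'
#' Rank-based rules: ammonia-oxidizing archaea (AOA) are ASVs of the class
#' Nitrososphaeria; ammonia-oxidizing bacteria (AOB) are ASVs of the family
#' Nitrosomonadaceae or the genus Nitrosococcus; nitrite-oxidizing bacteria
#' (NOB) are ASVs of the phyla Nitrospinota or Nitrospirota or the genera
#' Nitrotoga or Nitrobacter.
#'
#' @return named list of guilds, each a list of `(rank, name)` rules; an ASV
#'   belongs to a guild iff any rule matches its lineage.
#' @export
default_guilds <- function() {
  list(
    AOA = list(c(rank = "class", name = "Nitrososphaeria")),
    AOB = list(c(rank = "family", name = "Nitrosomonadaceae"),
               c(rank = "genus", name = "Nitrosococcus")),
    NOB = list(c(rank = "phylum", name = "Nitrospinota"),
               c(rank = "phylum", name = "Nitrospirota"),
               c(rank = "genus", name = "Nitrotoga"),
               c(rank = "genus", name = "Nitrobacter"))
  )
}

#' Nitrifier guild abundances against the total community
#'
#' Assigns each ASV to a guild by the rank rules, resolving the rare
#' multi-guild overlaps by the precedence AOA > AOB > NOB (counted once;
#' the number of overlapping ASVs is reported).  Guild relative abundances
#' are expressed against the whole community — the nitrifier subset is not
#' rescaled to 100% — and the non-nitrifying remainder is split into
#' archaea and bacteria by domain.
#'
#' @param tt a [taxa_table()].
#' @param guilds guild definitions, default [default_guilds()].
#' @return samples x categories proportion matrix with columns `AOA`,
#'   `AOB`, `NOB`, `Other_Archaea`, `Other_Bacteria`; attributes
#'   `"assignment"` (per-ASV guild) and `"n_overlap"`.
#' @export
subset_nitrifiers <- function(tt, guilds = default_guilds()) {
  tax <- tt$taxonomy
  match_guild <- function(rules) {
    hit <- rep(FALSE, nrow(tax))
    for (rule in rules) {
      v <- tax[[rule[["rank"]]]]
      hit <- hit | (!is.na(v) & v == rule[["name"]])
    }
    hit
  }
  hits <- matrix(vapply(guilds, match_guild, logical(nrow(tax))),
                 nrow = nrow(tax), dimnames = list(NULL, names(guilds)))
  n_overlap <- sum(rowSums(hits) > 1)
  assignment <- rep(NA_character_, nrow(tax))
  for (g in names(guilds)) {          # list order is the precedence
    assignment[is.na(assignment) & hits[, g]] <- g
  }
  rest_arch <- is.na(assignment) & !is.na(tax$domain) &
    tax$domain == "Archaea"
  assignment[rest_arch] <- "Other_Archaea"
  assignment[is.na(assignment)] <- "Other_Bacteria"

  totals <- rowSums(tt$counts)
  keep <- totals > 0
  grouped <- t(rowsum(t(tt$counts[keep, , drop = FALSE]), group = assignment))
  prop <- grouped / totals[keep]
  cats <- c(names(guilds), "Other_Archaea", "Other_Bacteria")
  out <- matrix(0, nrow(prop), length(cats),
                dimnames = list(rownames(prop), cats))
  out[, colnames(prop)] <- prop
  attr(out, "assignment") <- setNames(assignment, tax$asv_id)
  attr(out, "n_overlap") <- n_overlap
  out
}

#' Per-sample taxon richness
#'
#' Number of ASVs with non-zero counts in each sample.
#'
#' @param tt a [taxa_table()] or a counts matrix (samples x taxa).
#' @return named integer vector.
#' @export
richness <- function(tt) {
  counts <- if (inherits(tt, "taxa_table")) tt$counts else as.matrix(tt)
  rowSums(counts > 0)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(i, j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})},
#' computed directly from the definition.  For non-negative rows the result
#' lies in \[0, 1\], is symmetric and has a zero diagonal.
#'
#' @param x samples x taxa matrix of non-negative abundances (counts or
#'   proportions).
#' @return dense symmetric matrix of dissimilarities.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  n <- nrow(x)
  tot <- rowSums(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- tot[i] + tot[j]
      if (denom == 0) {
        stop("two all-zero samples: distance undefined", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  d
}

#' Pool minor taxa into an "Other" category
#'
#' Keeps the `top_n` taxa by grand mean relative abundance and sums the rest
#' into `"Other"`, the usual display convention for phylum-level barplots.
#'
#' @param prop samples x taxa proportion matrix.
#' @param top_n number of taxa kept (default 9).
#' @return samples x (top_n + 1) proportion matrix.
#' @export
pool_minor_taxa <- function(prop, top_n = 9) {
  if (ncol(prop) <= top_n) return(prop)
  keep <- names(sort(colMeans(prop), decreasing = TRUE))[seq_len(top_n)]
  other <- rowSums(prop[, !colnames(prop) %in% keep, drop = FALSE])
  cbind(prop[, keep, drop = FALSE], Other = other)
}
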