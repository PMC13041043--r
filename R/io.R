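#' Table schemas for the supported file formats
#'
#' Each schema names the required columns and their types (`"character"`,
#' `"integer"`, `"numeric"`); extra columns are preserved.  The analyte
#' columns of the nutrient table are optional but type-checked when
#' present.
#'
#' @return named list of schema definitions.
#' @export
table_schemas <- function() {
  list(
    ctd = list(
      required = c(station_id = "character", region = "character",
                   year = "integer", depth_m = "numeric",
                   temp_c = "numeric", sal = "numeric"),
      optional = c(sigma_theta = "numeric", water_mass = "character")),
    nutrients = list(
      required = c(station_id = "character", region = "character",
                   year = "integer", depth_m = "numeric"),
      optional = c(sal = "numeric", water_mass = "character",
                   setNames(rep("numeric", length(.analytes)), .analytes))),
    sample_meta = list(
      required = c(sample_id = "character", region = "character",
                   year = "integer", depth_m = "numeric",
                   water_mass = "character"),
      optional = character(0)),
    taxonomy = list(
      required = c(asv_id = "character", domain = "character"),
      optional = setNames(rep("character", 5),
                          c("phylum", "class", "order", "family", "genus"))),
    gene_counts = list(
      required = c(sample_id = "character", gene_symbol = "character",
                   mapped_reads = "numeric", gene_length_bp = "numeric"),
      optional = c(contig_id = "character"))
  )
}

#' Read and validate a delimited table
#'
#' The delimiter is taken from the extension: `.csv` is comma-separated,
#' anything else tab-separated.  Columns are validated against the named
#' schema; a missing required column or an unparseable numeric cell is a
#' row-addressed error.  Missing values (empty cells, `NA`) stay missing.
#'
#' @param path file path.
#' @param schema schema name (one of `names(table_schemas())`) or a schema
#'   definition list; `NULL` skips validation.
#' @return data frame.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  if (is.null(schema)) return(df)
  if (is.character(schema)) {
    schema <- table_schemas()[[match.arg(schema, names(table_schemas()))]]
  }
  missing_cols <- setdiff(names(schema$required), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), " in ", basename(path),
         call. = FALSE)
  }
  types <- c(schema$required, schema$optional)
  for (col in intersect(names(types), names(df))) {
    df[[col]] <- parse_column(df[[col]], types[[col]], col)
  }
  df
}

parse_column <- function(v, type, col) {
  if (type == "character") return(as.character(v))
  raw <- as.character(v)
  parsed <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(parsed))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable numeric value '%s' at row %d",
                 col, raw[bad[1]], bad[1]), call. = FALSE)
  }
  if (type == "integer") as.integer(parsed) else parsed
}

#' Write a delimited table
#'
#' Counterpart of [read_table()]: comma-separated for `.csv`, tab-separated
#' otherwise; missing values as empty cells; no row names; numerics at full
#' precision (15 significant digits), so a round trip reproduces values to
#' well within 1e-6 relative.
#'
#' @param df data frame (may have zero rows; the header is still written).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA,
                        format(df[[col]], digits = 15, trim = TRUE,
                               scientific = FALSE))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Read a station-role configuration
#'
#' YAML with one block per region: `shelf` and `fjord` station lists and a
#' `pairs` list of `{year, shelf_wm, fjord_wm}` water-mass pairings for the
#' source/sink estimator.
#'
#' @param path YAML file path.
#' @return named list of region role definitions.
#' @export
read_station_roles <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (region in names(cfg)) {
    rg <- cfg[[region]]
    if (is.null(rg$shelf) || is.null(rg$fjord)) {
      stop("region ", region, " needs 'shelf' and 'fjord' station lists",
           call. = FALSE)
    }
    cfg[[region]]$shelf <- as.character(unlist(rg$shelf))
    cfg[[region]]$fjord <- as.character(unlist(rg$fjord))
    if (is.null(rg$pairs)) cfg[[region]]$pairs <- list()
  }
  cfg
}

#' Read a taxa table from its three component files
#'
#' @param counts_path TSV with ASV rows (first column `asv_id`) and sample
#'   columns.
#' @param taxonomy_path taxonomy TSV (`asv_id`, `domain` .. `genus`).
#' @param meta_path sample metadata TSV.
#' @return a [taxa_table()].
#' @export
read_taxa_table <- function(counts_path, taxonomy_path, meta_path) {
  raw <- read_table(counts_path)
  if (names(raw)[1] != "asv_id") {
    stop("taxa count table must have 'asv_id' as its first column",
         call. = FALSE)
  }
  counts <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(counts) <- raw$asv_id
  taxonomy <- read_table(taxonomy_path, "taxonomy")
  meta <- read_table(meta_path, "sample_meta")
  taxa_table(counts, taxonomy, meta)
}
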