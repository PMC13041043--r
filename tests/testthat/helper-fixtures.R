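# shared fixtures: toy envelopes, oracles, and small tables built in code

# the four-envelope toy configuration used throughout the classifier tests
toy_envelopes <- function() {
  envelope_table(list(
    water_mass_envelope("AW", t_min = 3.0, s_min = 34.9, sigma_max = 27.92),
    water_mass_envelope("TAW", t_min = 1.0, t_max = 3.0, s_min = 34.7,
                        sigma_max = 27.92),
    water_mass_envelope("ArW", t_max = 1.0, s_min = 34.3, s_max = 34.8,
                        closed = c(s_max = TRUE)),
    water_mass_envelope("LW", t_min = 0.5, t_max = 1.0, s_min = 34.3)))
}

# literal-rules brute-force classifier: tests every envelope, then applies
# the fallback rules exactly as stated, with no vectorization tricks
oracle_classify <- function(t, s, sigma, env) {
  contains <- function(e) {
    cl <- e$closed
    ok_t <- (if (cl[["t_min"]]) t >= e$t_min else t > e$t_min) &&
      (if (cl[["t_max"]]) t <= e$t_max else t < e$t_max)
    ok_s <- (if (cl[["s_min"]]) s >= e$s_min else s > e$s_min) &&
      (if (cl[["s_max"]]) s <= e$s_max else s < e$s_max)
    ok_sig <- is.na(e$sigma_max) || sigma < e$sigma_max
    ok_t && ok_s && ok_sig
  }
  matches <- names(Filter(contains, env$envelopes))
  if (length(matches) == 1) return(matches)
  if (length(matches) > 1) {
    return(env$precedence[min(match(matches, env$precedence))])
  }
  ts_box <- function(e) {
    cl <- e$closed
    ((if (cl[["t_min"]]) t >= e$t_min else t > e$t_min) &&
       (if (cl[["t_max"]]) t <= e$t_max else t < e$t_max) &&
       (if (cl[["s_min"]]) s >= e$s_min else s > e$s_min) &&
       (if (cl[["s_max"]]) s <= e$s_max else s < e$s_max))
  }
  for (atl in c("AW", "TAW")) {
    e <- env$envelopes[[atl]]
    if (!is.null(e) && ts_box(e) && sigma >= env$sigma_threshold) return(atl)
  }
  arw <- env$envelopes[["ArW"]]
  lw <- env$envelopes[["LW"]]
  if (!is.null(arw) && !is.null(lw) && s < arw$s_min && t < lw$t_min) {
    return("ArW")
  }
  "Unclassified"
}

# exact two-sided Mann-Whitney p by full enumeration of rank splits
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  n <- n1 + n2
  r_obs <- rank(c(x, y))
  u_obs <- sum(r_obs[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_min <- min(u_obs, n1 * n2 - u_obs)
  splits <- combn(n, n1)
  u_all <- apply(splits, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  min(1, 2 * mean(u_all <= u_min))
}

# elementwise Bray-Curtis oracle
oracle_bray_curtis <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; den <- 0
      for (k in seq_len(ncol(x))) {
        num <- num + abs(x[i, k] - x[j, k])
        den <- den + x[i, k] + x[j, k]
      }
      d[i, j] <- num / den
    }
  }
  d
}

# minimal three-sample taxa table with two phyla and one AOA
tiny_taxa_table <- function() {
  counts <- matrix(c(2, 3, 5,
                     0, 4, 6,
                     1, 0, 9), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("asv1", "asv2", "asv3")))
  tax <- data.frame(
    asv_id = c("asv1", "asv2", "asv3"),
    domain = c("Bacteria", "Bacteria", "Archaea"),
    phylum = c("Proteobacteria", "Bacteroidota", "Thermoproteota"),
    class = c(NA, NA, "Nitrososphaeria"),
    order = NA_character_, family = NA_character_, genus = NA_character_,
    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     region = "Kongsfjorden", year = 2016,
                     depth_m = c(5, 50, 500),
                     water_mass = c("SW", "IW", "WCW"),
                     stringsAsFactors = FALSE)
  taxa_table(counts, tax, meta)
}

# four-point distance matrix of the PERMANOVA worked example
worked_permanova_dist <- function() {
  d <- matrix(1, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d
}
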