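test_that("relative abundance aggregates ranks and normalizes rows", {
  tt <- tiny_taxa_table()
  prop <- relative_abundance(tt, "phylum")
  expect_equal(unname(rowSums(prop)), rep(1, 3), tolerance = 1e-12)
  expect_equal(prop["s1", "Proteobacteria"], 0.2)
  expect_equal(prop["s1", "Bacteroidota"], 0.3)
  expect_equal(prop["s1", "Thermoproteota"], 0.5)

  # two ASVs of one phylum pool
  counts <- matrix(c(2, 3, 5), 1, dimnames = list("s1", c("a", "b", "c")))
  tax <- data.frame(asv_id = c("a", "b", "c"), domain = "Bacteria",
                    phylum = c("P1", "P1", "P2"), class = NA, order = NA,
                    family = NA, genus = NA)
  meta <- data.frame(sample_id = "s1", region = "K", year = 2016,
                     depth_m = 5, water_mass = "SW")
  tt2 <- taxa_table(counts, tax, meta)
  prop2 <- relative_abundance(tt2, "phylum")
  expect_equal(prop2[1, "P1"], 0.5)

  # unassigned rank pools under the parent name
  tax$phylum <- c("P1", NA, "P2")
  tt3 <- taxa_table(counts, tax, meta)
  expect_true("Unclassified_Bacteria" %in%
                colnames(relative_abundance(tt3, "phylum")))

  # zero-count sample excluded and reported
  counts4 <- rbind(counts, s2 = c(0, 0, 0))
  tt4 <- taxa_table(counts4, tax, rbind(meta,
    data.frame(sample_id = "s2", region = "K", year = 2016, depth_m = 5,
               water_mass = "SW")))
  prop4 <- relative_abundance(tt4, "asv")
  expect_identical(attr(prop4, "excluded"), "s2")
  expect_identical(nrow(prop4), 1L)
})

test_that("nitrifier guilds follow the rank rules without rescaling", {
  tax <- data.frame(
    asv_id = paste0("a", 1:6),
    domain = c("Archaea", "Bacteria", "Bacteria", "Bacteria", "Bacteria",
               "Archaea"),
    phylum = c("Thermoproteota", "Proteobacteria", "Proteobacteria",
               "Nitrospinota", "Bacteroidota", "Halobacteriota"),
    class = c("Nitrososphaeria", "Gammaproteobacteria", NA, NA, NA, NA),
    order = NA, family = c(NA, "Nitrosomonadaceae", NA, NA, NA, NA),
    genus = c(NA, NA, "Nitrosococcus", NA, NA, NA))
  counts <- matrix(c(10, 20, 5, 15, 40, 10), 1,
                   dimnames = list("s1", tax$asv_id))
  meta <- data.frame(sample_id = "s1", region = "K", year = 2016,
                     depth_m = 100, water_mass = "AW")
  g <- subset_nitrifiers(taxa_table(counts, tax, meta))
  expect_equal(g["s1", "AOA"], 0.10)                  # class rule
  expect_equal(g["s1", "AOB"], 0.25)                  # family + genus rules
  expect_equal(g["s1", "NOB"], 0.15)                  # phylum rule
  expect_equal(g["s1", "Other_Archaea"], 0.10)
  expect_equal(g["s1", "Other_Bacteria"], 0.40)
  expect_equal(sum(g), 1)                             # partition, no rescale
  asn <- attr(g, "assignment")
  expect_identical(unname(asn[c("a1", "a3", "a4")]), c("AOA", "AOB", "NOB"))
})

test_that("guild overlaps resolve once by AOA > AOB > NOB precedence", {
  tax <- data.frame(asv_id = "x1", domain = "Bacteria",
                    phylum = "Nitrospinota", class = NA, order = NA,
                    family = "Nitrosomonadaceae", genus = NA)
  counts <- matrix(8, 1, dimnames = list("s1", "x1"))
  meta <- data.frame(sample_id = "s1", region = "K", year = 2016,
                     depth_m = 5, water_mass = "SW")
  g <- subset_nitrifiers(taxa_table(counts, tax, meta))
  expect_identical(attr(g, "n_overlap"), 1L)
  expect_equal(g["s1", "AOB"], 1)       # AOB precedes NOB; counted once
  expect_equal(g["s1", "NOB"], 0)
  expect_equal(sum(g), 1)
})

test_that("richness counts non-zero taxa and ignores scaling", {
  m <- rbind(a = c(5, 0, 2, 0, 1), b = rep(0, 5))
  expect_identical(unname(richness(m)), c(3, 0))
  expect_identical(richness(m * 2), richness(m))
})

test_that("Bray-Curtis matches the formula, its oracle and vegan", {
  x <- rbind(a = c(0.5, 0.5, 0), b = c(0.25, 0.25, 0.5))
  expect_equal(bray_curtis(x)["a", "b"], 0.5)
  expect_equal(bray_curtis(rbind(x[1, ], x[1, ]))[1, 2], 0)      # identical
  y <- rbind(c(1, 1, 0, 0), c(0, 0, 2, 3))
  expect_equal(bray_curtis(y)[1, 2], 1)                          # disjoint
  set.seed(6)
  for (i in 1:10) {
    m <- matrix(rexp(40), 5, 8)
    d <- bray_curtis(m)
    expect_equal(d, oracle_bray_curtis(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(as.matrix(vegan::vegdist(m, "bray"))), unname(d),
                 tolerance = 1e-12)
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("nMDS embeds exactly when possible and decreases stress", {
  d3 <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(0, 1))))
  f <- nmds(d3, k = 2, seed = 1, n_restarts = 3)
  expect_lt(f$stress, 1e-6)
  expect_true(all(diff(f$stress_sequence) <= 1e-15))

  set.seed(5)
  xy <- matrix(rnorm(20), 10)
  d <- as.matrix(dist(xy))
  f10 <- nmds(d, k = 2, seed = 2, n_restarts = 5)
  expect_true(all(diff(f10$stress_sequence) <= 1e-15))
  pr <- vegan::procrustes(xy, f10$coordinates, symmetric = TRUE)
  expect_gt(sqrt(1 - pr$ss), 0.99)

  # identical seed and input: bit-reproducible
  g1 <- nmds(d, k = 2, seed = 9, n_restarts = 3)
  g2 <- nmds(d, k = 2, seed = 9, n_restarts = 3)
  expect_identical(g1$coordinates, g2$coordinates)
  expect_identical(g1$stress, g2$stress)

  expect_error(nmds(matrix(c(0, 1, 2, 0), 2), k = 1), "symmetric")
})

test_that("PERMANOVA reproduces the worked example exactly", {
  d <- worked_permanova_dist()
  res <- permanova(d, c("g1", "g1", "g2", "g2"), n_perm = 999, seed = 1)
  expect_equal(res$pseudo_f, 199)
  expect_true(res$exhaustive)
  expect_equal(res$p, 1 / 3)
  # SS decomposition behind the statistic
  ss <- fjordflux:::permanova_ss(d^2, c("g1", "g1", "g2", "g2"))
  expect_equal(ss$total, 1.005)
  expect_equal(ss$within, 0.01)
})

test_that("PERMANOVA enumeration agrees with Monte Carlo and vegan", {
  set.seed(12)
  pts <- matrix(rnorm(20), 10)
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 5)
  exact <- permanova(d, g, n_perm = 999, seed = 1)    # 252 labelings
  expect_true(exact$exhaustive)
  mc <- permanova(d, g, n_perm = 99, seed = 1)        # 252 > 99: sampled
  expect_false(mc$exhaustive)
  expect_lt(abs(mc$p - exact$p), 3 * sqrt(exact$p * (1 - exact$p) / 99) +
              0.02)
  # pseudo-F and R2 equal adonis2 on the same distances
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(exact$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(exact$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_error(permanova(d, rep("a", nrow(d))), "two groups")
})

test_that("dispersion homogeneity detects unequal spread, not location", {
  # identical internal geometry in both groups: F near 0, p near 1
  d <- worked_permanova_dist()
  res <- dispersion_homogeneity(d, c("g1", "g1", "g2", "g2"),
                                n_perm = 199, seed = 1)
  expect_equal(res$pseudo_f, 0, tolerance = 1e-10)
  expect_gt(res$p, 0.5)

  # one tight and one dispersed group
  set.seed(13)
  tight <- matrix(rnorm(20, sd = 0.01), 10)
  loose <- matrix(rnorm(20, sd = 1), 10)
  dd <- as.matrix(dist(rbind(tight, loose)))
  grp <- rep(c("t", "l"), each = 10)
  res2 <- dispersion_homogeneity(dd, grp, n_perm = 999, seed = 2)
  expect_lte(res2$p, 0.05)

  # all distances equal: every centroid distance equal, F = 0
  deq <- matrix(0.4, 6, 6); diag(deq) <- 0
  res3 <- dispersion_homogeneity(deq, rep(c("a", "b"), 3), n_perm = 199,
                                 seed = 3)
  expect_equal(res3$pseudo_f, 0, tolerance = 1e-10)
})

test_that("pool_minor_taxa keeps the top taxa and sums the rest", {
  prop <- matrix(c(0.5, 0.3, 0.1, 0.06, 0.04), 1,
                 dimnames = list("s", paste0("p", 1:5)))
  pooled <- pool_minor_taxa(prop, top_n = 2)
  expect_identical(colnames(pooled), c("p1", "p2", "Other"))
  expect_equal(pooled[1, "Other"], 0.2)
  expect_identical(pool_minor_taxa(prop, top_n = 10), prop)
})
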