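test_that("below-detection flagging keeps values and uses strict limits", {
  s <- data.frame(station_id = "a", region = "K", year = 2016, depth_m = 5,
                  nitrate_nitrite = c(0.3, 0.6, NA),
                  phosphate = c(0.06, 0.05, 0.2))
  out <- flag_below_detection(s)
  expect_identical(out$bd_nitrate_nitrite, c(TRUE, FALSE, NA))
  expect_identical(out$nitrate_nitrite, s$nitrate_nitrite)  # unchanged
  expect_identical(out$bd_phosphate, c(FALSE, TRUE, FALSE)) # boundary strict
  expect_error(flag_below_detection(s, limits = c(phosphate = -1)),
               "positive")
})

test_that("station median aggregation groups and excludes as specified", {
  s <- data.frame(
    station_id = c("a", "a", "a", "b", "b", "c"),
    region = "K", year = 2016,
    depth_m = c(5, 20, 50, 5, 20, 5),
    ammonium = c(1, 2, 10, 1, 3, 4),
    water_mass = c("SW", "SW", "SW", "SW", "SW", "Unclassified"))
  cells <- aggregate_station_medians(s)
  expect_identical(nrow(cells), 2L)           # two stations, never pooled
  expect_equal(cells$ammonium[cells$station_id == "a"], 2)  # odd-n median
  expect_equal(cells$ammonium[cells$station_id == "b"], 2)  # even-n midpoint
  expect_false("c" %in% cells$station_id)     # Unclassified dropped
  # idempotence: re-aggregating one-sample cells returns the same medians
  again <- aggregate_station_medians(cells, cells$water_mass)
  expect_equal(sort(again$ammonium), sort(cells$ammonium))
  # empty input
  expect_identical(nrow(aggregate_station_medians(s[0, ])), 0L)
})

test_that("Mann-Whitney U matches the worked examples and symmetry", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(t1$u_statistic, 0)
  expect_equal(t1$p, 0.1)
  expect_identical(t1$method, "exact")

  t2 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_identical(t2$u_statistic, 2)
  expect_equal(t2$p, 1)

  # swapping samples mirrors U and keeps p
  a <- c(0.3, 1.2, 2.2, 5); b <- c(0.9, 1.4, 3.1)
  f <- mann_whitney_u(a, b); g <- mann_whitney_u(b, a)
  expect_equal(g$u_statistic, f$n1 * f$n2 - f$u_statistic)
  expect_equal(g$p, f$p)

  # degenerate data
  d <- mann_whitney_u(c(2, 2), c(2, 2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
})

test_that("exact Mann-Whitney p equals the enumeration oracle", {
  set.seed(42)
  for (n1 in 2:4) {
    for (n2 in 2:4) {
      if (n1 + n2 > 8) next
      for (rep in 1:5) {
        x <- rnorm(n1); y <- rnorm(n2)   # continuous: tie-free
        expect_equal(mann_whitney_u(x, y)$p, oracle_mwu_p(x, y),
                     info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
      }
    }
  }
})

test_that("Benjamini-Hochberg matches the hand oracle and its properties", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.02)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_identical(benjamini_hochberg(numeric(0)), numeric(0))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))   # dominance
    o <- order(p)
    expect_true(!is.unsorted(adj[o]))                     # monotone
    expect_equal(adj, stats::p.adjust(p, "BH"))           # reference impl
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), adj[perm])  # permutation
  }
})

test_that("bootstrap CI is reproducible, degenerate-safe and covers", {
  v <- c(7, 7, 7, 7)
  expect_equal(unname(bootstrap_ci(v, b = 500)), c(7, 7))
  x <- rnorm(30)
  ci1 <- bootstrap_ci(x, b = 999, seed = 5)
  ci2 <- bootstrap_ci(x, b = 999, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1["low"], ci1["high"])
  expect_warning(bootstrap_ci(3), "single")
  expect_error(bootstrap_ci(numeric(0)), "no non-missing")
  expect_error(bootstrap_ci(1:5, b = 50), "at least 200")
  # modest coverage check (full-scale simulation lives in acceptance)
  set.seed(99)
  hits <- 0
  for (i in 1:200) {
    ci <- bootstrap_ci(rnorm(50), b = 400, seed = i)
    if (ci["low"] <= 0 && 0 <= ci["high"]) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.85)
})

test_that("water-mass summaries use type-7 quantiles and order invariance", {
  cells <- data.frame(ammonium = c(1, 2, 3))
  s <- summarize_water_mass(cells, "ammonium", b = 500)
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  q <- summarize_water_mass(data.frame(ammonium = c(1, 2, 3, 4)),
                            "ammonium", b = 500)
  expect_equal(q$q25, 1.75)
  expect_equal(q$q75, 3.25)
  single <- summarize_water_mass(data.frame(ammonium = 5), "ammonium")
  expect_true(all(unlist(single[c("median", "mean", "ci_low",
                                  "ci_high")]) == 5))
  shuffled <- summarize_water_mass(data.frame(ammonium = c(3, 1, 4, 2)),
                                   "ammonium", b = 500)
  ordered <- summarize_water_mass(data.frame(ammonium = 1:4),
                                  "ammonium", b = 500)
  expect_equal(shuffled[-1], ordered[-1])
})

test_that("stoichiometric ratios handle the Redfield boundary and zeros", {
  s <- data.frame(nitrate_nitrite = c(14, 8, 3), ammonium = c(2, 2, 1),
                  phosphate = c(1, 0, 0.2), silicic_acid = c(5, 5, NA))
  r <- stoichiometric_ratios(s)
  expect_equal(r$din_p[1], 16)
  expect_false(r$redfield_excess[1])        # strictly greater than 16
  expect_equal(r$din_si[2], 2)
  expect_true(is.na(r$din_p[2]) && r$din_p_undefined[2])
  expect_true(is.na(r$din_si[3]) && r$din_si_undefined[3])
})

test_that("fjord comparison tests comparable water masses only", {
  set.seed(3)
  cells <- data.frame(
    region = rep(c("K", "R"), c(6, 4)),
    year = 2016,
    water_mass = c(rep("IW", 3), rep("AW", 3), rep("IW", 4)),
    station_id = paste0("st", 1:10),
    ammonium = c(rnorm(3, 5), rnorm(3, 1), rnorm(4, 1)))
  res <- compare_fjords(cells, "K", "R")
  expect_identical(res$water_mass, "IW")    # AW absent in R: skipped
  expect_identical(res$n1, 3L)
  expect_identical(res$n2, 4L)
  expect_gte(res$p_corr, res$p)
  expect_identical(res$direction, "K")
})
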