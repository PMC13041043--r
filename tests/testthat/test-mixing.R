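test_that("SMA slope is sign(r) * sd(y)/sd(x) with centroid intercept", {
  f <- sma_fit(1:3, c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)

  g <- sma_fit(1:3, c(6, 4, 2))
  expect_equal(g$slope, -2)

  # slope depends on the sd ratio, not on |r|: construct sd_y = 3 sd_x,
  # r about -0.5
  set.seed(10)
  x <- rnorm(200)
  y <- -0.5 * x + rnorm(200, sd = sqrt(1 - 0.25))
  y <- 3 * (y - mean(y)) / sd(y)
  x <- (x - mean(x)) / sd(x)
  h <- sma_fit(x, y)
  expect_equal(h$slope, sign(h$r) * 3, tolerance = 1e-12)
  expect_lt(h$r, 0)

  expect_error(sma_fit(c(1, 1, 1), 1:3), "x has zero variance")
  expect_error(sma_fit(1:3, c(2, 2, 2)), "y has zero variance")
  expect_error(sma_fit(1:2, 1:2), "at least 3")
})

test_that("Deming slope has its closed form and major-axis behaviour", {
  # colinear slope-2 data: s_xx = 1, s_yy = 4, s_xy = 2 -> slope 2
  x <- c(1, 2, 3)
  f <- deming_fit(x, 2 * x)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)

  # lambda = 1 equals the first principal axis of the covariance matrix
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(20); y <- 1.7 * x + rnorm(20, sd = 0.8)
    f <- deming_fit(x, y, lambda = 1)
    ev <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
    expect_equal(f$slope, ev[2] / ev[1], tolerance = 1e-9)
    # swap symmetry of the major axis
    g <- deming_fit(y, x, lambda = 1)
    expect_equal(g$slope, 1 / f$slope, tolerance = 1e-9)
  }

  # orientation undefined: zero covariance, equal variances
  expect_error(deming_fit(c(-1, 0, 1, 0), c(0, 1, 0, -1)), "undefined")
})

test_that("SMA and Deming reproduce exact slopes on colinear data", {
  x <- seq(1, 5, by = 0.5)
  for (b in c(-3, 0.25, 2)) {
    y <- 1 + b * x
    expect_equal(sma_fit(x, y)$slope, b, tolerance = 1e-12)
    expect_equal(deming_fit(x, y)$slope, b, tolerance = 1e-12)
  }
})

test_that("jackknife slope SE shrinks with tighter data", {
  set.seed(8)
  x <- rnorm(30)
  loose <- deming_fit(x, x + rnorm(30, sd = 1))
  tight <- deming_fit(x, x + rnorm(30, sd = 0.05))
  expect_lt(tight$slope_se, loose$slope_se)
})

test_that("source_sink reproduces the hand substitution and its limits", {
  expect_equal(source_sink(5, 34, 8, 35), 5 - 34 * 8 / 35,
               tolerance = 1e-12)
  expect_equal(source_sink(5, 34, 8, 35), -2.771, tolerance = 1e-3)
  # conservative case: fjord point on the mixing line
  expect_equal(source_sink(34 * 8 / 35, 34, 8, 35), 0, tolerance = 1e-12)
  # equal salinities: difference of concentrations
  expect_equal(source_sink(5, 35, 8, 35), -3)
  expect_error(source_sink(5, 34, 8, 0), "undefined")
  # linearity in c_fjord with unit coefficient
  base <- source_sink(5, 34, 8, 35)
  for (delta in c(-2, 0.5, 3)) {
    expect_equal(source_sink(5 + delta, 34, 8, 35), base + delta,
                 tolerance = 1e-12)
  }
})

test_that("zero freshwater endmember overstates dilution, hiding sinks", {
  # when the real freshwater source carries nutrients (c0_true > 0), the
  # zero-concentration assumption overstates dilution: the conservative
  # expectation drops, so the estimate shifts positive and true sinks are
  # understated (conservative in the statistical sense); the shift is
  # c0 * (1 - s_fjord / s_shelf) exactly
  s_shelf <- 35; c_shelf <- 8; s_fjord <- 33
  c0_true <- 2; s0 <- 0
  c_fjord <- c0_true + (s_fjord - s0) * (c_shelf - c0_true) / (s_shelf - s0)
  est_true <- source_sink(c_fjord, s_fjord, c_shelf, s_shelf, c0 = c0_true)
  est_zero <- source_sink(c_fjord, s_fjord, c_shelf, s_shelf, c0 = 0)
  expect_equal(est_true, 0, tolerance = 1e-12)
  expect_gt(est_zero, est_true)
  expect_equal(est_zero - est_true, c0_true * (1 - s_fjord / s_shelf),
               tolerance = 1e-12)
})

test_that("pair means respect rosters, water masses and the depth cutoff", {
  samples <- data.frame(
    station_id = c("V10", "V10", "Kb1", "Kb1", "Kb2"),
    depth_m = c(50, 150, 50, 80, 60),
    sal = c(35, 35.1, 34, 34.5, 34.5),
    nitrate_nitrite = c(8, 9, 4, 6, 6),
    water_mass = c("AW", "AW", "IW", "IW", "AW"))
  pm <- compute_pair_means(samples, shelf_stations = "V10",
                           fjord_stations = c("Kb1", "Kb2"),
                           shelf_wm = "AW", fjord_wm = "IW",
                           analyte = "nitrate_nitrite")
  expect_equal(pm$c_shelf, 8)        # 150 m sample excluded by the cutoff
  expect_equal(pm$s_fjord, 34.25)    # arithmetic means over two samples
  expect_equal(pm$c_fjord, 5)
  expect_error(
    compute_pair_means(samples, "V10", "Kb9", "AW", "IW",
                       "nitrate_nitrite"),
    "fjord")
})

test_that("mixing diagrams stratify, fit and correct across strata", {
  set.seed(21)
  n <- 12
  samples <- do.call(rbind, lapply(c("K", "R"), function(rg) {
    do.call(rbind, lapply(c("SW", "IW"), function(wm) {
      sal <- runif(n, 33, 35)
      data.frame(region = rg, year = 2016, water_mass = wm, sal = sal,
                 nitrate_nitrite = 2 * sal - 60 + rnorm(n, sd = 0.1))
    }))
  }))
  fits <- mixing_diagrams(samples, analytes = "nitrate_nitrite")
  expect_identical(nrow(fits), 4L)  # 2 regions x 2 water masses x 1 analyte
  expect_true(all(abs(fits$slope - 2) < 0.2))
  expect_true(all(fits$p_corr >= fits$p - 1e-15))
  # degenerate stratum is kept with NA, not dropped
  samples2 <- rbind(samples,
                    data.frame(region = "K", year = 2016,
                               water_mass = "WCW", sal = rep(34.9, 2),
                               nitrate_nitrite = c(9, 9.1)))
  fits2 <- mixing_diagrams(samples2, analytes = "nitrate_nitrite")
  expect_true(any(is.na(fits2$slope)))
})
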