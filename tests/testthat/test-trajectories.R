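test_that("ages map to decade bins with the documented edge policy", {
  expect_equal(as.character(bin_by_age(c(21, 30, 31, 41, 90))),
               c("21-30", "21-30", "31-40", "41-50", "81-90"))
  expect_warning(b <- bin_by_age(20), "below 21")
  expect_equal(as.character(b), "21-30")
  expect_warning(b2 <- bin_by_age(c(50, 95)), "above 90")
  expect_true(is.na(b2[2]))
  expect_equal(levels(b2), age_bins())
  expect_equal(bin_midpoints(), seq(25.5, 85.5, by = 10))
})

test_that("bin summaries exclude zeros and carry normal-theory CIs", {
  df <- data.frame(subject_id = sprintf("s%d", 1:5), cohort = "A",
                   age = c(25, 26, 61, 62, 63), sex = "F",
                   Thalamus = c(16000, 16204, 0, 100, 100))
  s <- suppressWarnings(summarize_bins(volume_matrix(df)))
  young <- s[s$bin == "21-30", ]
  expect_equal(young$mean, 16102)
  expect_equal(young$n, 2)
  old <- s[s$bin == "61-70", ]
  expect_equal(old$n, 2)        # the zero volume is excluded
  expect_equal(old$mean, 100)
  expect_equal(old$sd, 0)
  # CI is mean +/- 1.96 sd/sqrt(n)
  expect_equal(young$ci_hi - young$mean, 1.96 * young$sd / sqrt(2))
  expect_true(all(s$ci_lo <= s$mean & s$mean <= s$ci_hi))
})

test_that("symmetric percent change matches hand-computed references", {
  expect_equal(round(endpoint_change(16102.0, 13322.4), 1), -18.9)
  expect_equal(round(endpoint_change(1228.9, 5121.1), 1), 122.6)
  expect_equal(endpoint_change(500, 500), 0)
  expect_error(endpoint_change(-1, 5), "positive")
  expect_equal(max_consecutive_change(rep(42, 7)), 0)
  expect_equal(range_change(rep(42, 7)), 0)
})

test_that("change statistics obey antisymmetry, scale invariance, ordering", {
  set.seed(19)
  for (i in 1:50) {
    s <- stats::runif(7, 100, 50000)
    a <- s[1]; b <- s[7]
    expect_equal(sym_pct_change(a, b), -sym_pct_change(b, a))
    c0 <- stats::runif(1, 0.1, 10)
    expect_equal(endpoint_change(a * c0, b * c0), endpoint_change(a, b))
    expect_equal(range_change(s * c0), range_change(s))
    expect_equal(max_consecutive_change(s * c0), max_consecutive_change(s))
    # range change dominates both other statistics
    expect_gte(range_change(s) + 1e-12,
               abs(endpoint_change(s[1], s[7])))
    expect_gte(range_change(s) + 1e-12, max_consecutive_change(s))
    expect_gte(max_consecutive_change(s), 0)
  }
})

test_that("a missing interior bin degrades gracefully with a warning", {
  s <- c(100, 110, NA, 130, 120, 115, 105)
  expect_warning(mc <- max_consecutive_change(s), "available")
  expect_warning(rc <- range_change(s), "available")
  expect_equal(rc, sym_pct_change(100, 130))
  expect_error(max_consecutive_change(c(NA, 5, NA, NA, NA, NA, NA)),
               "at least 2")
})

test_that("polynomial fits match the normal-equations oracle", {
  set.seed(55)
  ages <- bin_midpoints()
  for (i in 1:20) {
    y <- stats::runif(7, 1000, 30000)
    fit <- fit_trajectory(y, ages)
    expect_equal(unname(coef(fit, "cubic")), cubic_normal_eq(ages, y),
                 tolerance = 1e-8)
    expect_gte(fit$r2_improvement, 0)
    expect_true(all(abs(residuals(fit) -
                          (y - predict(fit))) < 1e-8))
  }
})

test_that("trajectory classification separates line, U, and inverted U", {
  ages <- bin_midpoints()
  lin <- fit_trajectory(100 + 3 * ages, ages)
  expect_equal(lin$pattern, "linear")
  expect_equal(lin$linear[["r2"]], 1)
  expect_equal(lin$r2_improvement, 0, tolerance = 1e-9)

  # pure quadratic with an interior maximum
  invu <- fit_trajectory(20000 - 5 * (ages - 52)^2, ages)
  expect_equal(invu$pattern, "inverted-U")
  expect_gt(invu$r2_improvement, 0.2)
  expect_equal(invu$extremum_age, 52, tolerance = 0.5)

  ush <- fit_trajectory(20000 + 5 * (ages - 58)^2, ages)
  expect_equal(ush$pattern, "U-shaped")

  # a strong cubic kink that fails the improvement threshold stays linear
  weak <- fit_trajectory(100 + 3 * ages + stats::rnorm(7, 0, 1e-4), ages)
  expect_equal(weak$pattern, "linear")

  # fewer than 4 points: linear fit only
  short <- fit_trajectory(c(10, 20, 15), c(25.5, 35.5, 45.5))
  expect_null(short$cubic)
  expect_equal(short$pattern, "linear")
})

test_that("generative patterns are recovered across many noise seeds", {
  ages <- bin_midpoints()
  truth_u <- 10000 + 4 * (ages - 53)^2      # interior minimum near 53
  truth_n <- 10000 - 4 * (ages - 53)^2
  sigma <- 400   # curve deviation from the chord is several noise SDs
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    f1 <- fit_trajectory(truth_u + stats::rnorm(7, 0, sigma), ages)
    f2 <- fit_trajectory(truth_n + stats::rnorm(7, 0, sigma), ages)
    hits <- hits + (f1$pattern == "U-shaped") + (f2$pattern == "inverted-U")
  }
  expect_gte(hits / 400, 0.95)
})

test_that("trajectory table combines classification and change statistics", {
  m <- bin_means_matrix()[c("Caudate", "Thalamus"), ]
  tt <- trajectory_table(m)
  expect_equal(tt$region, c("Caudate", "Thalamus"))
  expect_equal(tt$pattern, c("U-shaped", "linear"))
  expect_equal(round(tt$endpoint_change, 1), c(6.6, -18.9))
})
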