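# Depth trends, group tests, TOST equivalence, quality gate.

test_that("pearson agrees with the hand-computed covariance ratio", {
  x <- c(1, 3, 4, 8, 9)
  y <- c(2, 3, 7, 6, 12)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson(x, y)
  expect_equal(res$r, r_brute)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_error(pearson(x, rep(3, 5)), "variance")
  expect_error(pearson(1:2, 1:2), "3 finite pairs")
})

test_that("p-values are uniform under the null (KS calibration)", {
  withr::with_seed(404, {
    ps <- vapply(1:500, function(i) pearson(rnorm(20), rnorm(20))$p, numeric(1))
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("noise-free panels give r = -1 at both depth-trend scopes", {
  p <- generate_site_panel(seed = 1, n_sites = 8, irep_slope = -1e-4,
                           irep_noise_sd = 0, n_high_co2 = 0,
                           genomes_per_site = 3, coverage = "skip")
  vals <- p$truth
  names(vals)[names(vals) == "true_ptr"] <- "value"
  t1 <- depth_trend(vals, "per_value")
  t2 <- depth_trend(vals, "per_ecosystem_median")
  expect_equal(t1$r, -1, tolerance = 1e-9)
  expect_equal(t2$r, -1, tolerance = 1e-9)
})

test_that("excluding elevated-offset sites strengthens the negative trend", {
  p <- generate_site_panel(seed = 6, n_sites = 12, irep_slope = -1.3e-4,
                           irep_noise_sd = 0.05, high_co2_offset = 0.4,
                           n_high_co2 = 3, genomes_per_site = 3,
                           coverage = "skip")
  vals <- p$truth
  names(vals)[names(vals) == "true_ptr"] <- "value"
  r_all <- depth_trend(vals, "per_value")$r
  r_excl <- depth_trend(vals, "per_value", exclude = vals$high_co2)$r
  expect_lt(r_excl, r_all)
  expect_lt(r_excl, 0)
})

test_that("slope-zero panels center the correlation on the null", {
  withr::with_seed(11, {
    rs <- vapply(1:50, function(i) {
      p <- generate_site_panel(seed = 7000 + i, n_sites = 6,
                               irep_slope = 0, irep_noise_sd = 0.1,
                               n_high_co2 = 0, genomes_per_site = 2,
                               coverage = "skip")
      vals <- p$truth
      names(vals)[names(vals) == "true_ptr"] <- "value"
      depth_trend(vals, "per_value")$r
    }, numeric(1))
    expect_lt(abs(mean(rs)), 0.15)
  })
})

test_that("group tests behave at the extremes", {
  g <- c(1, 2, 3, 4, 5)
  expect_gt(group_tests(g, g, kind = "welch_t")$p, 0.99)
  expect_equal(group_tests(g, g, kind = "mann_whitney_u")$p, 1)
  withr::with_seed(1, {
    a <- rnorm(30)
    b <- rnorm(30) + 10
    expect_lt(group_tests(a, b, kind = "welch_t")$p, 1e-8)
  })
  expect_error(group_tests(1:2, 1:5, kind = "welch_t"), "group sizes")
})

test_that("Kruskal-Wallis on two groups matches the Mann-Whitney U test", {
  withr::with_seed(2, {
    a <- rnorm(30); b <- rnorm(30) + 0.5
    p_kw <- group_tests(a, b, kind = "kruskal_wallis")$p
    p_u <- group_tests(a, b, kind = "mann_whitney_u")$p
    expect_equal(p_kw, p_u, tolerance = 0.02)
    p3 <- group_tests(list(rnorm(10), rnorm(10), rnorm(10) + 2),
                      kind = "kruskal_wallis")$p
    expect_lt(p3, 0.01)
  })
})

test_that("tied degenerate input falls back rather than failing", {
  res <- group_tests(rep(1, 5), rep(1, 6), kind = "mann_whitney_u")
  expect_true(is.finite(res$p) || is.na(res$p))
})

test_that("TOST equivalence verdicts at the extremes", {
  withr::with_seed(55, {
    a <- rnorm(200)
    b <- a + rnorm(200, 0, 1e-6)
    # 33%-power bounds are narrower than the one-sided critical region:
    # both TOST p-values equal P(T > ncp of the bound) even at zero
    # difference, so the verdict stays conservative
    eq33 <- tost_equivalence(a, b)
    ncp <- eq33$bound_d * sqrt(200 * 200 / 400)
    expect_equal(eq33$p_lower, stats::pt(ncp, 398, lower.tail = FALSE),
                 tolerance = 1e-3)
    expect_identical(eq33$verdict, "not shown")
    # bounds from 50% power are wide enough to show equivalence
    expect_identical(tost_equivalence(a, b, power_for_bound = 0.5)$verdict,
                     "equivalent")
    expect_identical(tost_equivalence(a, a + 5)$verdict, "not shown")
  })
})

test_that("TOST bound matches a brute-force power-grid search", {
  withr::with_seed(66, {
    cases <- list(c(8, 12), c(20, 20), c(15, 40))
    for (ns in cases) {
      a <- rnorm(ns[1]); b <- rnorm(ns[2])
      eq <- tost_equivalence(a, b)
      grid <- seq(1e-4, 5, by = 1e-5)
      pw <- t_test_power(grid, ns[1], ns[2], 0.05)
      d_grid <- grid[which.min(abs(pw - 0.33))]
      expect_lt(abs(eq$bound_d - d_grid), 1e-4)
    }
  })
})

test_that("TOST bound tightens as sample size grows", {
  withr::with_seed(77, {
    bounds <- vapply(c(6, 12, 25, 50, 100), function(n)
      tost_equivalence(rnorm(n), rnorm(n))$bound_d, numeric(1))
    expect_true(all(diff(bounds) < 0))
  })
})

test_that("quality gate keeps boundary values and matches the row oracle", {
  q <- data.frame(genome_id = c("a", "b", "c", "d"),
                  completeness = c(70, 69.9, 95, 100),
                  contamination = c(10, 5, 10.1, 0))
  kept <- quality_gate(q)
  expect_setequal(kept$genome_id, c("a", "d"))
  expect_error(quality_gate(data.frame(completeness = 50)), "quality")
  expect_error(quality_gate(data.frame(completeness = 120, contamination = 5)),
               "quality")
  withr::with_seed(88, {
    for (rep in 1:20) {
      q2 <- data.frame(completeness = runif(30, 0, 100),
                       contamination = runif(30, 0, 100))
      expect_equal(quality_gate(q2), oracle_quality_gate(q2))
    }
  })
})
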