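test_that("exact occupancy cdf matches closed forms and enumeration", {
  # 2 balls, 2 urns: split 1/1 in 2 of 4 outcomes
  expect_equal(exact_cdf(2, 2, 2), 0.5)
  # 3 balls, 3 urns, all distinct: 3! of 27 outcomes
  expect_equal(exact_cdf(3, 3, 2), 6 / 27)
  expect_equal(exact_cdf(4, 3, 5), 1) # x > n
  expect_equal(exact_cdf(10, 3, 2), 0) # pigeonhole
  # full enumeration over K^n outcomes
  for (K in 2:4) {
    for (n in 2:6) {
      for (x in 1:(n + 1)) {
        expect_equal(exact_cdf(n, K, x), enum_fmax_cdf(n, K, x),
                     tolerance = 1e-12,
                     info = sprintf("n=%d K=%d x=%d", n, K, x))
      }
    }
  }
})

test_that("exact upper tail matches closed-form combinatorics", {
  # all 6 balls in one of 85 urns
  expect_equal(exact_pvalue(6, 85, 6), 85^-5, tolerance = 1e-6)
  # >= 5 of 6 balls in some urn: 85 * (C(6,5) * 84 + 1) / 85^6
  expect_equal(exact_pvalue(6, 85, 5), 42925 / 85^6, tolerance = 1e-6)
  expect_equal(exact_pvalue(1, 85, 1), 1)
  expect_equal(exact_pvalue(5, 85, 5), 85^-4, tolerance = 1e-6)
})

test_that("cdf and pvalue are complementary, monotone and in [0,1]", {
  for (n in c(10, 50, 200)) {
    cdfs <- vapply(1:(n + 1), function(x) exact_cdf(n, 85, x), 0)
    pvs <- vapply(1:(n + 1), function(x) exact_pvalue(n, 85, x), 0)
    expect_true(all(cdfs >= 0 & cdfs <= 1))
    expect_true(all(pvs >= 0 & pvs <= 1))
    expect_true(all(diff(cdfs) >= 0))
    expect_true(all(diff(pvs) <= 0))
    mid <- which(pvs > 1e-6) # where 1 - cdf carries full precision
    expect_equal(cdfs[mid] + pvs[mid], rep(1, length(mid)), tolerance = 1e-9)
  }
})

test_that("refined tiny tails agree with the naive complement where both work", {
  # around p ~ 1e-7..1e-10 the complement is still meaningful to ~1e-16
  # absolute; the inclusion-exclusion refinement must agree
  for (n in c(50, 200, 600)) {
    for (x in 1:n) {
      pv <- exact_pvalue(n, 85, x)
      if (pv < 1e-13 || pv > 1e-8) next
      naive <- 1 - exact_cdf(n, 85, x)
      expect_equal(pv, naive, tolerance = 1e-4,
                   info = sprintf("n=%d x=%d", n, x))
    }
  }
})

test_that("asymptotic percentile follows the closed formula", {
  a <- stat_params()$alpha
  f <- function(n, K, alpha) {
    n / K + sqrt(n * log(K) / K) -
      (log(log(1 / (1 - alpha))) + 1.266) * sqrt(n / (2 * K * log(K)))
  }
  expect_equal(approx_percentile(85, 85, 0.01), f(85, 85, 0.01))
  expect_equal(approx_percentile(85, 85, 0.01), 4.226, tolerance = 1e-3)
  # strictly increasing in n; decreasing in alpha
  ns <- seq(100, 2000, by = 100)
  expect_true(all(diff(vapply(ns, approx_percentile, 0, K = 85,
                              alpha = a)) > 0))
  alphas <- c(1e-10, 1e-8, 1e-4, 0.01, 0.5)
  expect_true(all(diff(vapply(alphas, function(al)
    approx_percentile(500, 85, al), 0)) < 0))
  expect_error(approx_percentile(100, 85, 0), "alpha")
  expect_error(approx_percentile(100, 85, 1), "alpha")
})

test_that("cutoffs reproduce the minimum attainable significance", {
  expect_equal(fcut(6, 85), 6L) # smallest attainable cutoff
  expect_equal(fcut(5, 85), 6L) # > n: a total of 5 is never significant
  expect_equal(fcut(1, 85), 2L) # single occurrence never significant
  expect_equal(fcut(0, 85), 1L)
  tab <- fcut_table(600, 85)
  expect_true(all(diff(tab) >= 0)) # nondecreasing in n
  expect_equal(tab[6], 6L)
  # vectorized fcut spans the exact/approximate switchover
  v <- fcut(c(5, 6, 600, 601, 1000), 85)
  expect_equal(v[1:3], c(6L, 6L, tab[600]))
  expect_true(v[4] >= v[3] - 3 && v[5] > v[4])
})

test_that("approximate and exact cutoffs agree closely for K = 85", {
  # documented tolerance: the asymptotic percentile undershoots the exact
  # cutoff by at most 3 counts over n = 500..700 at alpha ~ 1e-8
  a <- 1e-8
  for (n in c(500, 550, 600)) {
    x <- 1
    while (exact_pvalue(n, 85, x) > a) x <- x + 1
    expect_lte(abs(ceiling(approx_percentile(n, 85, a)) - x), 3)
  }
})

test_that("Monte Carlo fmax matches the exact distribution", {
  s <- simulate_fmax(2, 2, 1e4, seed = 42)
  expect_equal(simulate_fmax(2, 2, 1e4, seed = 42), s) # deterministic
  p2 <- mean(s == 2)
  expect_lt(abs(p2 - 0.5), 3 * sqrt(0.25 / 1e4))

  s <- simulate_fmax(50, 85, 2e4, seed = 7)
  for (x in 2:6) {
    p <- exact_cdf(50, 85, x)
    se <- sqrt(p * (1 - p) / 2e4)
    expect_lt(abs(mean(s < x) - p), 3 * se + 1e-12)
  }
})
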