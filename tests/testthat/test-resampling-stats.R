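test_that("cv matches hand arithmetic and is scale invariant", {
  expect_equal(cv(c(2, 2, 2)), 0)
  expect_equal(cv(c(2, 4)), sqrt(2) / 3, tolerance = 1e-10)  # 0.4714
  expect_equal(round(cv(c(2, 4)), 4), 0.4714)
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(cv(7 * x), cv(x), tolerance = 1e-12)
  expect_error(cv(c(3)), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("the paired sign-flip test matches exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:3) {
    pre <- rnorm(8)
    post <- rnorm(8, mean = 0.4)
    p_exact <- oracle_signflip_p(pre, post)
    res <- resampling_paired_test(pre, post, n_iter = 10000, seed = rep)
    mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 10000) + 2 / 10000
    expect_lt(abs(res$p_value - p_exact), mc_err + 0.003)
  }
  # all-zero differences give p = 1 exactly
  expect_equal(resampling_paired_test(1:5, 1:5, seed = 1)$p_value, 1)
})

test_that("the unpaired median test matches exhaustive permutation enumeration", {
  set.seed(102)
  for (rep in 1:3) {
    a <- rnorm(4)
    b <- rnorm(4, mean = 1)
    p_exact <- oracle_permutation_median_p(a, b)
    res <- resampling_unpaired_median_test(a, b, n_iter = 10000, seed = rep)
    mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 10000) + 2 / 10000
    expect_lt(abs(res$p_value - p_exact), mc_err + 0.003)
  }
  # identical multisets give p near 1
  x <- c(1, 2, 3, 4)
  expect_gt(resampling_unpaired_median_test(x, x, n_iter = 2000,
                                            seed = 1)$p_value, 0.9)
})

test_that("the unpaired median test detects a 2-sd location shift at n = 20/20", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    a <- rnorm(20)
    b <- rnorm(20, mean = 2)
    resampling_unpaired_median_test(a, b, n_iter = 2000, seed = s)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("resampling one-way ANOVA is calibrated under the null and detects effects", {
  set.seed(103)
  ps <- vapply(1:150, function(i) {
    groups <- list(rnorm(6), rnorm(6), rnorm(6))
    resampling_oneway_anova(groups, n_iter = 400, seed = i)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.1)        # uniform null p
  expect_lt(mean(ps < 0.05), 0.11)
  # maximal separation with tied values: the exhaustive null has 2 of the
  # C(4,2) = 6 label splits reproducing the separation, so the exact p is 1/3
  res <- resampling_oneway_anova(list(c(0, 0), c(10, 10)), n_iter = 3000,
                                 seed = 1)
  expect_lt(abs(res$p_value - 1 / 3), 0.03)
  # maximal separation with continuous values: p near the attainable
  # minimum (the exact null reproduces the split with probability 2/252)
  res2 <- resampling_oneway_anova(list(rnorm(5), rnorm(5) + 100),
                                  n_iter = 2000, seed = 1)
  expect_lt(res2$p_value, 0.02)
  # distinct implanted syllable means -> significant within-bird effect
  set.seed(104)
  groups <- list(rnorm(20, 100, 3), rnorm(20, 110, 3), rnorm(20, 120, 3))
  expect_lt(resampling_oneway_anova(groups, n_iter = 2000, seed = 2)$p_value,
            0.05)
  expect_error(resampling_oneway_anova(list(c(1, 1), c(1, 1)), seed = 1),
               "undefined")
})

test_that("Mann-Whitney U matches exact rank enumeration for small groups", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  set.seed(105)
  for (rep in 1:5) {
    a <- rnorm(4)
    b <- rnorm(4)
    got <- mann_whitney_u(a, b)
    want <- oracle_mwu(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
  # identical groups: p in the non-significant region
  expect_gt(mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.6)
})

test_that("p-values are reproducible from the seed and never zero", {
  set.seed(106)
  a <- rnorm(10); b <- rnorm(10, 2)
  r1 <- resampling_unpaired_median_test(a, b, n_iter = 1000, seed = 7)
  r2 <- resampling_unpaired_median_test(a, b, n_iter = 1000, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)   # add-one correction
  pre <- rnorm(6); post <- pre + 100
  expect_gt(resampling_paired_test(pre, post, n_iter = 500,
                                   seed = 1)$p_value, 0)
})

test_that("bootstrap power is near alpha under the null, ~1 for huge effects, monotone in n", {
  # case-resampling power is upward-biased near the null at small n (the
  # bootstrap recenters on the observed, not the true, effect); average
  # over null datasets and allow that bias
  set.seed(107)
  p0 <- mean(vapply(1:20, function(i) {
    null_data <- list(pre = rnorm(25), post = rnorm(25))
    resampling_power(null_data, "paired", n_outer = 60, n_iter = 300,
                     seed = i)$power
  }, numeric(1)))
  expect_gt(p0, 0.01)
  expect_lt(p0, 0.2)
  big <- list(pre = rnorm(12), post = rnorm(12) + 10)
  p1 <- resampling_power(big, "paired", n_outer = 100, n_iter = 300,
                         seed = 2)$power
  expect_gt(p1, 0.95)
  # monotone in sample size at fixed effect
  set.seed(108)
  shift <- 1.2
  powers <- vapply(c(5, 10, 20, 40), function(n) {
    d <- list(pre = rnorm(n), post = rnorm(n) + shift)
    resampling_power(d, "paired", n_outer = 150, n_iter = 300,
                     seed = n)$power
  }, numeric(1))
  expect_gt(powers[4], powers[1])
  expect_true(all(diff(powers) > -0.15))  # statistical monotonicity
})
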