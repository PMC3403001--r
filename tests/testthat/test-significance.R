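test_that("surrogates are value-preserving permutations", {
  x <- withr::with_seed(1, rnorm(50))
  s1 <- shuffle_surrogate(x, seed = 10)
  s2 <- shuffle_surrogate(x, seed = 11)
  expect_identical(sort(s1), sort(x))
  expect_false(identical(s1, x))
  expect_false(identical(s1, s2))
  expect_identical(shuffle_surrogate(x, seed = 10), s1)
})

test_that("shuffling the source destroys the transfer entropy", {
  p <- simulate_pair(200, 20, seed = 3)
  te0 <- estimate_te(p$x, p$y, 2, "fixed_bin", Q = 4)$te_bits
  te_sh <- sapply(1:20, function(s) {
    estimate_te(shuffle_surrogate(p$x, seed = s), p$y, 2, "fixed_bin",
                Q = 4)$te_bits
  })
  expect_lt(median(te_sh), te0)
})

test_that("surrogate test flags strong coupling and is seed-stable", {
  p <- coupled_pair(150, lag = 2, noise = 0.1)
  for (m in c("fixed_bin", "kde", "dv")) {
    st <- surrogate_test(p$x, p$y, 2, method = m, Q = 4, alpha = 1.5,
                         n_surrogates = 100, seed = 42)
    expect_true(st$significant)
    expect_gt(st$te_original, max(st$te_surrogates))
    expect_equal(st$percentile_95,
                 unname(quantile(st$te_surrogates, 0.95, type = 7)))
    st2 <- surrogate_test(p$x, p$y, 2, method = m, Q = 4, alpha = 1.5,
                          n_surrogates = 100, seed = 42)
    expect_identical(st$te_surrogates, st2$te_surrogates)
  }
  expect_error(surrogate_test(p$x, p$y, 2, n_surrogates = 10), "20")
})

test_that("surrogate fast paths agree with the generic estimator", {
  # the surrogate engine precomputes target-side structures; its original-TE
  # value must equal the plain estimate exactly
  p <- coupled_pair(120, lag = 3, noise = 0.3, seed = 5)
  for (m in c("fixed_bin", "kde", "dv")) {
    st <- surrogate_test(p$x, p$y, 3, method = m, Q = 4, alpha = 1.5,
                         n_surrogates = 20, seed = 1)
    expect_equal(st$te_original,
                 estimate_te(p$x, p$y, 3, m, Q = 4, alpha = 1.5)$te_bits,
                 tolerance = 1e-12)
  }
})

test_that("lag scan finds the true coupling lag and degenerates cleanly", {
  p <- coupled_pair(220, lag = 2, noise = 0.2, seed = 9)
  sc <- scan_lags(p$x, p$y, 0:5, method = "fixed_bin", Q = 4,
                  n_surrogates = 100, seed = 7)
  expect_equal(attr(sc, "best_tau"), 2L)
  expect_equal(nrow(sc), 6)
  gl <- glance(sc)
  expect_equal(gl$best_tau, 2L)
  expect_true(gl$te_bits >= max(sc$te_bits[sc$significant]) - 1e-12)

  # independent series: no significant lag, best_tau is NA
  xi <- withr::with_seed(31, rnorm(120))
  yi <- withr::with_seed(32, rnorm(120))
  sc0 <- scan_lags(xi, yi, 1:5, method = "fixed_bin", Q = 4,
                   n_surrogates = 50, seed = 3)
  if (!any(sc0$significant)) {
    expect_true(is.na(attr(sc0, "best_tau")))
  }

  # a single-lag range reduces to the surrogate test at that lag
  sc1 <- scan_lags(p$x, p$y, 2, method = "fixed_bin", Q = 4,
                   n_surrogates = 50, seed = 13)
  st <- surrogate_test(p$x, p$y, 2, method = "fixed_bin", Q = 4,
                       n_surrogates = 50,
                       seed = tentropy:::derive_seed(13, 7L, 2))
  expect_equal(sc1$te_bits, st$te_original)
  expect_equal(sc1$percentile_95, st$percentile_95)
})

test_that("rank-sum comparison matches exact enumeration and conventions", {
  expect_lt(compare_unpaired(rnorm(100), rnorm(100) + 10), 1e-10)
  s <- withr::with_seed(3, rnorm(30))
  # identical samples: fully tied, exact distribution unavailable
  expect_gte(suppressWarnings(compare_unpaired(s, s)), 0.5)
  expect_warning(p <- compare_unpaired(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(p, 0.5)
  # exact case: {1,2,3} vs {4,5,6} over all C(6,3) assignments
  want <- oracle_ranksum_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(want, 1 / 20)
  expect_equal(compare_unpaired(c(1, 2, 3), c(4, 5, 6)), want)
})

test_that("signed-rank comparison matches exact enumeration and conventions", {
  pre <- withr::with_seed(4, rnorm(10))
  # all differences equal: ranks of |d| are tied, so the exact distribution
  # is unavailable and the normal approximation is used
  expect_lt(suppressWarnings(compare_paired(pre, pre + 1)), 0.01)
  expect_warning(p <- compare_paired(pre, pre), "tied")
  expect_equal(p, 0.5)
  expect_error(compare_paired(pre[1:3], pre[1:3] + 1), "4 pairs")
  expect_error(compare_paired(1:5, 1:4), "equal length")
  # six hand-listed pairs (distinct |differences|, so the exact signed-rank
  # distribution applies) against the 2^6 sign-flip enumeration
  pre6 <- c(0.31, 0.42, 0.25, 0.50, 0.38, 0.44)
  post6 <- c(0.46, 0.40, 0.33, 0.61, 0.52, 0.49)
  expect_equal(compare_paired(pre6, post6),
               oracle_signedrank_exact(pre6, post6))
})

test_that("surrogate test keeps its nominal false-positive rate", {
  # independent pairs: the 95th-percentile rule should reject ~5% of the time
  rej <- sapply(1:100, function(seed) {
    x <- withr::with_seed(seed + 5000, rnorm(80))
    y <- withr::with_seed(seed + 6000, rnorm(80))
    surrogate_test(x, y, 2, method = "fixed_bin", Q = 4,
                   n_surrogates = 100, seed = seed)$significant
  })
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)
})
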