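# Percent-difference maps, pass fractions, and the threshold statistic.

# a pair of doses on a 3x3 grid where one point differs by 6% of the
# global max (the same arithmetic as the classic 2x2 hand example)
mk_pair <- function() {
  R <- matrix(10, 3, 3)
  E <- matrix(10, 3, 3)
  E[1, 2] <- 9.4
  list(ref = as_dose(R), eval = as_dose(E))
}

test_that("percent-difference map reproduces hand arithmetic", {
  pr <- mk_pair()
  cfg <- comparison_config(low_dose_cutoff_fraction = 0)
  pd <- percent_diff_map(pr$ref, pr$eval, cfg)
  expected <- matrix(0, 3, 3); expected[1, 2] <- 6
  expect_equal(pd$diff, expected, tolerance = 1e-12)
  expect_true(all(pd$mask))
  # identical maps give all zeros
  pd0 <- percent_diff_map(pr$ref, pr$ref, cfg)
  expect_true(all(pd0$diff == 0))
  # grid mismatch is refused, never silently resampled
  other <- as_dose(matrix(10, 5, 5))
  expect_error(percent_diff_map(pr$ref, other, cfg),
               class = "arcqa_alignment_error")
})

test_that("the low-dose cutoff excludes points below the fraction of max", {
  R <- matrix(10, 3, 3); R[1, 2] <- 2
  cfg <- comparison_config(low_dose_cutoff_fraction = 0.5)
  pd <- percent_diff_map(as_dose(R), as_dose(R), cfg)
  expect_false(pd$mask[1, 2])
  expect_equal(sum(pd$mask), 8)
})

test_that("pass fraction enumerates the example and is monotone in delta", {
  pr <- mk_pair()
  cfg <- comparison_config(low_dose_cutoff_fraction = 0)
  pd <- percent_diff_map(pr$ref, pr$eval, cfg)
  expect_equal(pass_fraction(pd$diff, pd$mask, 5), 8 / 9)
  expect_equal(pass_fraction(pd$diff, pd$mask, 6), 1.0)
  expect_equal(pass_fraction(pd$diff, pd$mask, 100), 1.0)
  # the literal 2x2 enumeration: diffs {0, 0, 0, 6}
  d22 <- matrix(c(0, 0, 0, 6), 2, 2)
  m22 <- matrix(TRUE, 2, 2)
  expect_equal(pass_fraction(d22, m22, 5), 0.75)
  expect_equal(pass_fraction(d22, m22, 6), 1.0)
  expect_error(pass_fraction(pd$diff, matrix(FALSE, 3, 3), 5),
               class = "arcqa_statistic_error")
  set.seed(11)
  for (rep in 1:20) {
    d <- matrix(rnorm(49, sd = 5), 7, 7)
    m <- matrix(TRUE, 7, 7)
    deltas <- seq(0, 15, by = 0.5)
    pf <- vapply(deltas, function(x) pass_fraction(d, m, x), numeric(1))
    expect_true(all(diff(pf) >= 0))
  }
})

test_that("threshold equals the ceiling-quantile order statistic", {
  pr <- mk_pair()
  cfg <- comparison_config(low_dose_cutoff_fraction = 0,
                           target_match_fraction = 0.95)
  r <- threshold_to_target(pr$ref, pr$eval, cfg)
  # |diff| = {0 x8, 6}; ceiling(0.95 * 9) = 9 -> 6%
  expect_equal(r$threshold_at_target, 6, tolerance = 1e-9)
  expect_equal(threshold_to_target(pr$ref, pr$ref, cfg)$threshold_at_target, 0)
  # the pass-fraction curve stored in the result is non-decreasing
  expect_true(all(diff(r$pass_fraction_curve$pass_fraction) >= 0))
})

test_that("scan-grid search agrees with the order-statistic oracle", {
  set.seed(42)
  cfg <- comparison_config(low_dose_cutoff_fraction = 0)
  for (rep in 1:100) {
    n <- 9
    R <- matrix(runif(n^2, 1, 10), n, n)
    E <- R + matrix(rnorm(n^2, sd = 0.4), n, n)
    E[E < 0] <- 0
    ref <- as_dose(R); ev <- as_dose(E)
    exact <- threshold_to_target(ref, ev, cfg)$threshold_at_target
    scan <- threshold_to_target(ref, ev, cfg,
                                method = "scan")$threshold_at_target
    # the scan returns the smallest grid point at or above the exact value
    expect_gte(scan + 1e-9, exact)
    expect_lt(scan - exact, 0.1 + 1e-9)
  }
})

test_that("threshold is symmetric in the map pair under a shared normalization", {
  set.seed(7)
  cfg <- comparison_config(low_dose_cutoff_fraction = 0)
  for (rep in 1:10) {
    R <- matrix(runif(25, 1, 10), 5, 5)
    E <- R + matrix(rnorm(25, sd = 0.3), 5, 5)
    N <- max(R)
    a <- threshold_to_target(as_dose(R), as_dose(E), cfg,
                             norm_value = N)$threshold_at_target
    b <- threshold_to_target(as_dose(E), as_dose(R), cfg,
                             norm_value = N)$threshold_at_target
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("unreachable targets within the scan range raise a range error", {
  R <- matrix(10, 3, 3)
  E <- matrix(1, 3, 3)  # 90% differences everywhere
  cfg <- comparison_config(low_dose_cutoff_fraction = 0)
  expect_error(threshold_to_target(as_dose(R), as_dose(E), cfg),
               class = "arcqa_range_error")
})

test_that("local normalization divides by the local reference dose", {
  R <- matrix(c(10, 5, 10, 10, 10, 10, 10, 10, 10), 3, 3)
  E <- R; E[2, 1] <- 4  # ref 5 -> eval 4: 20% locally, 10% globally
  cfg_l <- comparison_config("local", low_dose_cutoff_fraction = 0)
  cfg_g <- comparison_config("global", low_dose_cutoff_fraction = 0)
  expect_equal(percent_diff_map(as_dose(R), as_dose(E), cfg_l)$diff[2, 1], 20)
  expect_equal(percent_diff_map(as_dose(R), as_dose(E), cfg_g)$diff[2, 1], 10)
})
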