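test_that("exact signed-rank p-values match full 2^N enumeration, including ties", {
  set.seed(51)
  for (n in c(5, 8, 12)) {
    for (rep in 1:4) {
      d <- round(rnorm(n), 1)           # rounding forces occasional ties
      d[d == 0] <- 0.1
      for (alt in c("greater", "two.sided")) {
        got <- signed_rank_test(d, alternative = alt)$p_value
        expect_equal(got, signed_rank_bf(d, alt), tolerance = 1e-12,
                     label = sprintf("n=%d alt=%s", n, alt))
      }
    }
  }
})

test_that("exact p-values agree with stats::wilcox.test on tie-free data", {
  set.seed(52)
  for (rep in 1:5) {
    d <- rnorm(15)
    expect_equal(signed_rank_test(d, alternative = "greater")$p_value,
                 wilcox.test(d, alternative = "greater", exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(signed_rank_test(d, alternative = "two.sided")$p_value,
                 wilcox.test(d, alternative = "two.sided", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("boundary cases: all-positive, mixed two-value, and all-negative samples", {
  all_pos <- signed_rank_test_greater(rexp(20) + 0.01)
  expect_equal(all_pos$p_value, 2^-20, tolerance = 1e-15)
  expect_true(all_pos$significant)

  expect_equal(signed_rank_test(c(2, -1))$p_value, 0.5)

  all_neg <- signed_rank_test_greater(-rexp(20) - 0.01)
  expect_gt(all_neg$p_value, 0.99)
  expect_false(all_neg$significant)
})

test_that("zeros are dropped before ranking; an all-zero sample is undefined", {
  a <- signed_rank_test(c(0, 0, 3, -1, 2))
  b <- signed_rank_test(c(3, -1, 2))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$n, 3)
  expect_error(signed_rank_test(c(0, 0, 0)), "undefined test")
})

test_that("the normal approximation is close to exact just above the cutoff", {
  set.seed(53)
  d <- rnorm(26, mean = 0.3)
  approx <- signed_rank_test(d)$p_value
  exact <- signed_rank_test(d, exact_limit = 30)$p_value
  expect_equal(approx, exact, tolerance = 0.05)
})

test_that("the one-sided exact test is calibrated under the symmetric null", {
  set.seed(54)
  rejections <- mean(replicate(2000, {
    signed_rank_test_greater(rnorm(20), alpha = 0.05)$significant
  }))
  expect_gt(rejections, 0.035)
  expect_lt(rejections, 0.065)
})

test_that("the equality-of-fits test is calibrated under exchangeable fits", {
  set.seed(55)
  ps <- replicate(400, {
    f <- rnorm(20, mean = 0.5, sd = 0.05)
    equality_of_fits_test(f + rnorm(20, sd = 0.03), f + rnorm(20, sd = 0.03))$p_value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps < 0.5), 0.40)
})

test_that("a constant offset between paired fits is detected at the 2^-19 scale", {
  set.seed(56)
  f <- rnorm(20, 0.5, 0.05)
  res <- equality_of_fits_test(f + 1, f)
  expect_equal(res$p_value, 2^-19, tolerance = 1e-12)
  expect_error(equality_of_fits_test(f, f), "undefined test")
  expect_error(equality_of_fits_test(f, f[-1]), "equal length")
})

test_that("the connectivity verdict follows its two clauses and is offset-monotone", {
  set.seed(57)
  base <- rnorm(20, 0.5, 0.05)
  good <- model_based_connectivity_verdict(base, base + rnorm(20, sd = 0.05))
  expect_true(good$verdict)

  # one region with negative fits kills positivity
  bad <- model_based_connectivity_verdict(base, -base)
  expect_false(bad$verdict)

  # fits straddling zero in both regions: not significantly positive, but
  # exchangeable, so the equality clause is satisfied
  w1 <- rnorm(20, 0.02, 0.05)
  weak <- model_based_connectivity_verdict(w1, w1 + rnorm(20, 0, 0.02))
  expect_false(weak$verdict)

  # adding the same constant to both regions can only help: the paired
  # differences (and so the equality clause) are unchanged
  shifted <- model_based_connectivity_verdict(weak$positivity_roi1$per_subject_values + 2,
                                              weak$positivity_roi2$per_subject_values + 2)
  expect_true(shifted$verdict)
  again <- model_based_connectivity_verdict(good$positivity_roi1$per_subject_values + 2,
                                            good$positivity_roi2$per_subject_values + 2)
  expect_true(again$verdict)
  expect_equal(again$equality$p_value, good$equality$p_value)
})

test_that("a vanishing common input produces no connectivity change and no relation", {
  cfg <- small_config(n_time = 40, common_input_variance = 1e-10)
  res <- noise_sensitivity_analysis(cfg, n_subjects = 6, master_seed = 3)
  expect_true(all(abs(res$pairs$connectivity_change) < 0.05))
  expect_equal(nrow(res$pairs), 6)
})
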