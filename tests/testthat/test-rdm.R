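test_that("compute_rdm gives 1 - Pearson dissimilarities with hand-computed values", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 3, 2))
  r <- compute_rdm(x)
  expect_equal(r["a", "b"], 2.0)
  expect_equal(r["a", "c"], 0.5)
  expect_equal(r["b", "c"], 1.5)
  expect_equal(diag(unclass(r)), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(unclass(r)))

  # identical rows at dissimilarity 0, a row and its negation at 2
  y <- rbind(p = c(1, 2, 3, 1), q = c(1, 2, 3, 1), r = -c(1, 2, 3, 1))
  ry <- compute_rdm(y)
  expect_equal(ry["p", "q"], 0)
  expect_equal(ry["p", "r"], 2)
})

test_that("compute_rdm rejects degenerate inputs, naming the condition", {
  x <- rbind(a = c(1, 2, 3), flatline = c(2, 2, 2), c = c(1, 3, 2))
  expect_error(compute_rdm(x), "flatline")
  expect_error(compute_rdm(x[1:2, ]), "at least 3 conditions")
  expect_error(compute_rdm(matrix(rnorm(3), 3, 1)), "at least 2 channels")
})

test_that("compute_rdm is invariant to shifting or positively rescaling a row", {
  set.seed(41)
  x <- matrix(rnorm(5 * 30), 5, 30)
  base <- compute_rdm(x)
  x2 <- x; x2[3, ] <- 10 + 2.5 * x2[3, ]
  expect_equal(unclass(compute_rdm(x2)), unclass(base), tolerance = 1e-12)
})

test_that("upper_vector is row-major (i < j) with documented order and length", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  v <- upper_vector(rdm(m, condition_ids = c("a", "b", "c")))
  expect_equal(unname(v), c(0.1, 0.2, 0.3))
  expect_equal(names(v), c("a:b", "a:c", "b:c"))

  # 16 conditions give n(n-1)/2 = 120 elements; 2 conditions give 1
  d <- factorial_design(position = 4, category = 4)
  expect_length(upper_vector(binary_factor_model(d, "position")), 120)
  expect_length(upper_vector(rdm(matrix(c(0, .5, .5, 0), 2, 2))), 1)

  # agreement with an explicit double loop on a random RDM
  set.seed(7)
  r <- compute_rdm(matrix(rnorm(16 * 20), 16, 20))
  expect_equal(unname(upper_vector(r)), ut_bf(unclass(r)))
})

test_that("rdm validation refuses asymmetry, non-zero diagonals and range violations", {
  m <- matrix(c(0, .1, .3, 0), 2, 2)
  expect_error(rdm(m), "not symmetric")
  m2 <- matrix(c(0.2, .1, .1, 0), 2, 2)
  expect_error(rdm(m2), "diagonal")
  m3 <- matrix(c(0, 2.5, 2.5, 0), 2, 2)
  expect_error(rdm(m3), "outside")
})

test_that("compare_rdms is a Pearson correlation on upper triangles", {
  set.seed(11)
  a <- compute_rdm(matrix(rnorm(16 * 25), 16, 25))
  b <- compute_rdm(matrix(rnorm(16 * 25), 16, 25))
  expect_equal(compare_rdms(a, a), 1.0)
  expect_equal(compare_rdms(a, b), compare_rdms(b, a))
  # brute-force sum-formula oracle to 1e-10 over random 16-condition RDMs
  for (k in 1:5) {
    x <- compute_rdm(matrix(rnorm(16 * 25), 16, 25))
    y <- compute_rdm(matrix(rnorm(16 * 25), 16, 25))
    expect_equal(compare_rdms(x, y),
                 pearson_bf(ut_bf(unclass(x)), ut_bf(unclass(y))),
                 tolerance = 1e-10)
  }
})

test_that("compare_rdms aligns conditions by ordered label, not position", {
  set.seed(12)
  x <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(letters[1:4], NULL))
  a <- compute_rdm(x)
  b <- compute_rdm(x[c(2, 1, 3, 4), ])
  expect_error(compare_rdms(a, b), "align")
  flat <- rdm(matrix(0.5, 4, 4) - diag(0.5, 4), condition_ids = letters[1:4])
  expect_error(compare_rdms(a, flat), "zero variance")
})

test_that("compare_rdms is invariant to a consistent relabeling of both RDMs", {
  set.seed(13)
  x <- matrix(rnorm(6 * 15), 6, 15, dimnames = list(letters[1:6], NULL))
  y <- matrix(rnorm(6 * 15), 6, 15, dimnames = list(letters[1:6], NULL))
  perm <- sample(6)
  r0 <- compare_rdms(compute_rdm(x), compute_rdm(y))
  r1 <- compare_rdms(compute_rdm(x[perm, ]), compute_rdm(y[perm, ]))
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("rdm_series builds per-sample RDMs and reports degenerate samples", {
  set.seed(14)
  x <- matrix(rnorm(4 * 12), 4, 12, dimnames = list(letters[1:4], NULL))
  s1 <- rdm_series(list(x))
  expect_length(s1, 1)
  expect_equal(unclass(series_rdm(s1, 1)), unclass(compute_rdm(x)), tolerance = 1e-12)

  # constant noise-free patterns give identical RDMs at every sample
  s5 <- rdm_series(rep(list(x), 5))
  expect_equal(s5$vectors[, 1], s5$vectors[, 5])

  bad <- x; bad[2, ] <- 3
  expect_error(rdm_series(list(x, bad, x)), "time sample 2")
})

test_that("every RDM in a simulated 200-sample series satisfies the RDM invariants", {
  cfg <- study_config(n_subjects = 1)
  ds <- simulate_timeseries_subject(cfg, subject_seed(5, 1, 1))
  s <- rdm_series(ds$roi1)
  expect_equal(length(s), 200)
  expect_true(all(s$vectors >= 0 & s$vectors <= 2))
  for (t in c(1, 100, 200)) expect_silent(validate_rdm(series_rdm(s, t)))
})
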