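test_that("level prototypes are centered, orthogonal, and variance-calibrated", {
  d <- factorial_design(position = 4, category = 4)
  p <- make_prototypes(d, "position", 120, 0.5, seed = 3)
  expect_equal(dim(p), c(4, 120))
  expect_equal(rowMeans(p), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(apply(p, 1, var)), rep(0.5, 4), tolerance = 1e-12)
  cp <- cor(t(p))
  expect_equal(cp, diag(4), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("noiseless condition patterns reproduce the binary factor model exactly", {
  d <- factorial_design(position = 4, category = 4)
  cfg <- study_config()
  ds <- simulate_static_subject(cfg, subject_seed(9, 1, 0))
  gt <- ds$ground_truth$roi1
  pm <- binary_factor_model(d, "position")
  expect_equal(unclass(gt), unclass(pm), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unclass(ds$ground_truth$roi2),
               unclass(binary_factor_model(d, "category")),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("different subject seeds give different prototypes with the same RDM zero pattern", {
  d <- factorial_design(position = 4, category = 4)
  p1 <- make_prototypes(d, "position", 60, 0.5, seed = 1)
  p2 <- make_prototypes(d, "position", 60, 0.5, seed = 2)
  expect_false(isTRUE(all.equal(p1, p2)))
  cfg <- study_config()
  a <- simulate_static_subject(cfg, subject_seed(1, 1, 0))
  b <- simulate_static_subject(cfg, subject_seed(1, 2, 0))
  expect_equal(abs(unclass(a$ground_truth$roi1)) < 1e-9,
               abs(unclass(b$ground_truth$roi1)) < 1e-9)
})

test_that("zero signal variance produces degenerate patterns that error downstream", {
  d <- factorial_design(position = 4, category = 4)
  p <- make_prototypes(d, "position", 30, 0, seed = 1)
  expect_true(all(p == 0))
  expect_error(compute_rdm(p[d$position, ]), "degenerate")
})

test_that("simulation is bit-identical given (master seed, subject index)", {
  cfg <- small_config()
  for (gen in list(function(s) simulate_static_subject(cfg, s),
                   function(s) simulate_timeseries_subject(cfg, s),
                   function(s) simulate_windowed_subject(cfg, TRUE, s))) {
    a <- gen(subject_seed(42, 3, 0))
    b <- gen(subject_seed(42, 3, 0))
    expect_identical(a$roi1, b$roi1)
    expect_identical(a$roi2, b$roi2)
  }
  # adding subjects never perturbs earlier subjects' seeds
  expect_identical(subject_seed(42, 1:5, 0), subject_seed(42, 1:9, 0)[1:5])
})

test_that("time-resolved noiseless content is constant across samples", {
  cfg <- small_config()
  ds <- simulate_timeseries_subject(cfg, subject_seed(8, 1, 1))
  # the stored signal is one fixed matrix; samples differ only by noise
  resid1 <- ds$roi1[, , 1] - ds$signal$roi1
  resid2 <- ds$roi1[, , 2] - ds$signal$roi1
  expect_false(isTRUE(all.equal(resid1, resid2)))
  expect_equal(mean(resid1), 0, tolerance = 0.05)
  expect_equal(var(as.vector(resid1)), cfg$noise_variance, tolerance = 0.15)
})

test_that("common input injection preserves the original dataset and ground truths", {
  cfg <- small_config(n_time = 30)
  ds <- simulate_timeseries_subject(cfg, subject_seed(2, 1, 1))
  roi1_before <- ds$roi1
  inj <- inject_common_input(ds, seed = subject_seed(2, 1, 2))
  expect_identical(ds$roi1, roi1_before)
  expect_identical(inj$ground_truth, ds$ground_truth)
  expect_false(isTRUE(all.equal(inj$roi1, ds$roi1)))
  expect_error(inject_common_input(ds, common_input_variance = 0, seed = 1), "> 0")
  expect_error(inject_common_input(simulate_static_subject(cfg, 1), seed = 1),
               "time-resolved")
})

test_that("a vanishing common input leaves the data unchanged up to tolerance", {
  cfg <- small_config(n_time = 10)
  ds <- simulate_timeseries_subject(cfg, subject_seed(3, 1, 1))
  inj <- inject_common_input(ds, common_input_variance = 1e-18, seed = 4)
  expect_equal(inj$roi1, ds$roi1, tolerance = 1e-6)
  expect_equal(inj$roi2, ds$roi2, tolerance = 1e-6)
})

test_that("the mixed common input preserves per-channel variance in ROI 2", {
  cfg <- small_config(n_time = 60)
  ds <- simulate_timeseries_subject(cfg, subject_seed(6, 1, 1))
  for (mix in c("orthonormal", "scaled")) {
    inj <- inject_common_input(ds, seed = subject_seed(6, 1, 2), mixing = mix)
    common2 <- inj$roi2 - ds$roi2   # the injected component, all samples
    v <- var(as.vector(common2))
    expect_lt(abs(v - cfg$common_input_variance) / cfg$common_input_variance, 0.2)
  }
})

test_that("windowed simulation places ROI 2 windows per the delay rule", {
  cfg <- study_config()
  on2 <- replicate(30, {
    ds <- simulate_windowed_subject(cfg, TRUE, sample.int(1e6, 1))
    ds$windows$roi2[1]
  })
  expect_true(all(on2 >= 40 & on2 <= 50))
  off2 <- on2 + 30
  expect_true(all(off2 >= 70 & off2 <= 80))

  w_inc <- replicate(30, {
    ds <- simulate_windowed_subject(cfg, FALSE, sample.int(1e6, 1))
    ds$windows$roi2
  })
  expect_true(all(w_inc >= 0 & w_inc <= 40))

  # no jitter: the delay is exact
  cfg0 <- study_config(jitter_range = c(0, 0))
  ds0 <- simulate_windowed_subject(cfg0, TRUE, 99)
  expect_equal(ds0$windows$roi2, c(50, 80))

  expect_error(simulate_windowed_subject(study_config(base_delay = 150), TRUE, 1),
               "outside")
})

test_that("no information leaks outside the ROI 1 window", {
  cfg <- study_config()
  pm <- binary_factor_model(cfg$design, "position")
  outside <- c()
  for (i in 1:5) {
    ds <- simulate_windowed_subject(cfg, TRUE, subject_seed(4, i, 3))
    fc <- fit_course(rdm_series(ds$roi1), pm)
    idx <- setdiff(seq_len(cfg$n_time), (cfg$window_roi1[1]:cfg$window_roi1[2]) + 1L)
    outside <- c(outside, mean(fc[idx]))
    # and the fits inside the window are clearly positive
    expect_gt(mean(fc[(cfg$window_roi1[1]:cfg$window_roi1[2]) + 1L]), 0.3)
  }
  expect_lt(abs(mean(outside)), 0.05)
})
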