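test_that("stride RMS matches closed forms", {
  expect_equal(stride_rms(rep(3, 17)), 3)
  t <- seq(0, 1, length.out = 513)[1:512]
  expect_equal(stride_rms(2.5 * sin(2 * pi * 4 * t)), 2.5 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(stride_rms(c(1, -1, 1, -1)), 1)
  expect_error(stride_rms(numeric(0)), "empty")
})

test_that("normalized RMS is a scale-invariant ratio", {
  expect_equal(nrms(0.6, 0.8), 0.75)
  expect_equal(nrms(1, 1), 1)
  x <- runif(1, 0.2, 2); y <- runif(1, 0.2, 2)
  expect_equal(nrms(5 * x, 5 * y), nrms(x, y))
  expect_error(nrms(1, 0), "degenerate CC")
})

test_that("symmetry index hits its analytic bounds and midpoint", {
  even <- stride_from_harmonics(c(`2` = 1, `4` = 0.5, `6` = 0.25))
  odd <- stride_from_harmonics(c(`1` = 1, `3` = 0.4, `5` = 0.2))
  expect_equal(ihr(even, "AP"), 100, tolerance = 1e-9)
  expect_equal(ihr(odd, "AP"), 0, tolerance = 1e-9)
  # for ML the parity convention flips
  expect_equal(ihr(odd, "ML"), 100, tolerance = 1e-9)
  # equal intrinsic and extrinsic power -> 50%
  both <- stride_from_harmonics(c(`1` = 1, `2` = 1))
  expect_equal(ihr(both, "AP"), 50, tolerance = 1e-6)
})

test_that("symmetry index is offset-invariant and bounded on arbitrary signals", {
  set.seed(7)
  for (r in 1:20) {
    x <- stride_from_harmonics(setNames(runif(6), 1:6), phases = runif(6, 0, 2 * pi))
    v0 <- ihr(x, "AP")
    expect_gte(v0, 0); expect_lte(v0, 100)
    expect_equal(ihr(x + 17.3, "AP"), v0, tolerance = 1e-9)
  }
  # too few supported harmonics degrades gracefully with a warning
  x <- stride_from_harmonics(c(`1` = 1, `2` = 1))
  expect_warning(v <- ihr(x, "AP", K = 20, resample_len = 32), "harmonics")
  expect_true(v >= 0 && v <= 100)
})

test_that("log dimensionless jerk matches its closed form and invariances", {
  # unit sinusoid over one second: -ln((2*pi)^2 / 2)
  s1 <- 3.7 * sin(2 * pi * seq(0, 1, length.out = 129))
  expect_equal(ldlj(s1, 128), -log((2 * pi)^2 / 2), tolerance = 1e-3)
  # time-stretched to T = 2 s, f = 0.5: -ln((2 pi f)^2 T^4 / 2)
  s2 <- sin(2 * pi * 0.5 * seq(0, 2, length.out = 257))
  expect_equal(ldlj(s2, 128), -log((pi)^2 * 2^4 / 2), tolerance = 1e-3)
  # amplitude scaling cancels exactly
  set.seed(3)
  s3 <- lowpass_filter(rnorm(400), 6, 128)
  expect_equal(ldlj(7.7 * s3, 128), ldlj(s3, 128), tolerance = 1e-12)
  expect_error(ldlj(rep(0, 100), 128), "degenerate")
  expect_error(ldlj(c(1, 2), 128), "too short")
})

test_that("per-trial aggregation uses the configured statistic and stride minimum", {
  ps <- list(a = c(2, 2, 2), b = c(1, 2, 3))
  out <- aggregate_trial_indices(ps)
  expect_equal(out$a, 2)
  expect_equal(out$b, 2)
  expect_equal(out$n_strides_used, 3L)
  out2 <- aggregate_trial_indices(list(b = c(1, 2, 10)), statistic = "median")
  expect_equal(out2$b, 2)
  expect_error(aggregate_trial_indices(list(a = c(1, 2))), "unusable")
})

test_that("trial indices are deterministic and scale-consistent", {
  spec <- noiseless_spec(seed = 21)
  tr <- synthesize_trial(make_profile(spec, 1), "test")
  al <- preprocess_trial(tr)
  res <- process_trial(tr)
  i1 <- compute_trial_indices(al, res$strides)
  i2 <- compute_trial_indices(al, res$strides)
  expect_identical(i1, i2)
  # scaling every pelvis acceleration uniformly leaves nRMS and LDLJa unchanged
  al2 <- al
  al2$sites$pelvis$acc_anat <- 3 * al$sites$pelvis$acc_anat
  i3 <- compute_trial_indices(al2, res$strides)
  for (cl in c("nRMS_AP_pelvis", "nRMS_ML_pelvis", "LDLJa_AP", "LDLJa_ML",
               "LDLJa_CC", "iHR_AP", "iHR_ML", "iHR_CC")) {
    expect_equal(i3[[cl]], i1[[cl]], tolerance = 1e-9)
  }
})
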