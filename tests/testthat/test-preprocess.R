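test_that("static gyro bias is the window mean", {
  n <- 640
  g <- cbind(rep(0.01, n), rep(-0.02, n), rep(0.003, n))
  expect_equal(estimate_static_bias(g, c(1, 384), 128),
               c(0.01, -0.02, 0.003), ignore_attr = TRUE)

  # zero-mean sinusoid over integer periods contributes nothing
  t <- (0:383) / 128
  g2 <- cbind(sin(2 * pi * 2 * t), cos(2 * pi * 4 * t) - mean(cos(2 * pi * 4 * t)),
              rep(0, 384))
  expect_equal(estimate_static_bias(g2, c(1, 384), 128)[1], 0,
               tolerance = 1e-12, ignore_attr = TRUE)

  # white-noise bias estimate obeys the standard-error bound
  set.seed(42)
  fails <- 0
  for (r in 1:50) {
    g3 <- matrix(rnorm(384 * 3, 0, 0.01), ncol = 3)
    b <- estimate_static_bias(g3, c(1, 384), 128)
    fails <- fails + any(abs(b) > 3 * 0.01 / sqrt(384))
  }
  expect_lt(fails / 50, 0.1)

  expect_error(estimate_static_bias(g, c(1, 100), 128), "shorter than 1 s")
})

test_that("gravity alignment maps the static mean to +CC and is orthonormal", {
  mk <- function(v) matrix(rep(v, each = 500), ncol = 3)
  # already aligned
  R1 <- gravity_alignment(mk(c(0, 0, 9.81)), c(1, 500))
  expect_equal(R1, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  # gravity on the sensor x-axis
  R2 <- gravity_alignment(mk(c(9.81, 0, 0)), c(1, 500))
  expect_equal(as.numeric(R2 %*% c(9.81, 0, 0)), c(0, 0, 9.81),
               tolerance = 1e-10)
  # small tilt: rotated static mean is purely CC with preserved norm
  m <- c(0.3, 0.2, 9.7)
  R3 <- gravity_alignment(mk(m), c(1, 500))
  out <- as.numeric(R3 %*% m)
  expect_equal(out[1:2], c(0, 0), tolerance = 1e-10)
  expect_equal(out[3], sqrt(sum(m^2)), tolerance = 1e-10)

  # property: orthonormal, det +1, norm-preserving for random tilts
  set.seed(1)
  for (r in 1:20) {
    v <- c(rnorm(2, 0, 1.5), 9.8)
    R <- gravity_alignment(mk(v), c(1, 500))
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(det(R), 1, tolerance = 1e-10)
    w <- rnorm(3)
    expect_equal(sqrt(sum((R %*% w)^2)), sqrt(sum(w^2)), tolerance = 1e-10)
  }

  expect_error(gravity_alignment(mk(c(0, 0, 2)), c(1, 500)),
               "not quasi-static")
})

test_that("gravity removal touches only the CC column", {
  n <- 900
  t <- (0:(n - 1)) / 128
  ap <- rnorm(n)
  acc <- cbind(ap, rnorm(n), 9.81 + c(rep(0, 384), sin(2 * pi * t[385:n])))
  out <- remove_gravity_cc(acc, c(1, 384))
  expect_identical(out[, 1], acc[, 1])       # bit-for-bit untouched
  expect_equal(mean(out[1:384, 3]), 0, tolerance = 1e-12)
  expect_equal(out[385:n, 3], sin(2 * pi * t[385:n]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-phase Butterworth filtering matches its analytic response", {
  fs <- 128
  expect_equal(lowpass_filter(rep(5, 400), 10, fs), rep(5, 400),
               tolerance = 1e-9)
  t <- (0:2047) / fs
  mid <- 512:1536
  # passband: squared order-2 magnitude at 2 Hz is 1/(1+(2/10)^4) = 0.9984
  y2 <- lowpass_filter(sin(2 * pi * 2 * t), 10, fs)
  expect_equal(max(abs(y2[mid])), 1, tolerance = 0.01)
  # at the cutoff the squared response is 1/2
  y10 <- lowpass_filter(sin(2 * pi * 10 * t), 10, fs)
  expect_equal(max(abs(y10[mid])), 0.5, tolerance = 0.025)
  # filtering an already band-limited signal barely changes its RMS
  xb <- lowpass_filter(rnorm(4096), 2.5, fs)
  yb <- lowpass_filter(xb, 10, fs)
  expect_lt(abs(sqrt(mean(yb^2)) / sqrt(mean(xb^2)) - 1), 0.01)

  expect_error(lowpass_filter(rnorm(100), 64, fs), "Nyquist")
})

test_that("the preprocessing chain is deterministic and satisfies the static invariants", {
  spec <- noiseless_spec(seed = 3)
  tr <- synthesize_trial(make_profile(spec, 1), "test")
  a1 <- preprocess_trial(tr)
  a2 <- preprocess_trial(tr)
  expect_identical(a1, a2)
  sw <- tr$static_window
  for (s in names(a1$sites)) {
    # CC acceleration is gravity-free in the static window
    expect_lt(abs(mean(a1$sites[[s]]$acc_anat[sw[1]:sw[2], "CC"])), 0.05)
    # rotation is proper orthonormal
    R <- a1$sites[[s]]$rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  # bias removal zeroes the static gyro mean before filtering
  bias <- estimate_static_bias(tr$sites$pelvis$gyro, sw, tr$fs)
  debiased <- sweep(tr$sites$pelvis$gyro, 2, bias)
  expect_lt(max(abs(colMeans(debiased[sw[1]:sw[2], ]))), 1e-9)
})
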