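# one stride spanning exactly one period: n interior samples plus the closing
# endpoint, built from sine harmonics (named amplitude vector, phases optional)
stride_from_harmonics <- function(amps, n = 256, phases = NULL) {
  k <- as.integer(names(amps))
  if (is.null(phases)) phases <- rep(0.3, length(k))
  tt <- seq(0, 1, length.out = n + 1)
  s <- numeric(n + 1)
  for (j in seq_along(k)) s <- s + amps[j] * sin(2 * pi * k[j] * tt + phases[j])
  s
}

# noiseless, jitter-free single-subject conditions for analytic-truth work
noiseless_spec <- function(seed = 7, n_strides = 8, ...) {
  cohort_spec(n_subjects = 1, n_strides = n_strides, noise_sd_acc = 0,
              noise_sd_gyro = 0, stride_jitter_cv = 0, seed = seed, ...)
}

# small in-memory paired cohort of trials
tiny_cohort <- function(n = 3, seed = 5, ...) {
  spec <- cohort_spec(n_subjects = n, seed = seed, ...)
  generate_cohort(spec)
}

# shank-like angular velocity with mid-swing bumps at given peak times and
# boundary troughs 0.2 s earlier
bump_train <- function(peak_times_s, fs = 128, dur_s = NULL, amp = 4) {
  dur_s <- dur_s %||% (max(peak_times_s) + 1)
  t <- seq(0, dur_s, by = 1 / fs)
  x <- numeric(length(t))
  for (pt in peak_times_s) {
    x <- x + amp * exp(-((t - pt) / 0.07)^2) -
      1.5 * exp(-((t - (pt - 0.2)) / 0.055)^2)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
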