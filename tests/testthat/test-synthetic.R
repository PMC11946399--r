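test_that("profiles and trials are deterministic under a fixed seed", {
  spec <- cohort_spec(n_subjects = 2, seed = 13)
  p1 <- make_profile(spec, 1)
  p2 <- make_profile(spec, 1)
  expect_identical(p1, p2)
  t1 <- synthesize_trial(p1, "test")
  t2 <- synthesize_trial(p1, "test")
  expect_identical(t1, t2)
  # sessions and subjects differ
  expect_false(identical(synthesize_trial(p1, "retest"), t1))
  expect_false(identical(make_profile(spec, 2), p1))
})

test_that("harmonic amplitude construction hits symmetry targets exactly", {
  a100 <- harmonic_amplitudes(1, 1, "AP")
  expect_true(all(a100[c("1", "3", "5")] == 0))   # no extrinsic power
  a0 <- harmonic_amplitudes(1, 0, "AP")
  expect_true(all(a0[c("2", "4", "6")] == 0))
  a75 <- harmonic_amplitudes(1.4, 0.75, "AP")
  p <- a75^2 / 2
  k <- as.integer(names(a75))
  expect_equal(sum(p[k %% 2 == 0]) / sum(p), 0.75, tolerance = 1e-12)
  expect_equal(sqrt(sum(p)), 1.4, tolerance = 1e-12)  # Parseval RMS
})

test_that("the injected misalignment is recovered by gravity alignment", {
  spec <- noiseless_spec(seed = 2, rotation_deg = 20)
  prof <- make_profile(spec, 1)
  tr <- synthesize_trial(prof, "test")
  for (s in c("pelvis", "sternum", "head")) {
    R_est <- gravity_alignment(tr$sites[[s]]$acc, tr$static_window)
    expect_equal(R_est, prof$rotations[[s]], tolerance = 1e-6,
                 ignore_attr = TRUE)
    m <- colMeans(tr$sites[[s]]$acc[1:384, ])
    expect_equal(as.numeric(R_est %*% m)[3], 9.80665, tolerance = 1e-6)
  }
})

test_that("synthesized bouts contain the designed stride count", {
  spec <- noiseless_spec(seed = 6, n_strides = 8)
  tr <- synthesize_trial(make_profile(spec, 1), "test")
  res <- process_trial(tr)
  expect_equal(nrow(res$strides), 8)
  expect_equal(sum(res$strides$steady_state), 6)
})

test_that("cohort generation writes a complete, readable file set", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_subjects = 3, seed = 17)
  co <- generate_cohort(spec, out_dir = dir)
  expect_equal(length(co$trials), 6)
  expect_equal(nrow(co$manifest), 6)
  expect_equal(nrow(co$truth), 6)
  expect_true(all(file.exists(co$manifest$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 6)
})

test_that("session noise vanishes at true ICC 1, giving perfect reliability", {
  spec <- cohort_spec(n_subjects = 4, seed = 29, noise_sd_acc = 0,
                      noise_sd_gyro = 0, stride_jitter_cv = 0,
                      true_icc = list(nRMS = 1, iHR = 1, LDLJ_drive = 1))
  co <- generate_cohort(spec)
  run <- run_pipeline(co$trials)
  expect_true(all(run$reliability$icc > 0.999))
  expect_true(all(run$reliability$sem < 1e-3))
})

test_that("generated index targets honor the variance decomposition", {
  spec <- cohort_spec(n_subjects = 200, seed = 37)
  truths <- purrr::map(1:200, function(i) {
    prof <- make_profile(spec, i)
    c(theta = unname(prof$ihr_theta["ML"]),
      test = unname(.subset2(gaitrel:::.session_params(prof, "test"), "ihr")["ML"]),
      retest = unname(.subset2(gaitrel:::.session_params(prof, "retest"), "ihr")["ML"]))
  })
  tt <- do.call(rbind, truths)
  # subject-level variance ~ icc * sd^2; session noise ~ (1-icc) * sd^2
  sd_tot <- unname(spec$ihr_sd["ML"])
  expect_equal(var(tt[, "theta"]), 0.90 * sd_tot^2, tolerance = 0.25)
  within_var <- var(tt[, "test"] - tt[, "theta"])
  expect_equal(within_var, 0.10 * sd_tot^2, tolerance = 0.35)
  # test/retest correlate through the subject effect
  expect_gt(cor(tt[, "test"], tt[, "retest"]), 0.75)
})

test_that("pipeline estimates track analytic truths as noise vanishes", {
  spec <- noiseless_spec(seed = 41, n_strides = 8)
  prof <- make_profile(spec, 1)
  tr <- synthesize_trial(prof, "test")
  est <- process_trial(tr)$indices
  truth <- analytic_truth(prof, "test")
  for (ax in c("AP", "ML", "CC")) {
    expect_lt(abs(est[[paste0("iHR_", ax)]] - truth[[paste0("iHR_", ax)]]),
              1)                         # within 1 percentage point
  }
  for (cl in grep("^nRMS", gait_index_names(), value = TRUE)) {
    expect_equal(est[[cl]], truth[[cl]], tolerance = 0.02)  # 2% relative
  }
})
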