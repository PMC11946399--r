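test_that("normality gate behaves under null, alternative, and degenerate input", {
  set.seed(11)
  keep <- vapply(1:200, function(i) normality_test(rnorm(49))$p > 0.05,
                 logical(1))
  expect_gte(mean(keep), 0.88)            # ~95% expected under the null
  rej <- vapply(1:100, function(i) normality_test(rexp(49))$p <= 0.05,
                logical(1))
  expect_gte(mean(rej), 0.9)              # strongly skewed samples rejected
  out <- normality_test(rep(1.3, 10))
  expect_true(out$degenerate)
})

test_that("paired comparison gates on normality and matches a textbook computation", {
  # 5-pair toy table: frozen against an independent scipy computation
  a <- c(5.1, 6.3, 4.8, 7.2, 5.9)
  b <- c(5.52, 6.17, 5.41, 7.44, 6.28)
  pc <- paired_comparison(a, b)
  expect_equal(pc$test_used, "paired_t")
  expect_equal(pc$p, 0.0696592511, tolerance = 1e-8)
  expect_equal(pc$d, 1.1003375969, tolerance = 1e-8)
  expect_equal(pc$d_band, "large")

  pc0 <- paired_comparison(a, a)
  expect_equal(pc0$p, 1)
  expect_equal(pc0$d, 0)

  # constant shift with tiny noise is a large effect
  set.seed(2)
  x <- rnorm(30)
  shift <- paired_comparison(x, x + 0.7 + rnorm(30, 0, 0.05))
  expect_gt(abs(shift$d), 0.8)
  expect_lt(shift$p, 1e-6)
})

test_that("ICC matches a direct variance-components oracle", {
  test <- c(10.2, 12.5, 9.8, 14.1, 11.0, 13.3)
  ret <- c(10.6, 12.1, 10.4, 13.6, 11.5, 12.9)
  # oracle: mean squares straight from the two-way ANOVA decomposition
  long <- data.frame(y = c(test, ret),
                     subj = factor(rep(1:6, 2)),
                     sess = factor(rep(c("t", "r"), each = 6)))
  ms <- anova(stats::lm(y ~ subj + sess, data = long))
  msr <- ms["subj", "Mean Sq"]; msc <- ms["sess", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  n <- 6; k <- 2
  icc_consistency_oracle <- (msr - mse) / (msr + (k - 1) * mse)
  icc_agreement_oracle <- (msr - mse) /
    (msr + (k - 1) * mse + k * (msc - mse) / n)

  fit_c <- icc_3_1(test, ret, "consistency")
  fit_a <- icc_3_1(test, ret, "agreement")
  expect_equal(fit_c$estimate, icc_consistency_oracle, tolerance = 1e-10)
  expect_equal(fit_a$estimate, icc_agreement_oracle, tolerance = 1e-10)
  # frozen cross-check values from an independent implementation
  expect_equal(fit_a$estimate, 0.951505500869, tolerance = 1e-9)
  expect_equal(fit_c$estimate, 0.942635881256, tolerance = 1e-9)
  expect_equal(round(c(fit_a$lower, fit_a$upper), 2), c(0.69, 0.99))
  expect_equal(round(c(fit_c$lower, fit_c$upper), 2), c(0.65, 0.99))

  td <- tidy(fit_a)
  expect_equal(td$estimate, fit_a$estimate)
  expect_true(all(c("conf.low", "conf.high", "form") %in% names(td)))
  expect_equal(glance(fit_a)$n, 6)
})

test_that("ICC handles perfect agreement, independence, and degeneracy", {
  test <- c(1, 2, 3, 4, 5.5)
  fit <- icc_3_1(test, test)
  expect_equal(fit$estimate, 1)
  expect_equal(c(fit$lower, fit$upper), c(1, 1))
  expect_equal(sem(sd(test), fit$estimate), 0)
  expect_equal(mdc(sem(sd(test), fit$estimate)), 0)

  set.seed(8)
  nulls <- vapply(1:100, function(i)
    icc_3_1(rnorm(200), rnorm(200))$estimate, numeric(1))
  expect_lt(abs(mean(nulls)), 0.05)

  deg <- icc_3_1(rep(2, 5), rep(2, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$estimate))
})

test_that("ICC confidence intervals recover the truth across reliability levels", {
  set.seed(19)
  for (true_icc in c(0.6, 0.8, 0.95)) {
    cover <- vapply(1:200, function(i) {
      d <- simulate_index_pairs(49, 10, 3, true_icc)
      fit <- icc_3_1(d$test, d$retest)
      fit$lower <= true_icc && true_icc <= fit$upper
    }, logical(1))
    expect_gte(mean(cover), 0.9)
  }
})

test_that("adding retest noise does not raise the expected ICC", {
  set.seed(23)
  deltas <- vapply(1:200, function(i) {
    d <- simulate_index_pairs(49, 0, 1, 0.8)
    base <- icc_3_1(d$test, d$retest)$estimate
    noisy <- icc_3_1(d$test, d$retest + rnorm(49, 0, 0.5))$estimate
    noisy - base
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("SEM and MDC follow their formulas and conventions", {
  expect_equal(sem(10, 0.84), 4.0)
  expect_equal(sem(3, 1), 0)
  expect_equal(sem(3, 0), 3)
  expect_error(sem(3, 1.2), "exceed")
  expect_equal(mdc(0, "printed_2"), 0)
  expect_equal(round(mdc(1, "sqrt2"), 4), 2.7719)
  expect_equal(mdc(0.5, "printed_2"), 0.5 * 1.96 * 2)
})

test_that("subgroup comparison is an exact Mann-Whitney on small groups", {
  out <- subgroup_compare(c(1, 2, 3, 4, 5, 6), c("a", "a", "a", "b", "b", "b"))
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1)
  expect_error(subgroup_compare(1:5, rep("a", 5)), "two non-empty groups")

  set.seed(31)
  # type-I error near nominal
  rej <- vapply(1:200, function(i) {
    subgroup_compare(rnorm(60), rep(c("a", "b"), each = 30))$p <= 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)
  # power against a 1 SD location shift
  pow <- vapply(1:50, function(i) {
    subgroup_compare(c(rnorm(50), rnorm(50, 1)),
                     rep(c("a", "b"), each = 50))$p <= 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.8)
})

test_that("the reliability table is complete, keyed by subject, and chain-consistent", {
  set.seed(4)
  idx <- NULL
  for (ix in gait_index_names()) {
    d <- simulate_index_pairs(20, 5, 2, 0.85)
    block <- tibble::tibble(
      subject_id = rep(d$subject_id, 2),
      session = rep(c("test", "retest"), each = 20),
      value = c(d$test, d$retest), index = ix)
    idx <- dplyr::bind_rows(idx, block)
  }
  wide <- tidyr::pivot_wider(idx, names_from = "index", values_from = "value")
  rel <- reliability_table(wide)
  expect_equal(nrow(rel), 15)
  expect_false(any(is.na(rel$icc)))
  expect_false(any(is.na(rel$sem)))
  # MDC / SEM equals the configured multiplier exactly
  nz <- rel$sem > 0
  expect_equal(rel$mdc[nz] / rel$sem[nz], rep(1.96 * 2, sum(nz)))
  # CI ordering
  expect_true(all(rel$icc_lo <= rel$icc & rel$icc <= rel$icc_hi))
  expect_true(all(rel$sem_lo <= rel$sem & rel$sem <= rel$sem_hi))

  # permuting retest rows changes nothing (keyed by subject_id)
  perm <- wide[c(which(wide$session == "test"),
                 sample(which(wide$session == "retest"))), ]
  expect_equal(reliability_table(perm), rel, ignore_attr = TRUE)

  # retest identical to test: perfect agreement everywhere
  dup <- wide[wide$session == "test", ]
  dup2 <- dup; dup2$session <- "retest"
  rel2 <- reliability_table(dplyr::bind_rows(dup, dup2))
  expect_true(all(rel2$icc == 1))
  expect_true(all(rel2$sem == 0 & rel2$mdc == 0))

  # unmatched subjects are a hard error naming the offender
  bad <- wide[-1, ]
  expect_error(reliability_table(bad), "unmatched subjects")
})
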