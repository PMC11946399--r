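#' Shapiro-Wilk normality gate
#'
#' Tests the per-subject test-retest differences for normality; the result
#' decides between the paired t-test and the Wilcoxon signed-rank test.
#'
#' @param differences Numeric vector (n >= 3).
#' @param alpha Significance level. Default 0.05.
#' @return Tibble: `statistic`, `p`, `is_normal`, `degenerate`.
#' @export
normality_test <- function(differences, alpha = 0.05) {
  stopifnot(length(differences) >= 3)
  if (sd(differences) == 0) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                          is_normal = NA, degenerate = TRUE))
  }
  sw <- shapiro.test(differences)
  tibble::tibble(statistic = unname(sw$statistic), p = sw$p.value,
                 is_normal = sw$p.value > alpha, degenerate = FALSE)
}

#' Paired test-retest comparison with effect size
#'
#' Compares the two sessions with a paired t-test when the differences pass
#' the Shapiro-Wilk gate, and a Wilcoxon signed-rank test otherwise. Cohen's
#' effect size is `d = mean(diff) / sd(diff)` with a t-based confidence
#' interval; conventional magnitude bands are 0.2 small, 0.5 medium,
#' 0.8 large. Identical sessions are handled by convention as `p = 1, d = 0`.
#'
#' @param test,retest Paired numeric vectors.
#' @param alpha Significance level. Default 0.05.
#' @return One-row tibble: `test_used`, `p`, `d`, `d_lo`, `d_hi`, `d_band`,
#'   `shapiro_p`, `is_normal`.
#' @export
paired_comparison <- function(test, retest, alpha = 0.05) {
  stopifnot(length(test) == length(retest), length(test) >= 3)
  n <- length(test)
  dif <- retest - test
  nt <- normality_test(dif, alpha)
  if (isTRUE(nt$degenerate)) {
    return(tibble::tibble(test_used = "degenerate", p = 1, d = 0,
                          d_lo = 0, d_hi = 0, d_band = "negligible",
                          shapiro_p = NA_real_, is_normal = NA))
  }
  if (isTRUE(nt$is_normal)) {
    ht <- t.test(retest, test, paired = TRUE)
    used <- "paired_t"
  } else {
    ht <- suppressWarnings(wilcox.test(retest, test, paired = TRUE))
    used <- "wilcoxon"
  }
  d <- mean(dif) / sd(dif)
  se_d <- sqrt(1 / n + d^2 / (2 * (n - 1)))
  tcrit <- qt(1 - alpha / 2, n - 1)
  band <- cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
              labels = c("negligible", "small", "medium", "large"))
  tibble::tibble(test_used = used, p = ht$p.value, d = d,
                 d_lo = d - tcrit * se_d, d_hi = d + tcrit * se_d,
                 d_band = as.character(band),
                 shapiro_p = nt$p, is_normal = nt$is_normal)
}

.icc_bands <- function(icc) {
  as.character(cut(icc, c(-Inf, 0.5, 0.75, 0.9, Inf),
                   labels = c("poor", "moderate", "good", "excellent")))
}

#' Single-measure intraclass correlation from a two-way model
#'
#' Computes ICC from the two-way crossed layout (subjects x sessions) via its
#' mean squares: `"consistency"` gives the classical ICC(3,1)
#' `(MSR - MSE) / (MSR + (k-1) MSE)`, while `"agreement"` (the default) gives
#' the single-measure absolute-agreement coefficient
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, which also charges
#' systematic session shifts against reliability. 95% confidence intervals
#' follow the F-distribution constructions of the two-way model (with a
#' Satterthwaite-type df for the agreement form).
#'
#' @param test,retest Paired numeric vectors, one value per subject.
#' @param form `"agreement"` or `"consistency"`.
#' @param alpha Significance level for the CI. Default 0.05.
#' @return An object of class `gaitrel_icc` (list with `estimate`, `lower`,
#'   `upper`, `form`, mean squares, `n`, `k`, `band`, `degenerate`).
#' @export
icc_3_1 <- function(test, retest, form = c("agreement", "consistency"),
                    alpha = 0.05) {
  form <- match.arg(form)
  stopifnot(length(test) == length(retest), length(test) >= 3)
  n <- length(test); k <- 2L
  Y <- cbind(test, retest)
  row_m <- rowMeans(Y); col_m <- colMeans(Y); g <- mean(Y)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  sse <- sum((Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))

  out <- list(form = form, msr = msr, msc = msc, mse = mse, n = n, k = k,
              alpha = alpha, degenerate = FALSE)
  if (msr <= .Machine$double.eps * abs(g + 1)) {
    out$degenerate <- TRUE
    out$estimate <- NA_real_; out$lower <- NA_real_; out$upper <- NA_real_
    out$band <- NA_character_
    class(out) <- "gaitrel_icc"
    return(out)
  }
  if (mse == 0 && msc == 0) {
    # perfect agreement
    out$estimate <- 1; out$lower <- 1; out$upper <- 1
    out$band <- "excellent"
    class(out) <- "gaitrel_icc"
    return(out)
  }
  if (form == "consistency" && mse == 0) {
    # error-free measurements: consistency is exact
    est <- 1; lo <- 1; hi <- 1
  } else if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    Fo <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    FL <- Fo / qf(1 - alpha / 2, df1, df2)
    FU <- Fo * qf(1 - alpha / 2, df2, df1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * est / (n * (1 - est)); b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - FL * mse) / (FL * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (FU * msr - mse) / (k * msc + (k * n - k - n) * mse + n * FU * msr)
  }
  out$estimate <- est; out$lower <- lo; out$upper <- hi
  out$band <- .icc_bands(est)
  class(out) <- "gaitrel_icc"
  out
}

#' @export
print.gaitrel_icc <- function(x, ...) {
  cat(sprintf("ICC (%s, single measure): %.3f [%.3f, %.3f] (%s)\n",
              x$form, x$estimate, x$lower, x$upper,
              x$band %||% "degenerate"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ICC fit
#' @param x A `gaitrel_icc`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.gaitrel_icc <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$lower,
                 conf.high = x$upper, form = x$form, band = x$band,
                 degenerate = x$degenerate)
}

#' @rdname tidy.gaitrel_icc
#' @export
glance.gaitrel_icc <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, msr = x$msr, msc = x$msc, mse = x$mse,
                 alpha = x$alpha)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`: the within-subject measurement noise implied by
#' the reliability coefficient and the observed dispersion.
#'
#' @param sd_value Dispersion entering the formula (>= 0); by default the
#'   pipeline uses the pooled SD of test and retest values.
#' @param icc Reliability coefficient (<= 1).
#' @return Non-negative scalar.
#' @export
sem <- function(sd_value, icc) {
  if (any(icc > 1)) abort("icc must not exceed 1")
  stopifnot(all(sd_value >= 0))
  sd_value * sqrt(pmax(0, 1 - icc))
}

#' Minimal detectable change
#'
#' The smallest change exceeding measurement error at 95% confidence.
#' Two multiplier conventions are provided: `"printed_2"` computes
#' `SEM x 1.96 x 2` and `"sqrt2"` the conventional MDC95
#' `SEM x 1.96 x sqrt(2)`.
#'
#' @param sem_value Standard error of measurement (>= 0).
#' @param convention `"printed_2"` (default) or `"sqrt2"`.
#' @return Non-negative scalar.
#' @export
mdc <- function(sem_value, convention = c("printed_2", "sqrt2")) {
  convention <- match.arg(convention)
  stopifnot(all(sem_value >= 0))
  mult <- if (convention == "printed_2") 1.96 * 2 else 1.96 * sqrt(2)
  sem_value * mult
}

#' Subgroup comparison of test-retest reliability
#'
#' Mann-Whitney (two-sided Wilcoxon rank-sum) test comparing per-subject
#' absolute test-retest differences between two subgroups (e.g. younger vs
#' older than 40, male vs female).
#'
#' @param values Numeric vector, one per subject (absolute differences).
#' @param groups Vector with exactly two distinct non-empty groups.
#' @return One-row tibble: `group1`, `group2`, `n1`, `n2`, `U`, `p`.
#' @export
subgroup_compare <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    abort("subgroup comparison needs exactly two non-empty groups")
  }
  groups <- droplevels(groups)
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble::tibble(group1 = levels(groups)[1], group2 = levels(groups)[2],
                 n1 = length(x), n2 = length(y),
                 U = unname(ht$statistic), p = ht$p.value)
}

.ci_mean <- function(x, alpha) {
  n <- length(x)
  hw <- qt(1 - alpha / 2, n - 1) * sd(x) / sqrt(n)
  c(mean(x) - hw, mean(x) + hw)
}

#' Test-retest reliability table
#'
#' Builds, for every gait index present, the full reliability record from a
#' paired index table: session means with confidence intervals, mean absolute
#' test-retest difference, normality-gated paired comparison with Cohen's d,
#' ICC with its confidence interval, SEM and MDC. SEM/MDC intervals are
#' obtained by propagating the ICC interval endpoints through their formulas.
#' Subjects are matched by `subject_id`, so row order is irrelevant.
#'
#' @param index_tbl Tibble with columns `subject_id`, `session`
#'   (`test`/`retest`) and one column per index.
#' @param config A [gait_config()]; its `reliability` entry fixes the ICC
#'   form, the SD and MDC conventions and alpha.
#' @return A tibble of class `gaitrel_reliability`, one row per index.
#' @export
reliability_table <- function(index_tbl, config = gait_config()) {
  rel <- config$reliability
  stopifnot(all(c("subject_id", "session") %in% names(index_tbl)))
  idx_cols <- intersect(gait_index_names(), names(index_tbl))
  if (length(idx_cols) == 0) abort("no gait index columns found")
  wide_t <- index_tbl[index_tbl$session == "test", ]
  wide_r <- index_tbl[index_tbl$session == "retest", ]
  off <- c(setdiff(wide_t$subject_id, wide_r$subject_id),
           setdiff(wide_r$subject_id, wide_t$subject_id))
  if (length(off) > 0) {
    abort(paste0("unmatched subjects across sessions: ",
                 paste(unique(off), collapse = ", ")))
  }
  wide_r <- wide_r[match(wide_t$subject_id, wide_r$subject_id), ]
  alpha <- rel$alpha

  rows <- purrr::map(idx_cols, function(ix) {
    x <- wide_t[[ix]]; y <- wide_r[[ix]]
    dif <- y - x; adif <- abs(dif)
    ci_t <- .ci_mean(x, alpha); ci_r <- .ci_mean(y, alpha)
    ci_d <- .ci_mean(adif, alpha)
    pc <- paired_comparison(x, y, alpha)
    fit <- icc_3_1(x, y, rel$icc_form, alpha)
    sd_value <- switch(rel$sd_convention,
                       pooled = sqrt((var(x) + var(y)) / 2),
                       test = sd(x),
                       differences = sd(dif))
    sem_est <- sem(sd_value, fit$estimate)
    sem_ci <- sem(sd_value, c(fit$upper, fit$lower))
    mdc_est <- mdc(sem_est, rel$mdc_convention)
    mdc_ci <- mdc(sem_ci, rel$mdc_convention)
    tibble::tibble(
      index = ix, n = length(x),
      test_mean = mean(x), test_lo = ci_t[1], test_hi = ci_t[2],
      retest_mean = mean(y), retest_lo = ci_r[1], retest_hi = ci_r[2],
      abs_diff_mean = mean(adif), abs_diff_lo = ci_d[1], abs_diff_hi = ci_d[2],
      shapiro_p = pc$shapiro_p, is_normal = pc$is_normal,
      test_used = pc$test_used, p = pc$p,
      d = pc$d, d_lo = pc$d_lo, d_hi = pc$d_hi, d_band = pc$d_band,
      icc = fit$estimate, icc_lo = fit$lower, icc_hi = fit$upper,
      icc_band = fit$band, icc_form = rel$icc_form,
      sd_used = sd_value,
      sem = sem_est, sem_lo = sem_ci[1], sem_hi = sem_ci[2],
      mdc = mdc_est, mdc_lo = mdc_ci[1], mdc_hi = mdc_ci[2],
      mdc_convention = rel$mdc_convention
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gaitrel_reliability", class(out))
  out
}
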