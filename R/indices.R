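#' Per-stride root mean square
#'
#' @param values Numeric vector of per-sample signal values within one stride.
#' @return `sqrt(mean(values^2))`.
#' @export
stride_rms <- function(values) {
  if (length(values) == 0) abort("empty stride segment")
  sqrt(mean(values^2))
}

#' Normalized RMS (stability index)
#'
#' Ratio of the per-stride RMS of a horizontal acceleration component (AP or
#' ML) to the RMS of the craniocaudal component. Dividing by CC absorbs
#' inter-individual differences in overall acceleration magnitude caused by
#' walking-speed variation; higher values indicate larger horizontal
#' accelerations relative to the vertical, i.e. reduced stability.
#'
#' @param rms_x RMS of the AP or ML component.
#' @param rms_y RMS of the CC component (must be > 0).
#' @return `rms_x / rms_y`.
#' @export
nrms <- function(rms_x, rms_y) {
  if (any(rms_y <= 0)) abort("degenerate CC signal: zero RMS")
  rms_x / rms_y
}

# powers of stride-frequency harmonics 1..n_h of a single-stride segment.
# The segment spans exactly one stride period (first and last sample one
# period apart); it is demeaned and resampled to a fixed length by periodic
# cubic spline so harmonics fall exactly on DFT bins.
.harmonic_powers <- function(x, n_h, resample_len = 256L) {
  n <- length(x)
  if (n < 4) abort("stride segment too short")
  # x[1] and x[n] sit one period apart at the same stride phase; tie them to
  # their average so the periodic spline closes cleanly, then demean
  x[c(1, n)] <- mean(x[c(1, n)])
  x <- x - mean(x)
  tt <- seq(0, 1, length.out = n)
  ts <- seq(0, 1, length.out = resample_len + 1L)[seq_len(resample_len)]
  xr <- spline(tt, x, method = "periodic", xout = ts)$y
  z <- fft(xr) / resample_len
  n_avail <- resample_len %/% 2 - 1L
  if (n_h > n_avail) {
    warn(sprintf("only %d harmonics supported by segment; using those", n_avail))
    n_h <- n_avail
  }
  amp2 <- Mod(z[2:(n_h + 1L)])^2   # bin k+1 holds harmonic k
  amp2
}

#' Improved harmonic ratio (symmetry index)
#'
#' Decomposes one demeaned stride of a pelvis acceleration component into its
#' stride-frequency harmonics and returns the percentage of harmonic power in
#' the intrinsic (symmetry-consistent) set: a stride contains two steps, so a
#' perfectly symmetric AP or CC signal repeats every half stride and carries
#' its power at even stride harmonics, while ML (which alternates sign between
#' steps) carries it at odd harmonics. The first `K` intrinsic and `K`
#' extrinsic harmonics (i.e. harmonics 1 .. 2K) are used.
#'
#' 100 means perfect left-right symmetry of the signal; 0 complete asymmetry.
#'
#' @param x Numeric vector: one stride of one acceleration component, spanning
#'   exactly one stride period (endpoints one period apart).
#' @param axis `"AP"`, `"ML"` or `"CC"` — selects the intrinsic parity.
#' @param K Number of intrinsic harmonics (default 20).
#' @param parity Intrinsic parity per axis; default even for AP/CC, odd for ML.
#' @param resample_len Fixed per-stride length for the DFT (default 256).
#' @return Percentage in `[0, 100]`.
#' @export
ihr <- function(x, axis = c("AP", "ML", "CC"), K = 20L,
                parity = list(AP = "even", ML = "odd", CC = "even"),
                resample_len = 256L) {
  axis <- match.arg(axis)
  p <- match.arg(parity[[axis]], c("even", "odd"))
  pw <- .harmonic_powers(x, 2L * K, resample_len)
  k <- seq_along(pw)
  intrinsic <- if (p == "even") k %% 2 == 0 else k %% 2 == 1
  tot <- sum(pw)
  if (tot <= 0) abort("degenerate stride: no harmonic power")
  100 * sum(pw[intrinsic]) / tot
}

#' Log dimensionless jerk (smoothness index)
#'
#' For a per-axis signal segment s(t) on `[t1, t2]` computes
#' `-ln( (t2 - t1)^3 / max(s^2) * integral( (ds/dt)^2 ) )`,
#' a duration- and amplitude-normalized measure of the signal's derivative
#' energy. Applied to stride-sliced pelvis accelerations (LDLJa) and angular
#' velocities (LDLJw), one axis at a time. The derivative is taken by central
#' differences (one-sided at the segment ends) and the integral by the
#' trapezoidal rule; the result is invariant to uniform amplitude scaling.
#'
#' Note on direction: by this formula, larger derivative energy (a rougher
#' signal) gives a more negative value; reported clinical interpretations of
#' the sign direction differ, so the formula is applied literally and the
#' interpretation is left to the report.
#'
#' @param s Numeric vector: one axis of one stride segment.
#' @param fs Sampling rate, Hz (defines `t2 - t1 = (length(s) - 1) / fs`).
#' @return Scalar.
#' @export
ldlj <- function(s, fs) {
  n <- length(s)
  if (n < 3) abort("segment too short for a derivative")
  if (max(abs(s)) == 0) abort("degenerate segment: identically zero")
  dt <- 1 / fs
  dsdt <- numeric(n)
  dsdt[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  dsdt[1] <- (s[2] - s[1]) / dt
  dsdt[n] <- (s[n] - s[n - 1]) / dt
  integrand <- dsdt^2
  int <- sum((integrand[-1] + integrand[-n]) / 2) * dt
  duration <- (n - 1) * dt
  -log(duration^3 / max(s^2) * int)
}

#' Aggregate per-stride index values to one per-trial value
#'
#' @param per_stride Named list: index name -> numeric vector of per-stride
#'   values (one element per steady-state stride).
#' @param statistic `"mean"` (default) or `"median"`.
#' @param min_strides Minimum strides required (default 3).
#' @return One-row tibble with one column per index plus `n_strides_used`.
#' @export
aggregate_trial_indices <- function(per_stride, statistic = c("mean", "median"),
                                    min_strides = 3L) {
  statistic <- match.arg(statistic)
  n_used <- unique(lengths(per_stride))
  if (length(n_used) != 1) abort("inconsistent stride counts across indices")
  if (n_used < min_strides) {
    abort(sprintf("trial unusable: %d steady-state strides (need >= %d)",
                  n_used, min_strides))
  }
  f <- if (statistic == "mean") mean else median
  out <- tibble::as_tibble(lapply(per_stride, f))
  out$n_strides_used <- as.integer(n_used)
  out
}

#' Compute the 15 per-trial gait indices
#'
#' Runs stride slicing and the three index families on an aligned trial:
#' normalized RMS of AP and ML accelerations at pelvis, trunk (sternum) and
#' head; improved harmonic ratio of the AP/ML/CC pelvis accelerations; and log
#' dimensionless jerk of the pelvis accelerations (LDLJa) and angular
#' velocities (LDLJw) per axis. Indices are computed per steady-state stride
#' and aggregated (mean by default).
#'
#' @param aligned A `gait_trial_aligned`.
#' @param strides A stride table with steady-state flags (anchor leg).
#' @param config A [gait_config()].
#' @return One-row tibble: `subject_id`, `session`, the 15 indices,
#'   `n_strides_used`.
#' @export
compute_trial_indices <- function(aligned, strides, config = gait_config()) {
  stopifnot(inherits(aligned, "gait_trial_aligned"))
  n_steady <- sum(strides$steady_state)
  if (n_steady < config$segmentation$min_steady_strides) {
    abort(sprintf("trial unusable: %d steady-state strides (need >= %d)",
                  n_steady, config$segmentation$min_steady_strides))
  }
  fs <- aligned$fs
  ih <- config$ihr
  per_stride <- setNames(vector("list", 15L), gait_index_names())

  site_map <- c(pelvis = "pelvis", trunk = "sternum", head = "head")
  for (lvl in names(site_map)) {
    segs <- slice_strides(aligned, strides, site_map[[lvl]], "acc")
    rms_cc <- vapply(segs, function(m) stride_rms(m[, "CC"]), numeric(1))
    for (ax in c("AP", "ML")) {
      rms_x <- vapply(segs, function(m) stride_rms(m[, ax]), numeric(1))
      per_stride[[paste0("nRMS_", ax, "_", lvl)]] <- nrms(rms_x, rms_cc)
    }
  }

  acc_segs <- slice_strides(aligned, strides, "pelvis", "acc")
  gyr_segs <- slice_strides(aligned, strides, "pelvis", "gyro")
  for (ax in c("AP", "ML", "CC")) {
    per_stride[[paste0("iHR_", ax)]] <- vapply(acc_segs, function(m)
      ihr(m[, ax], ax, ih$n_harmonics, ih$parity, ih$resample_len), numeric(1))
    per_stride[[paste0("LDLJa_", ax)]] <- vapply(acc_segs, function(m)
      ldlj(m[, ax], fs), numeric(1))
    per_stride[[paste0("LDLJw_", ax)]] <- vapply(gyr_segs, function(m)
      ldlj(m[, ax], fs), numeric(1))
  }

  out <- aggregate_trial_indices(per_stride, config$aggregate,
                                 config$segmentation$min_steady_strides)
  tibble::add_column(out,
                     subject_id = aligned$subject_id,
                     session = aligned$session,
                     .before = 1)
}
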