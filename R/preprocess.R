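#' Gyroscope static bias
#'
#' Per-axis mean of the angular velocity over the quiet-standing window;
#' subtracting it from the full stream removes the gyroscope's constant offset.
#'
#' @param gyro T x 3 matrix, rad/s.
#' @param static_window Integer pair `c(first, last)`, inclusive sample
#'   indices; must span at least 1 s.
#' @param fs Sampling rate, Hz.
#' @return Numeric 3-vector, rad/s.
#' @export
estimate_static_bias <- function(gyro, static_window, fs) {
  stopifnot(is.matrix(gyro), ncol(gyro) == 3)
  i0 <- static_window[1]; i1 <- static_window[2]
  if (i0 < 1 || i1 > nrow(gyro) || i1 < i0) abort("static_window out of bounds")
  if ((i1 - i0 + 1) < fs) abort("static window shorter than 1 s")
  colMeans(gyro[i0:i1, , drop = FALSE])
}

.normalize <- function(v) v / sqrt(sum(v^2))

#' Gravity-based alignment rotation
#'
#' Estimates, from the quiet-standing acceleration, the rotation taking the
#' sensor frame to an anatomical frame whose third axis (craniocaudal, CC) is
#' the gravity direction. The anteroposterior (AP) axis is completed as the
#' horizontal projection of a per-site nominal forward axis, and ML = CC x AP,
#' giving a proper (det = +1) orthonormal rotation. Rows of the returned
#' matrix are the AP, ML, CC axes in sensor coordinates, so
#' `acc %*% t(R)` expresses signals in (AP, ML, CC).
#'
#' @param acc T x 3 acceleration, m/s^2, sensor frame.
#' @param static_window Inclusive index pair for the quiet-standing segment.
#' @param forward_hint Sensor-frame 3-vector whose horizontal projection
#'   defines AP. Default the sensor x-axis.
#' @return 3 x 3 rotation matrix.
#' @export
gravity_alignment <- function(acc, static_window, forward_hint = c(1, 0, 0)) {
  stopifnot(is.matrix(acc), ncol(acc) == 3)
  m <- colMeans(acc[static_window[1]:static_window[2], , drop = FALSE])
  mag <- sqrt(sum(m^2))
  if (mag < 0.8 * .G || mag > 1.2 * .G) {
    abort("sensor not quasi-static or miscalibrated: static acceleration magnitude outside [0.8 g, 1.2 g]")
  }
  cc <- .normalize(m)
  f <- .normalize(forward_hint)
  # if the hint is (near) parallel to gravity, fall back to the canonical axis
  # most orthogonal to it
  if (abs(sum(f * cc)) > 0.99) {
    f <- diag(3)[, which.min(abs(cc))]
  }
  ap <- .normalize(f - sum(f * cc) * cc)
  ml <- c(cc[2] * ap[3] - cc[3] * ap[2],
          cc[3] * ap[1] - cc[1] * ap[3],
          cc[1] * ap[2] - cc[2] * ap[1])
  R <- rbind(AP = ap, ML = ml, CC = cc)
  dimnames(R) <- list(c("AP", "ML", "CC"), NULL)
  R
}

#' Remove gravity from the craniocaudal axis
#'
#' Subtracts the quiet-standing mean of the CC column from the whole CC
#' stream; AP and ML are left untouched. Using the measured static mean rather
#' than the 9.81 constant keeps the removal robust to residual misalignment.
#'
#' @param acc_anat T x 3 acceleration in (AP, ML, CC), m/s^2.
#' @param static_window Inclusive index pair.
#' @return T x 3 matrix.
#' @export
remove_gravity_cc <- function(acc_anat, static_window) {
  stopifnot(is.matrix(acc_anat), ncol(acc_anat) == 3)
  g_cc <- mean(acc_anat[static_window[1]:static_window[2], 3])
  acc_anat[, 3] <- acc_anat[, 3] - g_cc
  acc_anat
}

# direct-form II transposed IIR filter with initial state zi * x0
.iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(n - 2)) {
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    }
    z[n - 1] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

# steady-state initial filter state for a unit step (scaled by x0 on use)
.iir_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  # solve for state z s.t. filtering a constant 1 is transient-free:
  # (I - A^T) z = b[-1] - a[-1] * b[1], A the companion matrix of a
  M <- diag(n - 1)
  M[, 1] <- M[, 1] + a[-1]
  for (j in seq_len(n - 2)) M[j, j + 1] <- M[j, j + 1] - 1
  rhs <- b[-1] - a[-1] * b[1]
  solve(M, rhs)
}

.filtfilt_one <- function(b, a, x) {
  nfilt <- max(length(b), length(a))
  pad <- 3 * (nfilt - 1) * 3  # generous odd-reflection padding
  pad <- min(pad, length(x) - 1)
  if (pad < 1) abort("signal too short to filter")
  xpre <- 2 * x[1] - x[seq(pad + 1, 2)]
  xpost <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
  xe <- c(xpre, x, xpost)
  zi <- .iir_zi(b, a)
  y <- .iir_filter(b, a, xe, zi * xe[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad + 1):(pad + length(x))]
}

#' Low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter column-wise. With
#' `zero_phase = TRUE` (the default) the filter runs forward and backward,
#' giving zero phase lag and a squared magnitude response (-6 dB at the
#' cutoff); edge transients are suppressed by odd-reflection padding with
#' steady-state initial conditions, so a constant passes through unchanged.
#'
#' @param x Numeric vector or T x k matrix.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @param fs_hz Sampling rate, Hz.
#' @param order Filter order (default 2).
#' @param zero_phase Forward-backward filtering? Default `TRUE`.
#' @return Same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz, fs_hz, order = 2, zero_phase = TRUE) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    abort("cutoff must lie in (0, Nyquist)")
  }
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  f1 <- function(v) {
    if (zero_phase) .filtfilt_one(bf$b, bf$a, v)
    else .iir_filter(bf$b, bf$a, v, .iir_zi(bf$b, bf$a) * v[1])
  }
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Preprocess a trial to the anatomical frame
#'
#' Runs the per-sensor calibration chain on every site of a trial, in fixed
#' order: gyroscope static-bias removal, gravity alignment (rotation applied
#' to both acceleration and angular velocity), gravity removal from the CC
#' acceleration, and low-pass Butterworth filtering (10 Hz accelerations,
#' 6 Hz angular velocities by default). Static calibration statistics are
#' always taken from the raw, unfiltered signals.
#'
#' @param trial A [gait_trial()].
#' @param config A [gait_config()].
#' @return An object of class `gait_trial_aligned`: like the input but each
#'   site holds `acc_anat`, `gyro_anat` (columns AP, ML, CC) and `rotation`.
#' @export
preprocess_trial <- function(trial, config = gait_config()) {
  stopifnot(inherits(trial, "gait_trial"))
  fs <- trial$fs
  sw <- trial$static_window
  filt <- config$filter
  sites <- lapply(names(trial$sites), function(sname) {
    s <- trial$sites[[sname]]
    bias <- estimate_static_bias(s$gyro, sw, fs)
    gyro <- sweep(s$gyro, 2, bias)
    hint <- config$forward_axis[[sname]] %||% c(1, 0, 0)
    R <- gravity_alignment(s$acc, sw, hint)
    acc_anat <- s$acc %*% t(R)
    gyro_anat <- gyro %*% t(R)
    acc_anat <- remove_gravity_cc(acc_anat, sw)
    acc_anat <- lowpass_filter(acc_anat, filt$acc_cutoff_hz, fs,
                               filt$order, filt$zero_phase)
    gyro_anat <- lowpass_filter(gyro_anat, filt$gyro_cutoff_hz, fs,
                                filt$order, filt$zero_phase)
    colnames(acc_anat) <- colnames(gyro_anat) <- c("AP", "ML", "CC")
    list(acc_anat = acc_anat, gyro_anat = gyro_anat,
         rotation = R, gyro_bias = bias)
  })
  names(sites) <- names(trial$sites)
  structure(list(subject_id = trial$subject_id, session = trial$session,
                 fs = fs, sites = sites, static_window = sw,
                 filter_meta = filt),
            class = "gait_trial_aligned")
}
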