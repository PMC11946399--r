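#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters for preprocessing, stride
#' segmentation, index computation and the reliability analysis. Every
#' convention choice the pipeline makes is explicit here so that any output is
#' reproducible from (inputs, config).
#'
#' @param acc_cutoff_hz Low-pass cutoff for accelerations, Hz. Default 10.
#' @param gyro_cutoff_hz Low-pass cutoff for angular velocities, Hz. Default 6.
#' @param filter_order Butterworth order (applied zero-phase, so the effective
#'   magnitude response is squared). Default 2.
#' @param zero_phase Apply the filter forward-backward (zero phase lag)?
#'   Default `TRUE`; per-stride indices are phase-sensitive, so zero-phase
#'   filtering is the norm in gait work. `FALSE` gives a single causal pass.
#' @param static_window_s Two numbers, seconds: the quiet-standing calibration
#'   window at the start of each trial. Default `c(0, 3)`.
#' @param forward_axis Named list mapping sensor site to the sensor-frame axis
#'   (unit 3-vector) whose horizontal projection defines the anteroposterior
#'   direction after gravity alignment.
#' @param prominence_rad_s Minimum prominence of a mid-swing shank angular
#'   velocity peak, rad/s. Default 1.
#' @param min_separation_s Minimum separation between mid-swing peaks, s.
#'   Default 0.6.
#' @param stride_band_s Plausibility band for stride durations, s.
#'   Default `c(0.6, 2.5)`.
#' @param anchor_leg Which leg's stride grid windows the pelvis/trunk/head
#'   signals: `"left"` (default) or `"right"`.
#' @param drop_edge_strides Number of strides dropped at each end of the bout
#'   as gait initiation/termination. Default 1.
#' @param min_steady_strides Minimum steady-state strides for a usable trial.
#'   Default 3.
#' @param n_harmonics Number of intrinsic (and extrinsic) stride-frequency
#'   harmonics entering the improved harmonic ratio; the first
#'   `2 * n_harmonics` harmonics are used in total. Default 20.
#' @param parity Named list giving the intrinsic-harmonic parity per axis.
#'   A stride contains two steps, so signals symmetric between steps (AP, CC)
#'   concentrate power at even stride harmonics; mediolateral signals at odd.
#' @param resample_len Samples per stride after periodic resampling, so that
#'   stride-frequency harmonics fall exactly on DFT bins. Default 256.
#' @param aggregate Per-trial aggregation across steady-state strides:
#'   `"mean"` (default) or `"median"`.
#' @param icc_form `"agreement"` (two-way model, absolute agreement, the
#'   default) or `"consistency"` (classical ICC(3,1)).
#' @param mdc_convention `"printed_2"` (MDC = SEM x 1.96 x 2, default) or
#'   `"sqrt2"` (the conventional MDC95 = SEM x 1.96 x sqrt(2)).
#' @param sd_convention Which dispersion enters SEM = SD * sqrt(1 - ICC):
#'   `"pooled"` (default; pooled SD of test and retest), `"test"`, or
#'   `"differences"`.
#' @param alpha Significance level for all tests and intervals. Default 0.05.
#'
#' @return A nested list of class `gait_config`.
#' @export
gait_config <- function(acc_cutoff_hz = 10,
                        gyro_cutoff_hz = 6,
                        filter_order = 2,
                        zero_phase = TRUE,
                        static_window_s = c(0, 3),
                        forward_axis = NULL,
                        prominence_rad_s = 1.0,
                        min_separation_s = 0.6,
                        stride_band_s = c(0.6, 2.5),
                        anchor_leg = c("left", "right"),
                        drop_edge_strides = 1L,
                        min_steady_strides = 3L,
                        n_harmonics = 20L,
                        parity = list(AP = "even", ML = "odd", CC = "even"),
                        resample_len = 256L,
                        aggregate = c("mean", "median"),
                        icc_form = c("agreement", "consistency"),
                        mdc_convention = c("printed_2", "sqrt2"),
                        sd_convention = c("pooled", "test", "differences"),
                        alpha = 0.05) {
  anchor_leg <- match.arg(anchor_leg)
  aggregate <- match.arg(aggregate)
  icc_form <- match.arg(icc_form)
  mdc_convention <- match.arg(mdc_convention)
  sd_convention <- match.arg(sd_convention)
  if (is.null(forward_axis)) {
    forward_axis <- setNames(
      rep(list(c(1, 0, 0)), length(gait_sensor_sites())),
      gait_sensor_sites()
    )
  }
  stopifnot(acc_cutoff_hz > 0, gyro_cutoff_hz > 0, filter_order >= 1,
            length(static_window_s) == 2, diff(static_window_s) > 0,
            alpha > 0, alpha < 1)
  structure(list(
    filter = list(acc_cutoff_hz = acc_cutoff_hz,
                  gyro_cutoff_hz = gyro_cutoff_hz,
                  order = as.integer(filter_order),
                  zero_phase = isTRUE(zero_phase)),
    static_window_s = as.numeric(static_window_s),
    forward_axis = forward_axis,
    segmentation = list(prominence_rad_s = prominence_rad_s,
                        min_separation_s = min_separation_s,
                        stride_band_s = as.numeric(stride_band_s),
                        anchor_leg = anchor_leg,
                        drop_edge_strides = as.integer(drop_edge_strides),
                        min_steady_strides = as.integer(min_steady_strides)),
    ihr = list(n_harmonics = as.integer(n_harmonics),
               parity = parity,
               resample_len = as.integer(resample_len)),
    aggregate = aggregate,
    reliability = list(icc_form = icc_form,
                       mdc_convention = mdc_convention,
                       sd_convention = sd_convention,
                       alpha = alpha)
  ), class = "gait_config")
}
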