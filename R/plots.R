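#' Distribution of test-retest differences per index
#'
#' Density of the per-subject test-retest differences with the individual
#' subjects overplotted, one panel per index — the standard visual check that
#' differences are centred on zero and free of outlying subjects.
#'
#' @param index_tbl Paired index table (`subject_id`, `session`, indices).
#' @return A ggplot object.
#' @export
plot_test_retest_differences <- function(index_tbl) {
  idx_cols <- intersect(gait_index_names(), names(index_tbl))
  long <- tidyr::pivot_longer(index_tbl, dplyr::all_of(idx_cols),
                              names_to = "index", values_to = "value")
  wide <- tidyr::pivot_wider(long, id_cols = c("subject_id", "index"),
                             names_from = "session", values_from = "value")
  wide$diff <- wide$retest - wide$test
  wide$index <- factor(wide$index, levels = gait_index_names())
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4, colour = NA) +
    ggplot2::geom_point(ggplot2::aes(y = 0), shape = 1, alpha = 0.6,
                        position = ggplot2::position_jitter(height = 0)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = "retest - test", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a reliability table
#'
#' ICC point estimates with their confidence intervals per index, coloured by
#' the conventional reliability band.
#'
#' @param object A `gaitrel_reliability` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaitrel_reliability <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$index <- factor(df$index, levels = rev(gait_index_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$index,
                                   colour = .data$icc_band)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$icc_lo,
                                         xmax = .data$icc_hi), height = 0.25) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9), linetype = 3,
                        colour = "grey60") +
    ggplot2::labs(x = "ICC (95% CI)", y = NULL, colour = "reliability") +
    ggplot2::theme_minimal()
}

#' Stride segmentation QC plot
#'
#' Shank angular velocity with the detected mid-swing peaks and stride
#' boundaries overlaid.
#'
#' @param aligned A `gait_trial_aligned`.
#' @param strides A stride table.
#' @param site Shank site name. Default `"shank_left"`.
#' @return A ggplot object.
#' @export
plot_strides <- function(aligned, strides, site = "shank_left") {
  x <- aligned$sites[[site]]$gyro_anat[, "ML"]
  df <- tibble::tibble(t = (seq_along(x) - 1) / aligned$fs, gyro_ml = x)
  bt <- tibble::tibble(t = (c(strides$start, strides$end[nrow(strides)]) - 1) /
                         aligned$fs)
  pk <- tibble::tibble(t = (strides$peak - 1) / aligned$fs,
                       y = x[strides$peak])
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$gyro_ml)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(data = bt, ggplot2::aes(xintercept = .data$t),
                        colour = "steelblue", linetype = 2) +
    ggplot2::geom_point(data = pk, ggplot2::aes(.data$t, .data$y),
                        colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "shank ML angular velocity (rad/s)") +
    ggplot2::theme_minimal()
}
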