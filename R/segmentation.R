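# peak prominence: height above the higher of the two valley floors reached
# before meeting a taller sample on each side
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    left_min <- h
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      left_min <- min(left_min, x[i])
    }
    i <- p
    right_min <- h
    while (i < length(x)) {
      i <- i + 1
      if (x[i] > h) break
      right_min <- min(right_min, x[i])
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect strides from shank angular velocity
#'
#' Mid-swing shows as a prominent positive peak in the sagittal-plane (ML
#' axis) shank angular velocity. Peaks with prominence of at least
#' `prominence_rad_s` are found; peaks closer than `min_separation_s` are
#' merged keeping the more prominent one. Each stride boundary is placed at
#' the signal minimum preceding its mid-swing peak (a terminal-contact proxy),
#' and consecutive boundaries delimit strides, so `P` accepted peaks yield
#' `P - 1` strides. Strides whose duration falls outside `stride_band_s` are
#' discarded as implausible.
#'
#' @param gyro_ml Numeric vector, rad/s: the ML component of one shank's
#'   angular velocity, already low-pass filtered.
#' @param fs_hz Sampling rate, Hz.
#' @param prominence_rad_s Minimum peak prominence, rad/s. Default 1.
#' @param min_separation_s Minimum peak separation, s. Default 0.6.
#' @param stride_band_s Plausible stride duration band, s. Default
#'   `c(0.6, 2.5)`.
#' @return A tibble of class `stride_table` with columns `start`, `end`
#'   (sample indices, stride = `start:(end-1)`), `peak`, `duration_s`,
#'   `steady_state` (all `TRUE` until [select_steady_state()]). Zero rows,
#'   with a warning, if no peaks are found.
#' @export
detect_strides <- function(gyro_ml, fs_hz, prominence_rad_s = 1.0,
                           min_separation_s = 0.6,
                           stride_band_s = c(0.6, 2.5)) {
  stopifnot(is.numeric(gyro_ml), length(gyro_ml) >= 3 * fs_hz)
  x <- as.numeric(gyro_ml)
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) > 0) {
    prom <- .peak_prominence(x, cand)
    cand <- cand[prom >= prominence_rad_s]
    prom <- prom[prom >= prominence_rad_s]
  }
  if (length(cand) == 0) {
    warn("no mid-swing peaks found; returning empty stride table")
    return(.empty_stride_table())
  }
  # enforce minimum separation, keeping the more prominent peak
  min_sep <- round(min_separation_s * fs_hz)
  keep <- order(prom, decreasing = TRUE)
  accepted <- integer(0)
  for (i in keep) {
    if (all(abs(cand[i] - accepted) >= min_sep)) accepted <- c(accepted, cand[i])
  }
  peaks <- sort(accepted)
  if (length(peaks) < 2) {
    warn("fewer than two mid-swing peaks; no complete stride")
    return(.empty_stride_table())
  }
  # boundary = minimum between consecutive peaks (precedes the later peak)
  bounds <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1) max(1L, peaks[1] - round(1.5 * min_sep)) else peaks[i - 1]
    seg <- x[lo:peaks[i]]
    bounds[i] <- lo + which.min(seg) - 1L
  }
  tb <- tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    peak = peaks[-length(peaks)],
    duration_s = (bounds[-1] - bounds[-length(bounds)]) / fs_hz
  )
  tb <- tb[tb$duration_s >= stride_band_s[1] & tb$duration_s <= stride_band_s[2], ]
  tb$steady_state <- rep(TRUE, nrow(tb))
  class(tb) <- c("stride_table", class(tb))
  attr(tb, "fs") <- fs_hz
  tb
}

.empty_stride_table <- function() {
  tb <- tibble::tibble(start = integer(0), end = integer(0), peak = integer(0),
                       duration_s = numeric(0), steady_state = logical(0))
  class(tb) <- c("stride_table", class(tb))
  tb
}

#' Flag steady-state strides
#'
#' Drops `drop_edge` strides at each end of the bout as gait
#' initiation/termination — the walkway's auxiliary acceleration and
#' deceleration sections (about one stride each at this cohort's typical
#' speed). A trial needs at least `min_steady` steady-state strides to be
#' usable.
#'
#' @param strides A stride table from [detect_strides()].
#' @param drop_edge Strides dropped at each end. Default 1.
#' @param min_steady Minimum usable steady-state strides. Default 3.
#' @return The stride table with updated `steady_state` flags and attribute
#'   `usable` (`TRUE`/`FALSE`).
#' @export
select_steady_state <- function(strides, drop_edge = 1L, min_steady = 3L) {
  n <- nrow(strides)
  flag <- rep(FALSE, n)
  if (n > 2 * drop_edge) {
    flag[(drop_edge + 1):(n - drop_edge)] <- TRUE
  }
  strides$steady_state <- flag
  attr(strides, "usable") <- sum(flag) >= min_steady
  strides
}

#' Extract per-stride signal segments
#'
#' Slices one sensor site's anatomical-frame signals into per-stride segments
#' for the steady-state strides. Each segment spans samples
#' `start:end` inclusive, i.e. it covers exactly one stride period including
#' both boundary samples, which is what the per-stride index integrals need.
#'
#' @param aligned A `gait_trial_aligned` from [preprocess_trial()].
#' @param strides A stride table with steady-state flags.
#' @param site Sensor site name.
#' @param what `"acc"` or `"gyro"`.
#' @return List of T_i x 3 matrices (columns AP, ML, CC).
#' @export
slice_strides <- function(aligned, strides, site = "pelvis",
                          what = c("acc", "gyro")) {
  what <- match.arg(what)
  stopifnot(inherits(aligned, "gait_trial_aligned"), site %in% names(aligned$sites))
  sig <- if (what == "acc") aligned$sites[[site]]$acc_anat
         else aligned$sites[[site]]$gyro_anat
  ss <- strides[strides$steady_state, , drop = FALSE]
  if (nrow(ss) == 0) return(list())
  if (any(ss$start < 1) || any(ss$end > nrow(sig))) {
    abort("stride indices out of signal bounds")
  }
  lapply(seq_len(nrow(ss)), function(i) {
    sig[ss$start[i]:ss$end[i], , drop = FALSE]
  })
}
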