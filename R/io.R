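#' Construct a raw IMU gait trial
#'
#' Bundles the synchronized recordings of one walking trial. Each sensor site
#' carries a T x 3 acceleration matrix (m/s^2) and a T x 3 angular velocity
#' matrix (rad/s) in the sensor frame, sampled at `fs` Hz, with an initial
#' quiet-standing window used for calibration.
#'
#' @param subject_id Character scalar.
#' @param session `"test"` or `"retest"`.
#' @param fs Sampling rate, Hz (nominal 128).
#' @param sites Named list (names among [gait_sensor_sites()]); each element a
#'   list with `acc` and `gyro` T x 3 numeric matrices.
#' @param static_window Integer pair `c(first, last)`, 1-based inclusive sample
#'   indices of the quiet-standing segment.
#' @param walkway_total_m,walkway_core_m Walkway geometry, metres: the core
#'   measured distance plus auxiliary acceleration/deceleration sections.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, session, fs, sites, static_window,
                       walkway_total_m = 14, walkway_core_m = 10) {
  session <- match.arg(session, c("test", "retest"))
  stopifnot(is.list(sites), length(sites) > 0, fs > 0)
  bad <- setdiff(names(sites), gait_sensor_sites())
  if (length(bad) > 0) {
    abort(paste0("unknown sensor site(s): ", paste(bad, collapse = ", ")))
  }
  need <- c("pelvis", "sternum", "head")
  missing_sites <- setdiff(need, names(sites))
  if (length(missing_sites) > 0) {
    abort(paste0("required sensor site absent: ",
                 paste(missing_sites, collapse = ", ")))
  }
  if (!any(c("shank_left", "shank_right") %in% names(sites))) {
    abort("required sensor site absent: shank_left or shank_right")
  }
  T_len <- nrow(sites[[1]]$acc)
  for (s in names(sites)) {
    acc <- sites[[s]]$acc; gyro <- sites[[s]]$gyro
    stopifnot(is.matrix(acc), is.matrix(gyro), ncol(acc) == 3, ncol(gyro) == 3)
    if (nrow(acc) != T_len || nrow(gyro) != T_len) {
      abort("recordings are not synchronized: unequal lengths across sites")
    }
    if (!all(is.finite(acc)) || !all(is.finite(gyro))) {
      abort(paste0("non-finite samples at site ", s))
    }
    if (max(abs(acc)) > 16 * .G + 1e-9) {
      abort(paste0("acceleration exceeds +/-16 g sensor range at site ", s))
    }
    if (max(abs(gyro)) > 2000 * pi / 180 + 1e-9) {
      abort(paste0("angular velocity exceeds +/-2000 deg/s range at site ", s))
    }
  }
  static_window <- as.integer(static_window)
  stopifnot(length(static_window) == 2)
  if (static_window[1] < 1 || static_window[2] > T_len ||
      static_window[2] <= static_window[1]) {
    abort("static_window out of bounds")
  }
  if ((static_window[2] - static_window[1] + 1) < 3 * fs) {
    abort("static_window must span at least 3 s")
  }
  structure(list(subject_id = as.character(subject_id), session = session,
                 fs = fs, sites = sites, static_window = static_window,
                 walkway_total_m = walkway_total_m,
                 walkway_core_m = walkway_core_m),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial> subject", x$subject_id, "session", x$session, "\n")
  cat("  sites:", paste(names(x$sites), collapse = ", "), "\n")
  cat("  samples:", nrow(x$sites[[1]]$acc), "at", x$fs, "Hz;",
      "static window", x$static_window[1], "-", x$static_window[2], "\n")
  invisible(x)
}

.parse_units_line <- function(line) {
  # expects e.g. "# units: acc=m/s^2 gyro=deg/s"
  acc <- regmatches(line, regexpr("acc=[^ ,]+", line))
  gyro <- regmatches(line, regexpr("gyro=[^ ,]+", line))
  list(
    acc = if (length(acc)) sub("acc=", "", acc) else NA_character_,
    gyro = if (length(gyro)) sub("gyro=", "", gyro) else NA_character_
  )
}

.acc_factor <- function(u) {
  switch(u, "g" = .G, "m/s^2" = 1, "m/s2" = 1,
         abort(paste0("unknown acceleration unit: ", u)))
}
.gyro_factor <- function(u) {
  switch(u, "deg/s" = pi / 180, "dps" = pi / 180, "rad/s" = 1,
         abort(paste0("unknown angular velocity unit: ", u)))
}

#' Read one trial from CSV
#'
#' The trial format is one row per sample with a `time_s` column plus six
#' channels per sensor site (`<site>_acc_x/y/z`, `<site>_gyro_x/y/z`). Units
#' must be declared, either in a leading comment line
#' (`# units: acc=m/s^2 gyro=rad/s`; accepted values `g`, `m/s^2`, `deg/s`,
#' `rad/s`) or through the `units` argument — there is no silent guessing.
#' Signals are converted to SI (m/s^2, rad/s) on ingest. An optional 0/1
#' `static` column marks the quiet-standing samples; otherwise
#' `static_window_s` is used.
#'
#' @param path CSV file path.
#' @param subject_id,session Trial identity; defaults parsed from columns
#'   `subject_id`/`session` if present.
#' @param units Optional list `list(acc = , gyro = )` overriding the header
#'   declaration.
#' @param static_window_s Fallback static window, seconds.
#' @return A [gait_trial()].
#' @export
read_trial_csv <- function(path, subject_id = NULL, session = NULL,
                           units = NULL, static_window_s = c(0, 3)) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  hdr_units <- if (startsWith(first, "#")) .parse_units_line(first) else
    list(acc = NA_character_, gyro = NA_character_)
  if (is.null(units)) units <- list()
  acc_unit <- units$acc %||% hdr_units$acc
  gyro_unit <- units$gyro %||% hdr_units$gyro
  if (is.na(acc_unit %||% NA) || is.na(gyro_unit %||% NA)) {
    abort("units not declared: supply a '# units: acc=... gyro=...' header line or the `units` argument")
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"time_s" %in% names(df)) abort("missing required column: time_s")
  tt <- df$time_s
  if (any(diff(tt) <= 0)) abort("non-monotonic time column")
  fs <- 1 / median(diff(tt))

  present <- gait_sensor_sites()[vapply(gait_sensor_sites(), function(s)
    all(paste0(s, "_acc_", c("x", "y", "z")) %in% names(df)), logical(1))]
  fa <- .acc_factor(acc_unit); fg <- .gyro_factor(gyro_unit)
  sites <- lapply(present, function(s) {
    acc_cols <- paste0(s, "_acc_", c("x", "y", "z"))
    gyr_cols <- paste0(s, "_gyro_", c("x", "y", "z"))
    if (!all(gyr_cols %in% names(df))) {
      abort(paste0("incomplete channels for site ", s, ": missing gyro"))
    }
    list(acc = as.matrix(df[acc_cols]) * fa,
         gyro = as.matrix(df[gyr_cols]) * fg)
  })
  names(sites) <- present
  for (need in c("pelvis", "sternum", "head")) {
    if (!need %in% present) abort(paste0("required sensor site absent: ", need))
  }

  if ("static" %in% names(df)) {
    idx <- which(df$static > 0)
    if (length(idx) == 0) abort("static marker column contains no static samples")
    static_window <- c(min(idx), max(idx))
  } else {
    static_window <- c(floor(static_window_s[1] * fs) + 1,
                       floor(static_window_s[2] * fs))
  }
  subject_id <- subject_id %||%
    (if ("subject_id" %in% names(df)) as.character(df$subject_id[1]) else "unknown")
  session <- session %||%
    (if ("session" %in% names(df)) as.character(df$session[1]) else "test")
  gait_trial(subject_id, session, fs, sites, static_window)
}

#' Write a trial to CSV
#'
#' Inverse of [read_trial_csv()]; always writes SI units with the declaring
#' comment line and a `static` marker column.
#'
#' @param trial A [gait_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  T_len <- nrow(trial$sites[[1]]$acc)
  df <- tibble::tibble(time_s = (seq_len(T_len) - 1) / trial$fs)
  for (s in names(trial$sites)) {
    acc <- trial$sites[[s]]$acc; gyr <- trial$sites[[s]]$gyro
    for (j in 1:3) {
      df[[paste0(s, "_acc_", c("x", "y", "z")[j])]] <- acc[, j]
      df[[paste0(s, "_gyro_", c("x", "y", "z")[j])]] <- gyr[, j]
    }
  }
  df$static <- as.integer(seq_len(T_len) >= trial$static_window[1] &
                            seq_len(T_len) <= trial$static_window[2])
  df$subject_id <- trial$subject_id
  df$session <- trial$session
  con <- file(path, "w")
  writeLines("# units: acc=m/s^2 gyro=rad/s", con)
  close(con)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write / read a per-trial index table
#'
#' One row per (subject, session) with the 15 index columns in the canonical
#' [gait_index_names()] order, round-trippable at full double precision.
#'
#' @param tbl Tibble with columns `subject_id`, `session`, the indices, and
#'   optionally `n_strides_used`.
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_index_table <- function(tbl, path) {
  stopifnot(is.data.frame(tbl))
  if (nrow(tbl) == 0) abort("empty index table")
  keys <- paste(tbl$subject_id, tbl$session)
  if (anyDuplicated(keys)) {
    abort(paste0("duplicate (subject, session) rows: ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  cols <- c("subject_id", "session",
            intersect(gait_index_names(), names(tbl)),
            intersect("n_strides_used", names(tbl)))
  readr::write_csv(tbl[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(subject_id = readr::col_character(),
                                          session = readr::col_character()))
}

#' Read a cohort manifest
#'
#' The manifest lists one row per recorded trial: `subject_id`, `session`
#' (`test`/`retest`), `path` to the trial CSV, and optional clinical metadata
#' (age, sex, months_since_trauma, leg_length_cm, bmi, walking_speed_mps, bbs,
#' dgi).
#'
#' @param path Manifest CSV path.
#' @param require_pairs Require exactly one test and one retest per subject
#'   (the paired design)? Default `TRUE`.
#' @return A tibble.
#' @export
read_manifest <- function(path, require_pairs = TRUE) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "session", "path")
  if (!all(need %in% names(m))) {
    abort(paste0("manifest missing column(s): ",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  }
  m$subject_id <- as.character(m$subject_id)
  if (require_pairs) {
    counts <- table(m$subject_id, m$session)
    ok <- all(dim(counts) == c(length(unique(m$subject_id)), 2)) &&
      all(counts == 1)
    if (!ok) abort("each subject must have exactly one test and one retest trial")
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
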