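#' Process one trial end to end
#'
#' Preprocesses the raw trial, segments strides from the anchor-leg shank
#' angular velocity, and computes the 15 per-trial indices. A trial with
#' fewer steady-state strides than the configured minimum is reported as
#' unusable rather than raising.
#'
#' @param trial A [gait_trial()].
#' @param config A [gait_config()].
#' @return List: `indices` (one-row tibble or `NULL`), `strides` (stride
#'   table), `qc` (one-row tibble: subject, session, strides detected/used,
#'   usable flag, note).
#' @export
process_trial <- function(trial, config = gait_config()) {
  seg <- config$segmentation
  aligned <- preprocess_trial(trial, config)
  anchor <- paste0("shank_", seg$anchor_leg)
  if (!anchor %in% names(aligned$sites)) {
    other <- setdiff(c("shank_left", "shank_right"), anchor)
    other <- intersect(other, names(aligned$sites))
    if (length(other) == 0) abort("no shank recording available")
    warn(sprintf("anchor leg %s absent; using %s", anchor, other[1]))
    anchor <- other[1]
  }
  strides <- detect_strides(aligned$sites[[anchor]]$gyro_anat[, "ML"],
                            aligned$fs, seg$prominence_rad_s,
                            seg$min_separation_s, seg$stride_band_s)
  strides <- select_steady_state(strides, seg$drop_edge_strides,
                                 seg$min_steady_strides)
  usable <- isTRUE(attr(strides, "usable"))
  qc <- tibble::tibble(
    subject_id = trial$subject_id, session = trial$session,
    n_strides_detected = nrow(strides),
    n_strides_steady = sum(strides$steady_state),
    usable = usable,
    note = if (usable) "" else "fewer steady-state strides than minimum"
  )
  indices <- NULL
  if (usable) {
    indices <- compute_trial_indices(aligned, strides, config)
  }
  list(indices = indices, strides = strides, qc = qc)
}

#' Run the full cohort pipeline
#'
#' Orchestrates preprocessing, stride segmentation, index computation and the
#' reliability analysis over a whole test-retest cohort. Input is either a
#' manifest tibble (columns `subject_id`, `session`, `path` to trial CSVs) or
#' a list of in-memory [gait_trial()] objects. Subjects with an unusable
#' trial are excluded pairwise (both sessions), matching the paired design.
#'
#' @param manifest Manifest tibble or list of `gait_trial`s.
#' @param config A [gait_config()].
#' @param out_dir Optional: write `index_table.csv`, `reliability.csv`,
#'   `qc.csv` and `run_metadata.json` there.
#' @return List of class `gaitrel_run`: `index_table`, `reliability`, `qc`,
#'   `config`.
#' @export
run_pipeline <- function(manifest, config = gait_config(), out_dir = NULL) {
  trials <- if (is.data.frame(manifest)) {
    stopifnot(all(c("subject_id", "session", "path") %in% names(manifest)))
    purrr::pmap(manifest[c("subject_id", "session", "path")],
                function(subject_id, session, path) {
                  read_trial_csv(path, subject_id = subject_id,
                                 session = session)
                })
  } else {
    stopifnot(all(vapply(manifest, inherits, logical(1), "gait_trial")))
    manifest
  }
  res <- purrr::map(trials, process_trial, config = config)
  qc <- dplyr::bind_rows(purrr::map(res, "qc"))
  index_table <- dplyr::bind_rows(purrr::compact(purrr::map(res, "indices")))

  bad_subjects <- unique(qc$subject_id[!qc$usable])
  paired <- index_table[!index_table$subject_id %in% bad_subjects, ]
  n_t <- table(paired$session)
  reliability <- NULL
  if (length(n_t) == 2 && all(n_t >= 3)) {
    reliability <- reliability_table(paired, config)
  } else {
    warn("too few complete pairs for a reliability analysis")
  }
  out <- structure(list(index_table = index_table, reliability = reliability,
                        qc = qc, config = config),
                   class = "gaitrel_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_index_table(index_table, file.path(out_dir, "index_table.csv"))
    if (!is.null(reliability)) {
      readr::write_csv(reliability, file.path(out_dir, "reliability.csv"),
                       progress = FALSE)
    }
    readr::write_csv(qc, file.path(out_dir, "qc.csv"), progress = FALSE)
    meta <- list(
      package = "gaitrel",
      version = as.character(utils::packageVersion("gaitrel")),
      filter = config$filter, segmentation = config$segmentation,
      ihr = config$ihr, aggregate = config$aggregate,
      reliability = config$reliability,
      excluded_subjects = bad_subjects
    )
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "run_metadata.json"))
  }
  out
}

#' @export
print.gaitrel_run <- function(x, ...) {
  cat("<gaitrel_run>\n")
  cat("  trials:", nrow(x$qc), " usable:", sum(x$qc$usable), "\n")
  cat("  index table:", nrow(x$index_table), "rows x",
      ncol(x$index_table), "cols\n")
  if (!is.null(x$reliability)) {
    cat("  reliability: ", nrow(x$reliability), " indices, ICC ",
        sprintf("%.2f-%.2f", min(x$reliability$icc), max(x$reliability$icc)),
        "\n", sep = "")
  }
  invisible(x)
}
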