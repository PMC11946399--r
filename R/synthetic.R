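#' Specification of a synthetic test-retest gait cohort
#'
#' Describes the study conditions the generator emulates: a cohort walking a
#' short straight bout at slow self-selected speed (about 0.79 m/s, giving
#' roughly 1 m strides of ~1.27 s), recorded twice within a short interval by
#' five 128 Hz IMUs after a 3 s quiet stance. Upper-body accelerations are a
#' finite series of stride-frequency harmonics whose intrinsic/extrinsic power
#' split fixes the symmetry index analytically; per-axis RMS targets fix the
#' stability index; the shank angular velocity carries one template swing peak
#' per stride for segmentation. Test-retest dependence comes from a
#' subject-level random effect plus session noise whose variance ratio equals
#' `true_icc` per index family.
#'
#' Index-target means and dispersions default to values typical of a severe
#' TBI cohort on a 10 m walk (symmetry around 71-78%, pelvis/trunk/head
#' normalized RMS 0.6-0.85).
#'
#' @param n_subjects Number of subjects. Default 49.
#' @param n_strides Strides per bout (7-12 typical of a 10 m bout at this
#'   speed). Default 8.
#' @param fs Sampling rate, Hz. Default 128.
#' @param static_s Quiet-standing lead-in, s. Default 3.
#' @param stride_time_mean_s,stride_time_sd_s Between-subject stride time
#'   distribution, s. Default mean 163/128 (~1.27 s), SD 0.12.
#' @param stride_jitter_cv Within-bout stride-to-stride duration CV.
#'   Default 0.02; set 0 for analytic-truth work.
#' @param true_icc Named list, test-retest ICC per index family
#'   (`nRMS`, `iHR`, `LDLJ_drive`).
#' @param noise_sd_acc,noise_sd_gyro White sensor noise SD (m/s^2, rad/s).
#' @param rotation_deg Magnitude of the known sensor-to-anatomy misalignment
#'   applied per site (exercises gravity alignment). Default 20; 0 = identity.
#' @param seed Base seed; all randomness derives deterministically from it.
#' @return List of class `gait_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 49L, n_strides = 8L, fs = 128,
                        static_s = 3, stride_time_mean_s = 163 / 128,
                        stride_time_sd_s = 0.12, stride_jitter_cv = 0.02,
                        true_icc = list(nRMS = 0.95, iHR = 0.90,
                                        LDLJ_drive = 0.65),
                        noise_sd_acc = 0.05, noise_sd_gyro = 0.02,
                        rotation_deg = 20, seed = 1L) {
  stopifnot(n_subjects >= 1, n_strides >= 3, fs > 0,
            all(unlist(true_icc) >= 0), all(unlist(true_icc) <= 1))
  structure(list(
    n_subjects = as.integer(n_subjects), n_strides = as.integer(n_strides),
    fs = fs, static_s = static_s, lead_s = 0.5, tail_s = 0.5,
    stride_time_mean_s = stride_time_mean_s,
    stride_time_sd_s = stride_time_sd_s,
    stride_jitter_cv = stride_jitter_cv,
    true_icc = true_icc,
    # index-target distributions (subject-level means / between+within SD)
    ihr_mean = c(AP = 75, ML = 71.3, CC = 78.2),
    ihr_sd = c(AP = 17.2, ML = 12.2, CC = 14.4),
    nrms_mean = c(AP_pelvis = 0.82, ML_pelvis = 0.85, AP_trunk = 0.61,
                  ML_trunk = 0.71, AP_head = 0.68, ML_head = 0.68),
    nrms_sd = c(AP_pelvis = 0.23, ML_pelvis = 0.30, AP_trunk = 0.28,
                ML_trunk = 0.31, AP_head = 0.38, ML_head = 0.33),
    rms_cc_mean = c(pelvis = 1.3, sternum = 1.0, head = 0.9),
    rms_cc_sd = 0.2,
    gyro_rms_mean = c(AP = 0.30, ML = 0.45, CC = 0.35),
    gyro_rms_sd = 0.08,
    noise_sd_acc = noise_sd_acc, noise_sd_gyro = noise_sd_gyro,
    rotation_deg = rotation_deg, seed = as.integer(seed)
  ), class = "gait_cohort_spec")
}

.derive_seed <- function(base, ...) {
  ks <- c(base, ...)
  s <- 0
  for (k in ks) s <- (s * 7919 + (k %% 104729) + 13) %% 2147483647
  as.integer(s)
}

.rotmat <- function(axis, angle) {
  u <- .normalize(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * (u %o% u)
}

# harmonic numbers per parity set
.harm_sets <- function(axis) {
  if (axis == "ML") list(intrinsic = c(1, 3, 5), extrinsic = c(2, 4, 6))
  else list(intrinsic = c(2, 4, 6), extrinsic = c(1, 3, 5))
}

#' Harmonic amplitudes realizing a symmetry and amplitude target
#'
#' Builds per-harmonic sine amplitudes for one acceleration axis such that the
#' signal's total RMS equals `rms_target` and the fraction of harmonic power
#' in the intrinsic set equals `r` exactly (so the symmetry index of the
#' resulting stride-periodic signal is `100 * r` by construction). Amplitudes
#' fall off as 1/k^2 within each set, the steep harmonic decay typical of
#' trunk-level gait accelerations.
#'
#' @param rms_target Target RMS of the harmonic series.
#' @param r Intrinsic power fraction in `[0, 1]`.
#' @param axis `"AP"`, `"ML"` or `"CC"` (fixes the intrinsic parity).
#' @return Named numeric vector: amplitude per harmonic number.
#' @export
harmonic_amplitudes <- function(rms_target, r, axis = "AP") {
  stopifnot(rms_target > 0, r >= 0, r <= 1)
  hs <- .harm_sets(axis)
  p_tot <- rms_target^2
  split_power <- function(ks, p) {
    w <- (1 / ks)^4
    p * w / sum(w)
  }
  p_int <- split_power(hs$intrinsic, r * p_tot)
  p_ext <- split_power(hs$extrinsic, (1 - r) * p_tot)
  k <- c(hs$intrinsic, hs$extrinsic)
  a <- sqrt(2 * c(p_int, p_ext))
  ord <- order(k)
  setNames(a[ord], k[ord])
}

.make_amplitudes <- harmonic_amplitudes

#' Draw one subject's gait profile
#'
#' Deterministic given `(spec$seed, subject_index)`: draws the subject-level
#' index targets (symmetry percentage per axis, normalized RMS per site/axis,
#' CC acceleration scale, angular velocity scale, stride time), harmonic
#' phases, and the per-site misalignment rotations. Session-level draws happen
#' in [synthesize_trial()].
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Integer 1..n.
#' @return List of class `gait_profile`.
#' @export
make_profile <- function(spec, subject_index) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(spec$seed, subject_index, 1))
  icc_b <- function(fam) sqrt(spec$true_icc[[fam]])
  ihr_theta <- pmin(99, pmax(2, spec$ihr_mean +
                               spec$ihr_sd * icc_b("iHR") * rnorm(3)))
  nrms_theta <- pmax(0.05, spec$nrms_mean +
                       spec$nrms_sd * icc_b("nRMS") * rnorm(6))
  rms_cc <- pmax(0.4, spec$rms_cc_mean + spec$rms_cc_sd * rnorm(3))
  gyro_rms <- pmax(0.1, spec$gyro_rms_mean +
                     spec$gyro_rms_sd * icc_b("LDLJ_drive") * rnorm(3))
  stride_time <- max(0.8, min(2.2, spec$stride_time_mean_s +
                                spec$stride_time_sd_s * rnorm(1)))
  phases <- lapply(c(pelvis = "pelvis", sternum = "sternum", head = "head"),
                   function(s) {
                     lapply(c(AP = "AP", ML = "ML", CC = "CC"),
                            function(a) runif(6, 0, 2 * pi))
                   })
  gyro_phases <- lapply(c(AP = "AP", ML = "ML", CC = "CC"),
                        function(a) runif(3, 0, 2 * pi))
  # Sensor mounting: each sensor is tilted by rotation_deg away from the
  # anatomical vertical about a random horizontal axis, with its x-axis
  # facing forward — the same forward-axis convention the alignment step
  # completes AP/ML with, so the anatomical frame is fully recoverable.
  rot <- lapply(setNames(nm = gait_sensor_sites()), function(s) {
    if (spec$rotation_deg == 0) return(diag(3))
    beta <- runif(1, 0, 2 * pi)
    u <- .rotmat(c(cos(beta), sin(beta), 0),
                 spec$rotation_deg * pi / 180) %*% c(0, 0, 1)
    u <- as.numeric(u)                       # gravity direction, sensor frame
    ex <- c(1, 0, 0)
    ap <- .normalize(ex - sum(ex * u) * u)
    ml <- c(u[2] * ap[3] - u[3] * ap[2],
            u[3] * ap[1] - u[1] * ap[3],
            u[1] * ap[2] - u[2] * ap[1])
    rbind(ap, ml, u)
  })
  structure(list(
    spec = spec, subject_index = as.integer(subject_index),
    subject_id = sprintf("S%03d", subject_index),
    ihr_theta = setNames(ihr_theta, names(spec$ihr_mean)),
    nrms_theta = setNames(nrms_theta, names(spec$nrms_mean)),
    rms_cc = setNames(rms_cc, names(spec$rms_cc_mean)),
    gyro_rms = setNames(gyro_rms, names(spec$gyro_rms_mean)),
    stride_time_s = stride_time,
    phases = phases, gyro_phases = gyro_phases, rotations = rot
  ), class = "gait_profile")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# session-level realized index targets (deterministic per profile + session)
.session_params <- function(profile, session) {
  spec <- profile$spec
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(spec$seed, profile$subject_index,
                        if (session == "test") 2 else 3))
  icc_w <- function(fam) sqrt(1 - spec$true_icc[[fam]])
  ihr <- pmin(99.5, pmax(1, profile$ihr_theta +
                           spec$ihr_sd * icc_w("iHR") * rnorm(3)))
  nrms <- pmax(0.05, profile$nrms_theta +
                 spec$nrms_sd * icc_w("nRMS") * rnorm(6))
  gyro_rms <- pmax(0.08, profile$gyro_rms +
                     spec$gyro_rms_sd * icc_w("LDLJ_drive") * rnorm(3))
  list(ihr = setNames(ihr, names(profile$ihr_theta)),
       nrms = setNames(nrms, names(profile$nrms_theta)),
       gyro_rms = setNames(gyro_rms, names(profile$gyro_rms)))
}

# per-site, per-axis acceleration amplitude tables for one session
.session_amplitudes <- function(profile, sp) {
  sites <- c(pelvis = "pelvis", sternum = "sternum", head = "head")
  lvl <- c(pelvis = "pelvis", sternum = "trunk", head = "head")
  lapply(sites, function(s) {
    rms_cc <- profile$rms_cc[[if (s == "sternum") "sternum" else s]]
    r_cc <- sp$ihr[["CC"]] / 100
    amps <- list(
      AP = .make_amplitudes(sp$nrms[[paste0("AP_", lvl[[s]])]] * rms_cc,
                            sp$ihr[["AP"]] / 100, "AP"),
      ML = .make_amplitudes(sp$nrms[[paste0("ML_", lvl[[s]])]] * rms_cc,
                            sp$ihr[["ML"]] / 100, "ML"),
      CC = .make_amplitudes(rms_cc, r_cc, "CC")
    )
    amps
  })
}

.gyro_amplitudes <- function(profile, sp) {
  lapply(c(AP = "AP", ML = "ML", CC = "CC"), function(a) {
    rms <- sp$gyro_rms[[a]]
    w <- (1 / (1:3))^2
    p <- rms^2 * w / sum(w)
    setNames(sqrt(2 * p), 1:3)
  })
}

#' Synthesize one walking trial
#'
#' Realizes the profile as a raw-sensor-frame trial: 3 s quiet stance, a short
#' lead-in, `n_strides + 1` gait cycles (so the detector recovers exactly
#' `n_strides` complete strides) and a tail. Anatomical-frame signals are
#' rotated into the sensor frame by the profile's known misalignment, gravity
#' is added on the anatomical CC axis, a constant gyroscope bias and white
#' noise are applied. The attribute `"truth"` carries the session's realized
#' index targets and the true stride boundary times.
#'
#' @param profile A [make_profile()] result.
#' @param session `"test"` or `"retest"`.
#' @return A [gait_trial()] with attribute `truth`.
#' @export
synthesize_trial <- function(profile, session = c("test", "retest")) {
  session <- match.arg(session)
  spec <- profile$spec
  fs <- spec$fs
  sp <- .session_params(profile, session)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(spec$seed, profile$subject_index,
                        if (session == "test") 4 else 5))

  n_cycles <- spec$n_strides + 1L
  T_j <- profile$stride_time_s *
    (1 + spec$stride_jitter_cv * rnorm(n_cycles))
  static_n <- round(spec$static_s * fs)
  lead_n <- round(spec$lead_s * fs)
  walk_n <- round(sum(T_j) * fs)
  tail_n <- round(spec$tail_s * fs)
  T_len <- static_n + lead_n + walk_n + tail_n
  t_all <- (seq_len(T_len) - 1) / fs
  walk_start_s <- (static_n + lead_n) / fs

  # stride phase Phi(t): cycle index + within-cycle fraction; NA outside bout
  cyc_edges <- walk_start_s + c(0, cumsum(T_j))
  phi <- rep(NA_real_, T_len)
  in_walk <- t_all >= cyc_edges[1] & t_all < cyc_edges[n_cycles + 1]
  idx <- which(in_walk)
  cyc <- findInterval(t_all[idx], cyc_edges, rightmost.closed = TRUE)
  cyc <- pmin(cyc, n_cycles)
  phi[idx] <- (cyc - 1) +
    (t_all[idx] - cyc_edges[cyc]) / T_j[cyc]

  harm_series <- function(amps, phases, phi) {
    out <- numeric(length(phi))
    ok <- !is.na(phi)
    ks <- as.integer(names(amps))
    for (j in seq_along(ks)) {
      out[ok] <- out[ok] + amps[j] * sin(2 * pi * ks[j] * phi[ok] + phases[j])
    }
    out
  }

  amps <- .session_amplitudes(profile, sp)
  gamps <- .gyro_amplitudes(profile, sp)

  sites <- list()
  for (s in c("pelvis", "sternum", "head")) {
    acc_anat <- sapply(c("AP", "ML", "CC"), function(a)
      harm_series(amps[[s]][[a]], profile$phases[[s]][[a]], phi))
    acc_anat[, "CC"] <- acc_anat[, "CC"] + .G
    gyro_anat <- if (s == "pelvis") {
      sapply(c("AP", "ML", "CC"), function(a)
        harm_series(gamps[[a]], profile$gyro_phases[[a]], phi))
    } else {
      matrix(0, T_len, 3, dimnames = list(NULL, c("AP", "ML", "CC")))
    }
    R <- profile$rotations[[s]]
    sites[[s]] <- list(
      acc = acc_anat %*% R + matrix(rnorm(3 * T_len, 0, spec$noise_sd_acc),
                                    T_len, 3),
      gyro = gyro_anat %*% R +
        matrix(rnorm(3 * T_len, 0, spec$noise_sd_gyro), T_len, 3) +
        matrix(rep(c(0.01, -0.02, 0.005), each = T_len), T_len, 3)
    )
  }

  # shank angular velocity: one mid-swing positive peak per cycle (ML axis),
  # boundary trough at 55% of the cycle
  shank_ml <- function(phase_shift) {
    out <- numeric(T_len)
    ok <- !is.na(phi)
    ph <- (phi[ok] + phase_shift) %% n_cycles
    frac <- ph %% 1
    out[ok] <- 4.5 * exp(-((frac - 0.75) / 0.055)^2) -
      1.5 * exp(-((frac - 0.55) / 0.045)^2)
    out
  }
  for (s in c("shank_left", "shank_right")) {
    shift <- if (s == "shank_left") 0 else 0.5
    gyro_anat <- cbind(AP = numeric(T_len), ML = shank_ml(shift),
                       CC = numeric(T_len))
    acc_anat <- cbind(AP = numeric(T_len), ML = numeric(T_len),
                      CC = rep(.G, T_len))
    R <- profile$rotations[[s]]
    sites[[s]] <- list(
      acc = acc_anat %*% R + matrix(rnorm(3 * T_len, 0, spec$noise_sd_acc),
                                    T_len, 3),
      gyro = gyro_anat %*% R +
        matrix(rnorm(3 * T_len, 0, spec$noise_sd_gyro), T_len, 3) +
        matrix(rep(c(-0.005, 0.015, -0.01), each = T_len), T_len, 3)
    )
  }

  trial <- gait_trial(profile$subject_id, session, fs, sites,
                      static_window = c(1L, static_n))
  true_bounds <- walk_start_s + cumsum(c(0, T_j))[seq_len(n_cycles)] +
    0.55 * T_j
  attr(trial, "truth") <- list(
    session_params = sp,
    boundaries_s = true_bounds,
    stride_time_s = profile$stride_time_s,
    n_strides = spec$n_strides
  )
  trial
}

#' Analytic index truths for a synthetic profile
#'
#' Closed-form values of the indices the pipeline should recover from a
#' noiseless synthetic trial, accounting for the pipeline's own zero-phase
#' Butterworth filter (each stride harmonic is scaled by the filter's exact
#' magnitude gain): symmetry from the intrinsic/extrinsic power split, nRMS
#' from per-axis RMS by Parseval, and LDLJ by high-resolution quadrature of
#' the filtered harmonic waveform (analytic derivative, integral by
#' orthogonality, peak amplitude on a fine grid).
#'
#' @param profile A [make_profile()] result.
#' @param session `"test"` or `"retest"`.
#' @param config The [gait_config()] whose filter will process the trial.
#' @param filtered Apply the filter gains? Default `TRUE`.
#' @return One-row tibble with the 15 index truths.
#' @export
analytic_truth <- function(profile, session = "test", config = gait_config(),
                           filtered = TRUE) {
  sp <- .session_params(profile, session)
  T_s <- profile$stride_time_s
  f0 <- 1 / T_s
  ord <- config$filter$order
  gain <- function(k, fc) {
    if (!filtered) return(rep(1, length(k)))
    f <- k * f0
    if (config$filter$zero_phase) 1 / (1 + (f / fc)^(2 * ord))
    else 1 / sqrt(1 + (f / fc)^(2 * ord))
  }
  amps <- .session_amplitudes(profile, sp)
  gamps <- .gyro_amplitudes(profile, sp)
  fc_a <- config$filter$acc_cutoff_hz
  fc_w <- config$filter$gyro_cutoff_hz

  filt_amp <- function(a, fc) {
    k <- as.integer(names(a))
    setNames(a * gain(k, fc), k)
  }
  rms_of <- function(a) sqrt(sum(a^2) / 2)
  ihr_of <- function(a, axis) {
    hs <- .harm_sets(axis)
    k <- as.integer(names(a))
    p <- a^2 / 2
    100 * sum(p[k %in% hs$intrinsic]) / sum(p)
  }
  ldlj_of <- function(a, phases, T_s) {
    k <- as.integer(names(a))
    w <- 2 * pi * k / T_s
    int_d2 <- sum((a * w)^2) / 2 * T_s
    tt <- seq(0, T_s, length.out = 8193)
    s <- numeric(length(tt))
    for (j in seq_along(k)) s <- s + a[j] * sin(w[j] * tt + phases[j])
    -log(T_s^3 / max(s^2) * int_d2)
  }

  out <- list()
  lvl <- c(pelvis = "pelvis", sternum = "trunk", head = "head")
  for (s in names(lvl)) {
    fa <- lapply(amps[[s]], filt_amp, fc = fc_a)
    for (ax in c("AP", "ML")) {
      out[[paste0("nRMS_", ax, "_", lvl[[s]])]] <-
        rms_of(fa[[ax]]) / rms_of(fa[["CC"]])
    }
    if (s == "pelvis") {
      for (ax in c("AP", "ML", "CC")) {
        out[[paste0("iHR_", ax)]] <- ihr_of(fa[[ax]], ax)
        out[[paste0("LDLJa_", ax)]] <-
          ldlj_of(fa[[ax]], profile$phases$pelvis[[ax]], T_s)
      }
      fw <- lapply(gamps, filt_amp, fc = fc_w)
      for (ax in c("AP", "ML", "CC")) {
        out[[paste0("LDLJw_", ax)]] <-
          ldlj_of(fw[[ax]], profile$gyro_phases[[ax]], T_s)
      }
    }
  }
  tibble::as_tibble(out)[, gait_index_names()]
}

#' Generate a full test-retest cohort
#'
#' Draws `n_subjects` profiles and synthesizes both sessions for each. With
#' `out_dir` set, writes one trial CSV per (subject, session), a cohort
#' manifest and a ground-truth table of session-level index targets.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory.
#' @return List: `trials` (list of `gait_trial`, length 2n), `truth`
#'   (tibble of realized session targets), `manifest` (tibble).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  trials <- list()
  truth_rows <- list()
  manifest_rows <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(spec$n_subjects)) {
    prof <- make_profile(spec, i)
    for (sess in c("test", "retest")) {
      tr <- synthesize_trial(prof, sess)
      key <- paste0(prof$subject_id, "_", sess)
      trials[[key]] <- tr
      tru <- attr(tr, "truth")$session_params
      truth_rows[[key]] <- tibble::tibble(
        subject_id = prof$subject_id, session = sess,
        stride_time_s = prof$stride_time_s,
        !!!setNames(as.list(tru$ihr), paste0("true_iHR_", names(tru$ihr))),
        !!!setNames(as.list(tru$nrms), paste0("true_nRMS_", names(tru$nrms)))
      )
      if (!is.null(out_dir)) {
        fp <- file.path(out_dir, paste0(key, ".csv"))
        write_trial_csv(tr, fp)
        manifest_rows[[key]] <- tibble::tibble(
          subject_id = prof$subject_id, session = sess, path = fp)
      }
    }
  }
  truth <- dplyr::bind_rows(truth_rows)
  manifest <- if (length(manifest_rows)) dplyr::bind_rows(manifest_rows)
              else tibble::tibble()
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                     progress = FALSE)
    readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"),
                     progress = FALSE)
  }
  list(trials = trials, truth = truth, manifest = manifest)
}

#' Simulate paired index values from the variance-components model
#'
#' Draws `n` subjects' (test, retest) values of one index under the
#' reliability model: subject effect with variance `icc * sd^2`, independent
#' session noise with variance `(1 - icc) * sd^2`, so the true test-retest
#' ICC equals `icc`. This is the index-level counterpart of the full signal
#' generator, used for parameter-recovery studies of the reliability module.
#'
#' @param n Subjects.
#' @param mean,sd Marginal mean and SD of the index.
#' @param icc True ICC in `[0, 1)`.
#' @return Tibble: `subject_id`, `test`, `retest`.
#' @export
simulate_index_pairs <- function(n, mean = 0, sd = 1, icc = 0.9) {
  stopifnot(icc >= 0, icc < 1, sd > 0)
  theta <- rnorm(n, mean, sd * sqrt(icc))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    test = theta + rnorm(n, 0, sd * sqrt(1 - icc)),
    retest = theta + rnorm(n, 0, sd * sqrt(1 - icc))
  )
}
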