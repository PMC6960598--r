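#' Create a synthetic subject profile
#'
#' Draws a subject for the synthetic cohort: anthropometrics (height, weight,
#' BMI), gender code, baseline pressures, the coupling coefficients of the
#' ground-truth pressure function, and subject-level means of the latent beat
#' parameters (pulse transit time, heart rate, dicrotic amplitude ratio).
#'
#' The ground-truth pressure function attached to every rendered record is
#' \deqn{SBP = \beta_0 + \beta_1 / PTT + \beta_2 HR + \beta_3 \rho + \varepsilon,}
#' where `PTT` is the R-to-onset transit time (s), `HR` the heart rate (bpm),
#' `rho` the dicrotic-to-systolic amplitude ratio and `epsilon ~ N(0,
#' noise_sd)`; DBP uses its own coefficient set. The intercepts are chosen so
#' the subject's baseline pressures are attained at the subject's mean latents.
#'
#' @param seed Integer seed; profiles are deterministic given the seed.
#' @param ... Overrides for any profile field (`height`, `weight`, `gender`,
#'   `base_sbp`, `base_dbp`, `noise_sd`, `r_offset_mean`, `hr_mean`,
#'   `dicrotic_ratio_mean`, `subject_id`).
#' @return An object of class `bp_subject`.
#' @export
make_subject <- function(seed, ...) {
  ov <- list(...)
  p <- with_seed(derive_seed(seed, 101L), {
    list(
      subject_id = sprintf("S%04d", seed %% 10000L),
      gender = stats::rbinom(1, 1, 0.5),            # 0 = female, 1 = male
      height = max(1.45, stats::rnorm(1, 1.70, 0.08)),
      weight = max(40, stats::rnorm(1, 65, 10)),
      base_sbp = stats::rnorm(1, 115, 8),
      base_dbp = stats::rnorm(1, 72, 5),
      noise_sd = 2,
      r_offset_mean = stats::runif(1, 0.18, 0.26),
      hr_mean = stats::runif(1, 60, 85),
      dicrotic_ratio_mean = stats::runif(1, 0.30, 0.45)
    )
  })
  for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  if (p$height <= 0 || p$weight <= 0) stop("height and weight must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  p$base_dbp <- min(p$base_dbp, p$base_sbp - 25)
  p$bmi <- p$weight / p$height^2
  # coupling: sbp/dbp = beta0 + beta1/ptt + beta2*hr + beta3*rho
  cs <- c(NA, 3.5, 0.25, -12)
  cd <- c(NA, 2.0, 0.12, -6)
  cs[1] <- p$base_sbp - cs[2] / p$r_offset_mean - cs[3] * p$hr_mean -
    cs[4] * p$dicrotic_ratio_mean
  cd[1] <- p$base_dbp - cd[2] / p$r_offset_mean - cd[3] * p$hr_mean -
    cd[4] * p$dicrotic_ratio_mean
  p$coupling <- list(sbp = cs, dbp = cd)
  structure(p, class = "bp_subject")
}

#' @export
print.bp_subject <- function(x, ...) {
  cat(sprintf("<bp_subject %s> gender=%d height=%.2fm weight=%.1fkg BMI=%.1f\n",
              x$subject_id, x$gender, x$height, x$weight, x$bmi))
  cat(sprintf("  base BP %.0f/%.0f mmHg, mean PTT %.0f ms, mean HR %.0f bpm\n",
              x$base_sbp, x$base_dbp, 1000 * x$r_offset_mean, x$hr_mean))
  invisible(x)
}

#' Additive noise configuration for rendered records
#'
#' @param baseline_amp Amplitude (a.u.) of the sub-Hz baseline-wander sinusoid
#'   added to the PPG channel.
#' @param baseline_freq Baseline-wander frequency in Hz (must be <= 0.5).
#' @param powerline_amp Amplitude of the mains interference added to both
#'   channels.
#' @param powerline_freq Mains frequency in Hz (default 50).
#' @param white_sd Standard deviation of white noise added to both channels.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(baseline_amp = 0.05, baseline_freq = 0.3,
                         powerline_amp = 0.02, powerline_freq = 50,
                         white_sd = 0.01) {
  stopifnot(baseline_freq <= 0.5, baseline_amp >= 0, powerline_amp >= 0,
            white_sd >= 0)
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 white_sd = white_sd), class = "noise_config")
}

#' Noise-free configuration
#' @return A `noise_config` with every component zero.
#' @export
noise_none <- function() noise_config(0, 0.3, 0, 50, 0)

# Continuous single-beat model: systolic Gaussian + dicrotic Gaussian + a
# small linearly decaying diastolic ramp (guarantees the cycle minimum sits at
# the onset). tau in [0, Tb).
beat_wave <- function(tau, Tb, ra) {
  mu1 <- 0.13 * Tb; s1 <- 0.045 * Tb
  mu2 <- 0.40 * Tb; s2 <- 0.085 * Tb
  exp(-(tau - mu1)^2 / (2 * s1^2)) +
    ra * exp(-(tau - mu2)^2 / (2 * s2^2)) +
    0.01 * (1 - tau / Tb)
}

beat_wave_deriv <- function(tau, Tb, ra) {
  mu1 <- 0.13 * Tb; s1 <- 0.045 * Tb
  mu2 <- 0.40 * Tb; s2 <- 0.085 * Tb
  -(tau - mu1) / s1^2 * exp(-(tau - mu1)^2 / (2 * s1^2)) -
    ra * (tau - mu2) / s2^2 * exp(-(tau - mu2)^2 / (2 * s2^2)) -
    0.01 / Tb
}

# Planted fiducial truth for one beat, located on the continuous model.
beat_truth <- function(Tb, ra, r_offset) {
  f_w <- function(tau) beat_wave(tau, Tb, ra)
  f_d <- function(tau) beat_wave_deriv(tau, Tb, ra)
  t_c <- stats::optimize(f_w, c(0, 0.30 * Tb), maximum = TRUE, tol = 1e-10)$maximum
  t_a <- stats::optimize(f_d, c(0, t_c), maximum = TRUE, tol = 1e-10)$maximum
  t_e <- stats::optimize(f_d, c(t_c, 0.40 * Tb), tol = 1e-10)$minimum
  t_f <- NA_real_; t_g <- NA_real_
  if (ra > 0) {
    t_f <- stats::optimize(f_w, c(t_e, 0.40 * Tb), tol = 1e-10)$minimum
    t_g <- stats::optimize(f_w, c(t_f, 0.70 * Tb), maximum = TRUE, tol = 1e-10)$maximum
    # a notch exists only if the waveform genuinely turns up after t_f
    if (f_w(t_g) <= f_w(t_f) + 1e-12) { t_f <- NA_real_; t_g <- NA_real_ }
  }
  amp <- function(tt) if (is.na(tt)) NA_real_ else f_w(tt)
  list(t_b = 0, t_a = t_a, t_c = t_c, t_e = t_e, t_f = t_f, t_g = t_g,
       amp_b = f_w(0), amp_a = amp(t_a), amp_c = amp(t_c), amp_e = amp(t_e),
       amp_f = amp(t_f), amp_g = amp(t_g),
       r_offset = r_offset, period = Tb)
}

#' Render a synthetic PPG+ECG record
#'
#' Produces a synchronized two-channel record: the PPG is a concatenation of
#' beats, each the sum of a systolic and a dicrotic pulse component (plus a
#' small diastolic ramp) so that all six fiducial points (b, a, c, e, f, g)
#' exist with known locations; the ECG is a flat baseline with one triangular
#' 20 ms R-spike per beat, preceding the pulse onset by the transit time
#' `r_offset`. Reference pressures are computed from the documented
#' ground-truth function of the record's latent parameters (see
#' [make_subject()]); the formula is recorded in the record's `bp_function`
#' field.
#'
#' @param profile A `bp_subject`.
#' @param duration Record length in seconds (default 20).
#' @param hr Heart rate in bpm (30-200); default draws around the subject mean.
#' @param r_offset,ra Optional fixed transit time (s) and dicrotic amplitude
#'   ratio; by default both are drawn around the subject means.
#' @param noise A [noise_config()].
#' @param seed Integer seed; records are bit-identical given the seed.
#' @param fs Sampling frequency in Hz (default 500).
#' @param dicrotic Logical; render the dicrotic component (FALSE produces
#'   degenerate beats without notch/dicrotic peak, for detector stress tests).
#' @return An object of class `bp_record` with fields `ppg`, `ecg`, `fs`,
#'   `beats` (planted truth), `sbp_ref`, `dbp_ref`, `latent`, `subject_id`,
#'   `bp_function`.
#' @export
render_record <- function(profile, duration = 20, hr = NULL,
                          noise = noise_config(), seed = 1, fs = 500,
                          dicrotic = TRUE, r_offset = NULL, ra = NULL) {
  stopifnot(inherits(profile, "bp_subject"), duration > 0)
  rs <- derive_seed(seed, 211L)
  lat <- with_seed(rs, {
    list(
      hr = if (is.null(hr)) min(180, max(40, stats::rnorm(1, profile$hr_mean, 3)))
           else hr,
      r_offset = if (is.null(r_offset))
        min(0.35, max(0.12, stats::rnorm(1, profile$r_offset_mean, 0.015)))
      else r_offset,
      ra = if (!dicrotic) 0
      else if (is.null(ra))
        min(0.60, max(0.15, stats::rnorm(1, profile$dicrotic_ratio_mean, 0.03)))
      else ra,
      eps_s = stats::rnorm(1, 0, profile$noise_sd),
      eps_d = stats::rnorm(1, 0, profile$noise_sd)
    )
  })
  if (lat$hr < 30 || lat$hr > 200) stop("heart rate outside 30-200 bpm")
  Tb <- 60 / lat$hr
  t0 <- 0.05                              # lead-in before the first R-spike
  if (duration < t0 + lat$r_offset + Tb) stop("duration shorter than one beat")

  n <- round(duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  onsets <- seq(t0 + lat$r_offset, duration - 1e-9, by = Tb)
  ppg <- numeric(n)
  # virtual beat before the first onset fills the lead-in with a diastolic tail
  pre <- tgrid < onsets[1]
  ppg[pre] <- beat_wave(tgrid[pre] - (onsets[1] - Tb), Tb, lat$ra)
  beats <- vector("list", length(onsets))
  tr <- beat_truth(Tb, lat$ra, lat$r_offset)
  for (k in seq_along(onsets)) {
    idx <- which(tgrid >= onsets[k] & tgrid < onsets[k] + Tb)
    ppg[idx] <- beat_wave(tgrid[idx] - onsets[k], Tb, lat$ra)
    beats[[k]] <- c(tr, list(onset = onsets[k], r_time = onsets[k] - tr$r_offset))
  }
  ecg <- numeric(n)
  half <- 0.010                            # 20 ms triangular R-spike
  for (k in seq_along(onsets)) {
    rt <- onsets[k] - lat$r_offset
    idx <- which(abs(tgrid - rt) <= half)
    ecg[idx] <- pmax(ecg[idx], 1 - abs(tgrid[idx] - rt) / half)
  }

  ns <- derive_seed(seed, 223L)
  noisy <- with_seed(ns, {
    ph <- stats::runif(2, 0, 2 * pi)
    list(
      ppg = ppg +
        noise$baseline_amp * sin(2 * pi * noise$baseline_freq * tgrid + ph[1]) +
        noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tgrid + ph[2]) +
        stats::rnorm(n, 0, noise$white_sd),
      ecg = ecg +
        noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tgrid + ph[2]) +
        stats::rnorm(n, 0, noise$white_sd)
    )
  })

  cs <- profile$coupling$sbp; cd <- profile$coupling$dbp
  sbp <- cs[1] + cs[2] / lat$r_offset + cs[3] * lat$hr + cs[4] * lat$ra + lat$eps_s
  dbp <- cd[1] + cd[2] / lat$r_offset + cd[3] * lat$hr + cd[4] * lat$ra + lat$eps_d
  if (dbp >= sbp) dbp <- sbp - 10

  structure(list(
    ppg = noisy$ppg, ecg = noisy$ecg, fs = fs, beats = beats,
    sbp_ref = sbp, dbp_ref = dbp, subject_id = profile$subject_id,
    latent = lat[c("hr", "r_offset", "ra")],
    bp_function = "bp = beta0 + beta1/r_offset + beta2*hr + beta3*dicrotic_ratio + eps",
    coupling = profile$coupling, duration = duration
  ), class = "bp_record")
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf("<bp_record %s> %.0f s @ %d Hz, %d beats, ref %.1f/%.1f mmHg\n",
              x$subject_id, x$duration, x$fs, length(x$beats),
              x$sbp_ref, x$dbp_ref))
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Builds a train/test cohort partitioned by subject. The default layout
#' mirrors a realistic acquisition campaign: 17 training subjects contributing
#' between 20 and 64 records each (775 in total) and 10 test subjects with
#' exactly 12 records each (120 in total).
#'
#' @param n_train_subjects,n_test_subjects Subject counts (test may be 0).
#' @param records_per_subject List with elements `train` (vector, recycled to
#'   `n_train_subjects`) and `test` (scalar, default 12).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param duration,noise,fs Passed to [render_record()].
#' @param render_signals If `FALSE`, only subjects, latents, reference
#'   pressures and the manifest are generated (fast bookkeeping mode); the
#'   waveforms themselves are skipped.
#' @return An object of class `bp_cohort`: `subjects`, `records` (list of
#'   `bp_record`, signal-free in bookkeeping mode), and `manifest`
#'   (data.frame: subject_id, record_id, split, sbp_ref, dbp_ref).
#' @export
make_cohort <- function(n_train_subjects = 17, n_test_subjects = 10,
                        records_per_subject = NULL, seed = 1,
                        duration = 20, noise = noise_config(), fs = 500,
                        render_signals = TRUE) {
  stopifnot(n_train_subjects >= 0, n_test_subjects >= 0)
  default_train <- c(44, 61, 51, 52, 52, 31, 40, 53,
                     27, 47, 41, 28, 64, 55, 20, 55, 54)
  rps <- records_per_subject %||% list(train = default_train, test = 12)
  train_counts <- if (n_train_subjects > 0)
    rep_len(rps$train %||% default_train, n_train_subjects) else integer(0)
  test_count <- rps$test %||% 12

  subjects <- list(); records <- list(); man <- list()
  build <- function(split, i, n_rec) {
    sid <- derive_seed(seed, if (split == "train") 300L else 400L, i)
    subj <- make_subject(sid,
                         subject_id = sprintf("%s%02d",
                                              if (split == "train") "TR" else "TE", i))
    recs <- vector("list", n_rec)
    for (r in seq_len(n_rec)) {
      rseed <- derive_seed(sid, 7L, r)
      if (render_signals) {
        recs[[r]] <- render_record(subj, duration = duration, noise = noise,
                                   seed = rseed, fs = fs)
      } else {
        rr <- render_stub(subj, rseed)
        recs[[r]] <- rr
      }
      recs[[r]]$record_id <- sprintf("%s_R%03d", subj$subject_id, r)
      recs[[r]]$split <- split
    }
    list(subject = subj, records = recs)
  }
  for (i in seq_len(n_train_subjects)) {
    b <- build("train", i, train_counts[i])
    subjects[[b$subject$subject_id]] <- b$subject
    records <- c(records, b$records)
  }
  for (i in seq_len(n_test_subjects)) {
    b <- build("test", i, test_count)
    subjects[[b$subject$subject_id]] <- b$subject
    records <- c(records, b$records)
  }
  manifest <- if (length(records)) data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    record_id = vapply(records, `[[`, "", "record_id"),
    split = vapply(records, `[[`, "", "split"),
    sbp_ref = vapply(records, `[[`, 0, "sbp_ref"),
    dbp_ref = vapply(records, `[[`, 0, "dbp_ref"),
    stringsAsFactors = FALSE
  ) else data.frame(subject_id = character(0), record_id = character(0),
                    split = character(0), sbp_ref = numeric(0),
                    dbp_ref = numeric(0))
  structure(list(subjects = subjects, records = records, manifest = manifest,
                 seed = seed),
            class = "bp_cohort")
}

# bookkeeping-mode record: latents and reference pressures, no waveforms
render_stub <- function(profile, seed) {
  rs <- derive_seed(seed, 211L)
  lat <- with_seed(rs, {
    list(hr = min(180, max(40, stats::rnorm(1, profile$hr_mean, 3))),
         r_offset = min(0.35, max(0.12, stats::rnorm(1, profile$r_offset_mean, 0.015))),
         ra = min(0.60, max(0.15, stats::rnorm(1, profile$dicrotic_ratio_mean, 0.03))),
         eps_s = stats::rnorm(1, 0, profile$noise_sd),
         eps_d = stats::rnorm(1, 0, profile$noise_sd))
  })
  cs <- profile$coupling$sbp; cd <- profile$coupling$dbp
  sbp <- cs[1] + cs[2] / lat$r_offset + cs[3] * lat$hr + cs[4] * lat$ra + lat$eps_s
  dbp <- cd[1] + cd[2] / lat$r_offset + cd[3] * lat$hr + cd[4] * lat$ra + lat$eps_d
  structure(list(ppg = NULL, ecg = NULL, fs = NA_integer_, beats = list(),
                 sbp_ref = sbp, dbp_ref = min(dbp, sbp - 10),
                 subject_id = profile$subject_id,
                 latent = lat[c("hr", "r_offset", "ra")],
                 bp_function = "bp = beta0 + beta1/r_offset + beta2*hr + beta3*dicrotic_ratio + eps",
                 coupling = profile$coupling, duration = NA_real_),
            class = "bp_record")
}

#' @export
print.bp_cohort <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat(sprintf("<bp_cohort> %d subjects, %d records (%s)\n",
              length(x$subjects), nrow(x$manifest),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a record to plain-text files
#'
#' Each channel is written as a two-column CSV (`time_s`, `value`) and the
#' metadata (fs, subject, reference pressures, planted fiducial truth, the
#' ground-truth pressure function) as a JSON sidecar.
#'
#' @param rec A `bp_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_record <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, rec$record_id %||% "record")
  tgrid <- (seq_along(rec$ppg) - 1) / rec$fs
  utils::write.csv(data.frame(time_s = tgrid, value = rec$ppg),
                   paste0(stem, "_ppg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = tgrid, value = rec$ecg),
                   paste0(stem, "_ecg.csv"), row.names = FALSE)
  meta <- rec[c("fs", "sbp_ref", "dbp_ref", "subject_id", "bp_function",
                "latent", "duration")]
  meta$beats <- lapply(rec$beats, function(b) b[!vapply(b, is.na, TRUE)])
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paste0(stem, "_ppg.csv"), paste0(stem, "_ecg.csv"),
              paste0(stem, "_meta.json")))
}

#' Write a cohort manifest CSV
#' @param cohort A `bp_cohort`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
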