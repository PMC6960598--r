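# canonical column order of the feature vector
feature_names <- function() {
  c("t_up", "t_bf", "t_down", "t_fb", "t_ae",
    "t_upr", "t_bfr", "t_downr", "t_fbr", "t_aer",
    "PTT_b", "PTT_a", "PTT_c",
    "H_ar", "H_er", "H_fr", "H_gr",
    "S_bf", "S_fb", "K", "HR", "C_slope", "BMI", "gender")
}

#' Per-beat waveform features
#'
#' Computes the 22 waveform characteristics for every delineated beat: timing
#' intervals between fiducials and their ratios to the cardiac cycle, pulse
#' transit times from the R-peak, amplitude ratios referenced to the beat foot
#' (the PPG value at b), systolic/diastolic areas by trapezoidal integration,
#' the waveform factor K, heart rate from the adjacent R-R interval, and the
#' main-wave rising slope.
#'
#' @param fids A `bp_fiducials` table from [detect_ppg_fiducials()].
#' @param ppg The PPG sample vector the fiducials refer to.
#' @param fs Sampling frequency, Hz.
#' @param k_variant Waveform-factor definition: `"standard"` uses
#'   `(S_m - H_b)/(H_c - H_b)` (the literature waveform factor, with all
#'   amplitudes foot-referenced); `"peak_relative"` uses
#'   `(S_m - H_c)/(H_c - H_b)` (an alternative that is negative whenever the
#'   cycle mean lies below the peak).
#' @return data.frame with one row per retained beat and 22 feature columns;
#'   beats with a degenerate amplitude (peak equal to foot) are rejected.
#' @export
beat_features <- function(fids, ppg, fs, k_variant = c("standard", "peak_relative")) {
  k_variant <- match.arg(k_variant)
  dt <- 1 / fs
  out <- list()
  for (i in seq_len(nrow(fids))) {
    z <- fids[i, ]
    foot <- ppg[z$b]
    H_c <- ppg[z$c] - foot
    if (H_c <= .Machine$double.eps) next   # division-by-zero guard: H_c == H_b
    Tb <- (z$next_b - z$b) * dt
    seg_bf <- ppg[z$b:z$f] - foot
    seg_fb <- ppg[z$f:z$next_b] - foot
    seg_all <- ppg[z$b:z$next_b] - foot
    S_bf <- trapz_uniform(seg_bf, dt)
    S_fb <- trapz_uniform(seg_fb, dt)
    S_m <- trapz_uniform(seg_all, dt) / Tb
    K <- if (k_variant == "standard") S_m / H_c else (S_m - H_c) / H_c
    t_up <- (z$c - z$b) * dt
    row <- data.frame(
      beat = z$beat,
      t_up = t_up,
      t_bf = (z$f - z$b) * dt,
      t_down = (z$next_b - z$c) * dt,
      t_fb = (z$next_b - z$f) * dt,
      t_ae = (z$e - z$a) * dt,
      t_upr = (z$c - z$b) / (z$next_b - z$b),
      t_bfr = (z$f - z$b) / (z$next_b - z$b),
      t_downr = (z$next_b - z$c) / (z$next_b - z$b),
      t_fbr = (z$next_b - z$f) / (z$next_b - z$b),
      t_aer = (z$e - z$a) / (z$next_b - z$b),
      PTT_b = (z$b - z$R) * dt,
      PTT_a = (z$a - z$R) * dt,
      PTT_c = (z$c - z$R) * dt,
      H_ar = (ppg[z$a] - foot) / H_c,
      H_er = (ppg[z$e] - foot) / H_c,
      H_fr = (ppg[z$f] - foot) / H_c,
      H_gr = (ppg[z$g] - foot) / H_c,
      S_bf = S_bf, S_fb = S_fb, K = K,
      HR = 60 / ((z$next_R - z$R) * dt),
      C_slope = H_c / t_up
    )
    out[[length(out) + 1]] <- row
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

#' Aggregate beat features into a record-level feature vector
#'
#' Each waveform feature is the median across the record's valid beats
#' (robust to residual artifacts); BMI and gender are appended, giving the
#' 24-component feature vector used by the pressure models.
#'
#' @param bf Per-beat feature data.frame from [beat_features()].
#' @param subject The record's `bp_subject` (supplies BMI and gender).
#' @return Named numeric vector of length 24 (see `feature_names`).
#' @export
record_features <- function(bf, subject) {
  if (nrow(bf) < 3) stop("record rejected: fewer than 3 valid beats (",
                         nrow(bf), ")")
  wf <- setdiff(feature_names(), c("BMI", "gender"))
  v <- vapply(wf, function(nm) stats::median(bf[[nm]]), numeric(1))
  c(v, BMI = subject$bmi, gender = as.numeric(subject$gender))
}

#' Extract the feature matrix of a cohort
#'
#' Runs the per-record pipeline (optional denoising, R-peak detection, PPG
#' delineation, beat features, record aggregation) over every record of a
#' cohort that carries signals.
#'
#' @param cohort A `bp_cohort` with rendered signals.
#' @param denoise Logical; apply [preprocess_record()] first (use `FALSE` for
#'   noise-free cohorts).
#' @param cfg A [denoise_config()] used when `denoise = TRUE`.
#' @param k_variant Passed to [beat_features()].
#' @return List: `X` (records x 24 feature matrix), `meta` (data.frame with
#'   subject_id, record_id, split, sbp_ref, dbp_ref), `dropped` (character
#'   vector naming records that failed with the reason).
#' @export
cohort_features <- function(cohort, denoise = FALSE, cfg = denoise_config(),
                            k_variant = "standard") {
  rows <- list(); meta <- list(); dropped <- character(0)
  for (rec in cohort$records) {
    fv <- tryCatch({
      r <- if (denoise) preprocess_record(rec, cfg) else rec
      rp <- detect_r_peaks(r$ecg, r$fs)
      fid <- detect_ppg_fiducials(r$ppg, rp$peaks, r$fs)
      bf <- beat_features(fid, r$ppg, r$fs, k_variant = k_variant)
      record_features(bf, cohort$subjects[[rec$subject_id]])
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      dropped <- c(dropped, sprintf("%s: %s", rec$record_id, conditionMessage(fv)))
      next
    }
    rows[[length(rows) + 1]] <- fv
    meta[[length(meta) + 1]] <- data.frame(
      subject_id = rec$subject_id, record_id = rec$record_id,
      split = rec$split %||% NA_character_,
      sbp_ref = rec$sbp_ref, dbp_ref = rec$dbp_ref, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no record yielded a feature vector")
  X <- do.call(rbind, rows)
  colnames(X) <- feature_names()
  list(X = X, meta = do.call(rbind, meta), dropped = dropped)
}

#' Write a feature matrix as CSV
#'
#' One row per record: the 24 named feature columns plus subject_id,
#' record_id, split and the reference pressures.
#'
#' @param fm Result of [cohort_features()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(fm, path) {
  utils::write.csv(cbind(fm$meta, as.data.frame(fm$X)), path, row.names = FALSE)
  invisible(path)
}
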