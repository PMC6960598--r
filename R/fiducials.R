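# local extrema helpers on the sample grid
local_maxima <- function(x) which(diff(sign(diff(x))) < 0) + 1L
local_minima <- function(x) which(diff(sign(diff(x))) > 0) + 1L

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]; d[n] <- x[n] - x[n - 1]
  d
}

#' Detect ECG R-peaks
#'
#' Lightweight Pan-Tompkins-style detector: 5-15 Hz band-pass, derivative,
#' squaring, 150 ms moving-window integration, adaptive threshold with a
#' 250 ms refractory period, and refinement to the local maximum of the input
#' signal. Beats implying an instantaneous heart rate outside 30-200 bpm are
#' flagged, not silently kept.
#'
#' @param ecg Numeric ECG sample vector (at least 2 s).
#' @param fs Sampling frequency, Hz.
#' @return List with `peaks` (strictly increasing sample indices), `flagged`
#'   (indices into `peaks` whose preceding RR interval is physiologically
#'   implausible) and `note` (character, non-empty when nothing was found).
#' @export
detect_r_peaks <- function(ecg, fs) {
  stopifnot(fs > 0)
  if (length(ecg) < 2 * fs) stop("record shorter than 2 s")
  if (anyNA(ecg)) stop("signal contains NA")
  if (max(ecg) - min(ecg) < .Machine$double.eps^0.5) {
    return(list(peaks = integer(0), flagged = integer(0),
                note = "no QRS activity detected"))
  }
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, ecg))
  integ <- as.numeric(stats::filter(c(diff(xf), 0)^2,
                                    rep(1 / round(0.15 * fs), round(0.15 * fs)),
                                    sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.25 * stats::quantile(integ, 0.99)
  cand <- local_maxima(integ)
  cand <- cand[integ[cand] > thr]
  if (length(cand) == 0) {
    return(list(peaks = integer(0), flagged = integer(0),
                note = "no QRS activity detected"))
  }
  # refractory: keep the strongest candidate within any 250 ms window
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] > 0.25 * fs) {
      keep <- c(keep, i)
    } else if (integ[i] > integ[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  # refine to the raw-signal local maximum within +/- 60 ms
  w <- round(0.06 * fs)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - w); hi <- min(length(ecg), i + w)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  rr <- diff(peaks) / fs
  hr <- 60 / rr
  flagged <- which(hr < 30 | hr > 200) + 1L
  list(peaks = peaks, flagged = flagged, note = "")
}

# pulse onsets (point b) given R-peaks: minimum between the R-peak and the
# following systolic peak; used both by the fiducial delineator and as spline
# anchors for baseline removal
ppg_onsets <- function(ppg, r_peaks, fs) {
  stopifnot(length(r_peaks) >= 1)
  n <- length(ppg)
  onsets <- integer(0)
  for (k in seq_along(r_peaks)) {
    r <- r_peaks[k]
    hi <- if (k < length(r_peaks)) r_peaks[k + 1] else min(n, r + round(0.9 * fs))
    lo <- min(r + round(0.05 * fs), n)
    if (hi - lo < 3) next
    cpk <- lo + which.max(ppg[lo:hi]) - 1L
    b <- r + which.min(ppg[(r + 1):cpk])
    if ((b - r) / fs >= 0.05 && (b - r) / fs <= 0.6) onsets <- c(onsets, b)
  }
  onsets
}

#' Delineate PPG fiducial points
#'
#' For each beat between consecutive R-peaks, locates the six classical PPG
#' fiducial points: b (pulse onset, the minimum before the systolic upstroke),
#' a (maximum ascending slope), c (systolic peak), e (minimum descending
#' slope), f (dicrotic notch, first local minimum after e) and g (dicrotic
#' peak, first local maximum after f). R-peaks are paired with the first onset
#' 50-600 ms later; beats lacking any point are dropped and counted.
#'
#' @param ppg Denoised PPG sample vector.
#' @param r_peaks R-peak sample indices (from [detect_r_peaks()]).
#' @param fs Sampling frequency, Hz.
#' @return An object of class `bp_fiducials`: data.frame with columns `beat`,
#'   `R`, `b`, `a`, `c`, `e`, `f`, `g` (sample indices); attributes `fs`,
#'   `dropped` (count) and `drop_reasons`.
#' @export
detect_ppg_fiducials <- function(ppg, r_peaks, fs) {
  if (length(r_peaks) < 1) stop("no R-peaks supplied")
  d1 <- central_diff(ppg)
  rows <- list(); reasons <- character(0)
  # onsets for every R first (the next beat's onset closes the current cycle)
  bs <- rep(NA_integer_, length(r_peaks))
  cs <- rep(NA_integer_, length(r_peaks))
  n <- length(ppg)
  for (k in seq_along(r_peaks)) {
    r <- r_peaks[k]
    hi <- if (k < length(r_peaks)) r_peaks[k + 1] else min(n, r + round(0.9 * fs))
    lo <- min(r + round(0.05 * fs), n - 1)
    if (hi - lo < 3) next
    cpk <- lo + which.max(ppg[lo:hi]) - 1L
    if (cpk <= r + 1) next
    b <- r + which.min(ppg[(r + 1):cpk])
    if ((b - r) / fs < 0.05 || (b - r) / fs > 0.6) next
    bs[k] <- b; cs[k] <- cpk
  }
  for (k in seq_len(length(r_peaks) - 1)) {
    fail <- function(why) reasons[length(reasons) + 1] <<- sprintf("beat %d: %s", k, why)
    if (is.na(bs[k])) { fail("no onset (b) pairable with R") ; next }
    if (is.na(bs[k + 1])) { fail("next onset missing") ; next }
    b <- bs[k]; cc <- cs[k]; nb <- bs[k + 1]
    a <- b + which.max(d1[b:cc]) - 1L
    e <- cc + which.min(d1[cc:nb]) - 1L
    seg <- ppg[e:nb]
    lm <- local_minima(seg)
    f <- if (length(lm)) e + lm[1] - 1L else {
      # fallback: first upward zero-crossing of the second derivative
      d2 <- diff(d1[e:nb])
      zc <- which(d2[-1] > 0 & d2[-length(d2)] <= 0)
      if (length(zc)) e + zc[1] else NA_integer_
    }
    if (is.na(f)) { fail("no dicrotic notch (f)") ; next }
    sg <- ppg[f:nb]
    lx <- local_maxima(sg)
    g <- if (length(lx)) f + lx[1] - 1L else NA_integer_
    if (is.na(g)) { fail("no dicrotic peak (g)") ; next }
    if (!(r_peaks[k] < b && b < a && a < cc && cc < e && e <= f && f <= g)) {
      fail("fiducial ordering violated") ; next
    }
    rows[[length(rows) + 1]] <- data.frame(beat = k, R = r_peaks[k], b = b,
                                           a = a, c = cc, e = e, f = f, g = g,
                                           next_b = nb, next_R = r_peaks[k + 1])
  }
  if (length(rows) == 0)
    stop("no complete beat delineated: ", paste(reasons, collapse = "; "))
  out <- do.call(rbind, rows)
  structure(out, class = c("bp_fiducials", "data.frame"), fs = fs,
            dropped = length(reasons), drop_reasons = reasons)
}
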