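#' Denoising configuration
#'
#' Settings for wavelet-packet denoising of ECG/PPG records and for the
#' cubic-spline baseline-drift removal applied to PPG.
#'
#' @param wavelet Orthonormal wavelet basis; only `"coif5"` is provided.
#' @param levels Wavelet-packet decomposition depth (default 3).
#' @param cost_function Best-basis information cost; `"SURE"` entropy.
#' @param threshold_rule Coefficient quantization rule; `"universal_soft"`
#'   applies the soft universal threshold `sigma * sqrt(2 log N)` with `sigma`
#'   estimated from the median absolute deviation of the finest detail
#'   coefficients.
#' @param spline_anchor Knots for the baseline spline; `"pulse_onsets"` (the
#'   detected b points).
#'
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(wavelet = "coif5", levels = 3,
                           cost_function = "SURE",
                           threshold_rule = "universal_soft",
                           spline_anchor = "pulse_onsets") {
  stopifnot(levels >= 1)
  cost_function <- match.arg(cost_function, "SURE")
  threshold_rule <- match.arg(threshold_rule, c("universal_soft", "donoho_sure"))
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 cost_function = cost_function,
                 threshold_rule = threshold_rule,
                 spline_anchor = spline_anchor),
            class = "denoise_config")
}

#' Wavelet-packet denoising
#'
#' Decomposes the signal over a full wavelet-packet tree, selects the best
#' basis by SURE-entropy cost, soft-thresholds every basis node except the
#' approximation (repeated lowpass) node with the universal threshold, and
#' reconstructs. Signals whose length is not divisible by `2^levels` are
#' reflection-padded at the end and trimmed after reconstruction.
#'
#' @param x Numeric sample vector.
#' @param cfg A [denoise_config()].
#' @return Denoised vector of the same length as `x`.
#' @export
wp_denoise <- function(x, cfg = denoise_config()) {
  if (anyNA(x)) stop("signal contains NA")
  n <- length(x)
  block <- 2^cfg$levels
  if (n < block) stop("signal too short for ", cfg$levels, " decomposition levels")
  pad <- (block - n %% block) %% block
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x

  flt <- wp_filters(cfg$wavelet)
  tree <- wp_decompose(xp, cfg$levels, flt)
  keep <- wp_best_basis(tree)

  # noise scale from the finest (level-1) detail coefficients
  d1 <- tree[[2]][[2]]
  sigma <- stats::median(abs(d1 - stats::median(d1))) / 0.6745
  thr <- sigma * sqrt(2 * log(length(xp)))

  for (j in seq_along(keep)) {
    for (p in seq_along(keep[[j]])) {
      if (keep[[j]][p] && p > 1) {  # p == 1 is the pure-lowpass approximation
        tree[[j]][[p]] <- soft_threshold(tree[[j]][[p]], thr)
      }
    }
  }
  out <- wp_reconstruct(tree, keep, flt)
  out[seq_len(n)]
}

#' Cubic-spline baseline-drift removal
#'
#' Fits a natural cubic spline through the PPG values at the anchor samples
#' (normally the detected pulse onsets) and subtracts it, removing sub-Hz
#' baseline wander while leaving beat-relative amplitudes intact.
#'
#' @param ppg Numeric PPG sample vector.
#' @param anchors Strictly increasing sample indices (at least 4).
#' @return Baseline-corrected vector; values at the anchors are approximately 0.
#' @export
baseline_correct <- function(ppg, anchors) {
  anchors <- as.integer(anchors)
  if (length(anchors) < 4) stop("baseline spline needs at least 4 anchor points")
  if (any(diff(anchors) <= 0)) stop("anchors must be strictly increasing")
  if (any(anchors < 1) || any(anchors > length(ppg))) stop("anchors out of range")
  sf <- stats::splinefun(anchors, ppg[anchors], method = "natural")
  ppg - sf(seq_along(ppg))
}

#' Denoise one synthetic record
#'
#' Applies [wp_denoise()] to both channels and, when pulse onsets can be
#' located, [baseline_correct()] to the PPG channel.
#'
#' @param rec A `bp_record` from [render_record()].
#' @param cfg A [denoise_config()].
#' @param baseline Logical; also remove PPG baseline drift via onset-anchored
#'   spline (skipped with fewer than 4 detected onsets).
#' @return The record with denoised channels.
#' @export
preprocess_record <- function(rec, cfg = denoise_config(), baseline = TRUE) {
  rec$ecg <- wp_denoise(rec$ecg, cfg)
  rec$ppg <- wp_denoise(rec$ppg, cfg)
  if (baseline) {
    r <- detect_r_peaks(rec$ecg, rec$fs)
    if (length(r$peaks) >= 1) {
      on <- tryCatch(ppg_onsets(rec$ppg, r$peaks, rec$fs), error = function(e) integer(0))
      if (length(on) >= 4) rec$ppg <- baseline_correct(rec$ppg, on)
    }
  }
  rec
}
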