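#' Mean absolute deviation of predictions
#'
#' @param y Measured values, mmHg.
#' @param yhat Predicted values, mmHg.
#' @return `mean(|y - yhat|)`, mmHg.
#' @export
mad_error <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) stop("empty or mismatched input")
  mean(abs(y - yhat))
}

#' Standard deviation of the prediction error
#'
#' Sample standard deviation (n-1 denominator) of the error after removing
#' its mean.
#'
#' @inheritParams mad_error
#' @return SD of `y - yhat`, mmHg.
#' @export
std_error <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("mismatched input")
  if (length(y) < 2) stop("at least 2 paired values required")
  stats::sd(y - yhat)
}

#' Pool per-individual RMSEs
#'
#' Sample-size-weighted quadratic pooling: `sqrt(sum(n_i r_i^2) / sum(n_i))`,
#' identical to the RMSE over the concatenated errors.
#'
#' @param rmse_i Per-individual RMSEs, mmHg.
#' @param n_i Per-individual sample counts (default: equal).
#' @return Pooled RMSE, mmHg.
#' @export
pooled_rmse <- function(rmse_i, n_i = rep(1, length(rmse_i))) {
  if (length(rmse_i) == 0) stop("empty input")
  stopifnot(length(rmse_i) == length(n_i), all(n_i > 0))
  sqrt(sum(n_i * rmse_i^2) / sum(n_i))
}

#' AAMI agreement criterion
#'
#' Device-agreement bound of the Association for the Advancement of Medical
#' Instrumentation: mean absolute error at most 5 mmHg and error SD at most
#' 8 mmHg (boundary inclusive).
#'
#' @param mad Mean absolute deviation, mmHg.
#' @param std Error standard deviation, mmHg.
#' @return Logical pass/fail.
#' @export
aami_check <- function(mad, std) {
  stopifnot(mad >= 0, std >= 0)
  mad <= 5 && std <= 8
}

#' BHS letter grade
#'
#' British Hypertension Society grading from the cumulative fractions of
#' absolute errors within 5, 10 and 15 mmHg: grade A requires 60/85/95%,
#' B 50/75/90%, C 40/65/85%; anything less is D. The highest grade whose three
#' thresholds are all met is returned.
#'
#' @param p5,p10,p15 Percentages of absolute errors `<= 5`, `<= 10`,
#'   `<= 15` mmHg (must be non-decreasing).
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
bhs_grade <- function(p5, p10, p15) {
  if (p5 < 0 || p15 > 100 || p5 > p10 || p10 > p15)
    stop("cumulative percentages must satisfy 0 <= p5 <= p10 <= p15 <= 100")
  lim <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  for (g in names(lim)) {
    if (all(c(p5, p10, p15) >= lim[[g]])) return(g)
  }
  "D"
}

#' Cumulative error fractions
#'
#' @inheritParams mad_error
#' @return Named vector `c(p5, p10, p15)`: percentages of absolute errors
#'   within 5, 10 and 15 mmHg (inclusive thresholds).
#' @export
error_fractions <- function(y, yhat) {
  ae <- abs(y - yhat)
  c(p5 = 100 * mean(ae <= 5), p10 = 100 * mean(ae <= 10),
    p15 = 100 * mean(ae <= 15))
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (predicted minus measured, so a positive value means the
#' model reads high) and 95% limits of agreement.
#'
#' @inheritParams mad_error
#' @return Named vector `c(mean_diff, loa_low, loa_high)`, mmHg.
#' @export
bland_altman <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("at least 2 paired values required")
  d <- yhat - y
  m <- mean(d); s <- stats::sd(d)
  c(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Pearson correlation of predictions and measurements
#'
#' @inheritParams mad_error
#' @return Product-moment correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 3)
    stop("at least 3 paired values required")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined for constant input")
  stats::cor(y, yhat)
}

#' Per-individual and pooled evaluation report
#'
#' Computes RMSE/MAD/STD per individual and pooled (quadratic pooling for
#' RMSE, sample-size-weighted means for MAD, SD of pooled centred errors for
#' STD), plus AAMI pass/fail, BHS grade, Pearson correlation and Bland-Altman
#' statistics on the pooled errors.
#'
#' @param y Measured pressures, mmHg.
#' @param yhat Predicted pressures, mmHg.
#' @param individual Factor/character vector assigning records to individuals.
#' @return An object of class `bp_eval`: list with `per_individual`
#'   (data.frame) and `pooled` (list of the summary statistics).
#' @export
eval_report <- function(y, yhat, individual) {
  stopifnot(length(y) == length(yhat), length(y) == length(individual))
  ids <- unique(individual)
  per <- do.call(rbind, lapply(ids, function(id) {
    sel <- individual == id
    data.frame(individual = id, n = sum(sel),
               RMSE = rmse(y[sel], yhat[sel]),
               MAD = mad_error(y[sel], yhat[sel]),
               STD = std_error(y[sel], yhat[sel]))
  }))
  err <- y - yhat
  fr <- error_fractions(y, yhat)
  pooled <- list(
    n = length(y),
    RMSE = pooled_rmse(per$RMSE, per$n),
    MAD = mad_error(y, yhat),
    STD = std_error(y, yhat),
    aami_pass = aami_check(mad_error(y, yhat), std_error(y, yhat)),
    p5 = fr[["p5"]], p10 = fr[["p10"]], p15 = fr[["p15"]],
    bhs = bhs_grade(fr[["p5"]], fr[["p10"]], fr[["p15"]]),
    pearson_r = pearson_r(y, yhat),
    bland_altman = bland_altman(y, yhat)
  )
  stopifnot(pooled$MAD <= pooled$RMSE + 1e-12)   # Jensen
  structure(list(per_individual = per, pooled = pooled), class = "bp_eval")
}

#' @export
print.bp_eval <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<bp_eval> n=%d  RMSE=%.4f  MAD=%.4f  STD=%.4f mmHg\n",
              p$n, p$RMSE, p$MAD, p$STD))
  cat(sprintf("  AAMI: %s   BHS: %s (%.1f/%.1f/%.1f%%)   r=%.4f\n",
              if (p$aami_pass) "pass" else "FAIL", p$bhs, p$p5, p$p10, p$p15,
              p$pearson_r))
  cat(sprintf("  Bland-Altman: %.4f [%.4f, %.4f] mmHg\n",
              p$bland_altman[1], p$bland_altman[2], p$bland_altman[3]))
  invisible(x)
}

#' Write an evaluation report as CSV
#' @param report A `bp_eval`.
#' @param path Output CSV path (per-individual rows; the pooled row is
#'   appended with individual = "pooled").
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  p <- report$pooled
  pooled_row <- data.frame(individual = "pooled", n = p$n, RMSE = p$RMSE,
                           MAD = p$MAD, STD = p$STD)
  utils::write.csv(rbind(report$per_individual, pooled_row), path,
                   row.names = FALSE)
  invisible(path)
}
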