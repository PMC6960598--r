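#' Mean impact values of a trained network's inputs
#'
#' For each feature the sample matrix is perturbed by +10% and -10% of its
#' original values (other columns untouched); the mean impact value (MIV) is
#' the signed mean difference between the two resulting predictions. The
#' absolute value is applied later, when contributions are formed.
#'
#' @param net A trained `bp_network`.
#' @param X Feature matrix the network was trained on (original scale).
#' @return Named numeric vector of MIVs, mmHg.
#' @export
miv_scores <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$topo$n_in) stop("feature dimension mismatch with network")
  miv <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    P1 <- X; P1[, j] <- P1[, j] * 1.1
    P2 <- X; P2[, j] <- P2[, j] * 0.9
    miv[j] <- mean(predict(net, P1) - predict(net, P2))
  }
  names(miv) <- colnames(X)
  miv
}

#' Contribution table from mean impact values
#'
#' Normalizes absolute MIVs into relative contributions
#' `|MIV_i| / sum |MIV_i|`, ranks features by descending `|MIV|` (ties broken
#' by original column order) and attaches cumulative contributions.
#'
#' @param miv Named numeric vector of MIVs.
#' @return An object of class `miv_table`: data.frame with columns `rank`,
#'   `feature`, `MIV`, `contribution`, `cumulative`.
#' @export
contributions <- function(miv) {
  if (length(miv) < 1) stop("no features")
  if (all(miv == 0)) stop("all MIVs are zero; contributions undefined")
  if (is.null(names(miv))) names(miv) <- sprintf("x%d", seq_along(miv))
  ord <- order(-abs(miv), seq_along(miv))
  contrib <- abs(miv)[ord] / sum(abs(miv))
  out <- data.frame(rank = seq_along(miv), feature = names(miv)[ord],
                    MIV = unname(miv[ord]), contribution = unname(contrib),
                    cumulative = cumsum(unname(contrib)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("miv_table", "data.frame"))
}

#' Select features by cumulative contribution
#'
#' Returns the smallest prefix of the ranked features whose cumulative
#' contribution reaches the threshold.
#'
#' @param table A `miv_table` from [contributions()].
#' @param threshold Cumulative-contribution threshold in (0, 1).
#' @return Character vector of selected feature names.
#' @export
screen <- function(table, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  k <- which(table$cumulative >= threshold - 1e-12)[1]
  if (is.na(k)) k <- nrow(table)
  table$feature[seq_len(k)]
}

#' Two-round MIV feature screening
#'
#' Round 1 trains a network on all features and screens at the first
#' threshold; round 2 retrains on the survivors and screens at the second
#' threshold. A single trained network per round supplies the MIVs;
#' optionally the MIVs are averaged over `k_retrain` retrainings with
#' different initializations for stability.
#'
#' @param X Feature matrix (original scale).
#' @param y Target vector, mmHg.
#' @param n_hidden Hidden-layer size used for the screening networks.
#' @param cfg A [train_config()].
#' @param thresholds Length-2 vector of cumulative-contribution thresholds
#'   (default `c(0.91, 0.89)`).
#' @param seed Integer seed for the trainings.
#' @param k_retrain Number of retrainings averaged per round (default 1).
#' @return List: `selected` (final feature names), `round1`, `round2`
#'   (the two `miv_table`s).
#' @export
two_round_screen <- function(X, y, n_hidden, cfg = train_config(),
                             thresholds = c(0.91, 0.89), seed = 1,
                             k_retrain = 1) {
  X <- as.matrix(X)
  one_round <- function(Xr, thr, round_id) {
    mivs <- sapply(seq_len(k_retrain), function(k) {
      ck <- cfg; ck$seed <- derive_seed(seed, round_id, k)
      net <- train_lm(Xr, y, n_hidden, ck)
      miv_scores(net, Xr)
    })
    tab <- contributions(rowMeans(as.matrix(mivs)))
    list(tab = tab, sel = screen(tab, thr))
  }
  r1 <- one_round(X, thresholds[1], 1L)
  r2 <- one_round(X[, r1$sel, drop = FALSE], thresholds[2], 2L)
  list(selected = r2$sel, round1 = r1$tab, round2 = r2$tab)
}

#' Write an MIV table as CSV
#' @param table A `miv_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_miv_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
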