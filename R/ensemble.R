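#' Train five base networks by fivefold cross-validation
#'
#' Shuffles the samples with the given seed, splits them into five folds, and
#' trains network k (via [optimize_network()]) on the four folds excluding
#' fold k; each network's held-out-fold RMSE is recorded. Each fold's GA and
#' fine-tuning run from a fresh derived seed.
#'
#' @param X Feature matrix (>= 50 samples).
#' @param y Target vector, mmHg.
#' @param n_hidden Hidden-layer size.
#' @param ga_cfg A [ga_config()] for the weight-initialization GA.
#' @param train_cfg A [train_config()] for fine-tuning.
#' @param seed Integer seed governing the shuffle and all trainings.
#' @return List: `nets` (5 `bp_network`s), `fold` (fold id per sample),
#'   `fold_rmse` (held-out RMSE per network).
#' @export
train_base_models <- function(X, y, n_hidden, ga_cfg = ga_config(),
                              train_cfg = train_config(), seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 50) stop("at least 50 samples required for fivefold training")
  perm <- with_seed(derive_seed(seed, 55L), sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(1:5, n)
  nets <- vector("list", 5)
  fold_rmse <- numeric(5)
  for (k in 1:5) {
    tr <- fold != k
    gk <- ga_cfg; gk$seed <- derive_seed(seed, 60L, k)
    tk <- train_cfg; tk$seed <- derive_seed(seed, 61L, k)
    nets[[k]] <- optimize_network(X[tr, , drop = FALSE], y[tr], n_hidden,
                                  ga_cfg = gk, train_cfg = tk)
    fold_rmse[k] <- rmse(y[!tr], predict(nets[[k]], X[!tr, , drop = FALSE]))
  }
  list(nets = nets, fold = fold, fold_rmse = fold_rmse)
}

#' Assemble an integrated (ensemble) pressure model
#'
#' Holds the five SBP and five DBP base networks plus, after calibration,
#' per-individual proportional coefficients: the individualized prediction is
#' the plain weighted sum `a1*Net1 + ... + a5*Net5` (the coefficients are not
#' re-normalized and need not sum to 1).
#'
#' @param nets_sbp,nets_dbp Lists of five `bp_network`s each.
#' @param features Character vector naming the feature columns the networks
#'   expect.
#' @return An object of class `bp_ensemble`.
#' @export
new_ensemble <- function(nets_sbp, nets_dbp, features = NULL) {
  stopifnot(length(nets_sbp) == 5, length(nets_dbp) == 5)
  structure(list(nets_sbp = nets_sbp, nets_dbp = nets_dbp,
                 features = features, coefficients = list()),
            class = "bp_ensemble")
}

#' @export
print.bp_ensemble <- function(x, ...) {
  cat(sprintf("<bp_ensemble> 5 SBP + 5 DBP networks, %d calibrated individual(s)\n",
              length(x$coefficients)))
  invisible(x)
}

# each base network picks its own feature columns when the supplied matrix is
# wider than its input layer (SBP and DBP models may use different screened
# feature sets)
base_predictions <- function(nets, X) {
  X <- as.matrix(X)
  P <- vapply(nets, function(nn) {
    Xn <- X
    if (ncol(Xn) != nn$topo$n_in) {
      if (is.null(colnames(Xn)) || is.null(nn$feature_names))
        stop("feature dimension mismatch and no names to subset by")
      Xn <- Xn[, nn$feature_names, drop = FALSE]
    }
    predict(nn, Xn)
  }, numeric(nrow(X)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  P
}

#' Calibrate the ensemble for one individual
#'
#' Fits the five proportional coefficients per pressure target (SBP and DBP
#' independently) on the individual's calibration records by minimizing the
#' calibration RMSE of the weighted sum of base-network predictions with the
#' multiple-population GA. Coefficients stay inside the decoding range by
#' construction, not by clipping.
#'
#' @param model A `bp_ensemble`.
#' @param individual_id Identifier of the individual being calibrated.
#' @param calib_X Calibration feature matrix (>= 2 records; 6 by default
#'   protocol).
#' @param calib_y_sbp,calib_y_dbp Calibration reference pressures, mmHg.
#' @param ga_cfg A [ga_config()]; the default uses 15 populations of 20,
#'   25 bits per coefficient and range \[-0.5, 0.8\].
#' @return The model with coefficients (and calibration RMSEs) stored for the
#'   individual.
#' @export
calibrate_individual <- function(model, individual_id, calib_X,
                                 calib_y_sbp, calib_y_dbp,
                                 ga_cfg = ga_config(n_populations = 15,
                                                    pop_size = 20,
                                                    bits_per_variable = 25)) {
  calib_X <- as.matrix(calib_X)
  if (nrow(calib_X) < 2) stop("at least 2 calibration records required")
  fit_one <- function(nets, yc, sub) {
    P <- base_predictions(nets, calib_X)
    cfg <- ga_cfg; cfg$seed <- derive_seed(ga_cfg$seed, 91L, sub)
    # the equal-weight ensemble is part of the initial gene pool, so the
    # calibrated coefficients can only improve on it (elitism)
    eq <- rep(0.2, 5)
    init <- if (all(eq >= cfg$var_range[1] & eq <= cfg$var_range[2]))
      list(eq) else NULL
    ga <- mpga_evolve(function(a) rmse(yc, drop(P %*% a)), 5, cfg, init = init)
    list(coef = ga$best, rmse = ga$fitness)
  }
  s <- fit_one(model$nets_sbp, calib_y_sbp, 1L)
  d <- fit_one(model$nets_dbp, calib_y_dbp, 2L)
  model$coefficients[[individual_id]] <- list(
    a = s$coef, b = d$coef, rmse_sbp = s$rmse, rmse_dbp = d$rmse)
  model
}

#' Individualized pressure prediction
#'
#' @param object A calibrated `bp_ensemble`.
#' @param individual_id Identifier used at calibration.
#' @param X Feature matrix of the records to predict.
#' @param ... Unused.
#' @return data.frame with columns `sbp` and `dbp`, mmHg. Implausible outputs
#'   (below 40 mmHg) trigger a warning.
#' @export
predict.bp_ensemble <- function(object, individual_id, X, ...) {
  co <- object$coefficients[[individual_id]]
  if (is.null(co)) stop("individual not calibrated: ", individual_id)
  X <- as.matrix(X)
  sbp <- drop(base_predictions(object$nets_sbp, X) %*% co$a)
  dbp <- drop(base_predictions(object$nets_dbp, X) %*% co$b)
  if (any(c(sbp, dbp) < 40))
    warning("implausible prediction below 40 mmHg for ", individual_id)
  data.frame(sbp = sbp, dbp = dbp)
}

#' Export the per-individual coefficient tables as CSV
#'
#' One row per calibrated individual: a1..a5, b1..b5 and the calibration
#' RMSEs.
#'
#' @param model A calibrated `bp_ensemble`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_coefficients <- function(model, path) {
  ids <- names(model$coefficients)
  rows <- lapply(ids, function(id) {
    co <- model$coefficients[[id]]
    cbind(data.frame(individual = id),
          as.data.frame(as.list(stats::setNames(co$a, paste0("a", 1:5)))),
          as.data.frame(as.list(stats::setNames(co$b, paste0("b", 1:5)))),
          data.frame(rmse_sbp = co$rmse_sbp, rmse_dbp = co$rmse_dbp))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
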