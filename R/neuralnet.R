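#' Hidden-layer sizing rule
#'
#' Empirical range for the number of hidden nodes of a single-hidden-layer
#' network: `m = round(sqrt(n + l)) + delta` with `delta` between 1 and 10
#' (rounding half-up). For 14 inputs and 1 output this gives the range 5-14.
#'
#' @param n Number of input nodes.
#' @param l Number of output nodes.
#' @return Integer vector `c(m_min, m_max)`.
#' @export
sizing_range <- function(n, l) {
  stopifnot(n >= 1, l >= 1)
  s <- sqrt(n + l)
  c(m_min = as.integer(round_half_up(s + 1)),
    m_max = as.integer(round_half_up(s + 10)))
}

#' Training configuration
#'
#' @param learning_rate Step size for the plain-gradient algorithm (default
#'   0.01); ignored by Levenberg-Marquardt, which adapts its own damping.
#' @param max_epochs Epoch cap (default 1000).
#' @param goal_mse Stopping goal on the scaled-space training MSE (default 1e-4).
#' @param algorithm `"levenberg_marquardt"` (default) or `"gradient"`.
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, max_epochs = 1000,
                         goal_mse = 1e-4,
                         algorithm = c("levenberg_marquardt", "gradient"),
                         seed = 1) {
  stopifnot(learning_rate > 0, max_epochs >= 1, goal_mse > 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), goal_mse = goal_mse,
                 algorithm = match.arg(algorithm), seed = seed),
            class = "train_config")
}

#' Number of free parameters of a topology
#' @param n_in,n_hidden,n_out Node counts (output defaults to 1).
#' @return Integer parameter count `n_hidden*(n_in+1) + n_out*(n_hidden+1)`.
#' @export
n_params <- function(n_in, n_hidden, n_out = 1) {
  n_hidden * (n_in + 1) + n_out * (n_hidden + 1)
}

# min-max scaling records to [-1, 1]; degenerate (constant) columns map to 0
fit_scaling <- function(X, y) {
  xr <- apply(X, 2, range)
  yr <- range(y)
  list(x_min = xr[1, ], x_max = xr[2, ], y_min = yr[1], y_max = yr[2])
}

scale_x <- function(X, sc) {
  span <- sc$x_max - sc$x_min
  span[span == 0] <- 1
  sweep(sweep(X, 2, sc$x_min), 2, span, "/") * 2 - 1
}

scale_y <- function(y, sc) {
  span <- sc$y_max - sc$y_min
  if (span == 0) span <- 1
  2 * (y - sc$y_min) / span - 1
}

descale_y <- function(ys, sc) {
  span <- sc$y_max - sc$y_min
  if (span == 0) span <- 1
  (ys + 1) / 2 * span + sc$y_min
}

#' Construct a single-hidden-layer regression network
#'
#' Architecture: tansig (tanh) hidden layer, linear output. The flat parameter
#' vector is ordered as: input-to-hidden weights (column-major, hidden index
#' fastest), hidden biases, hidden-to-output weights, output bias. Input and
#' target min-max scaling to \[-1, 1\] is fitted on the supplied training data
#' and stored with the model.
#'
#' @param X Training feature matrix (rows = samples) used to fit the scaling.
#' @param y Training target vector (mmHg).
#' @param n_hidden Hidden-layer size.
#' @param theta Optional flat parameter vector (default zeros).
#' @return An object of class `bp_network`.
#' @export
new_network <- function(X, y, n_hidden, theta = NULL) {
  X <- as.matrix(X)
  topo <- list(n_in = ncol(X), n_hidden = as.integer(n_hidden), n_out = 1L)
  P <- n_params(topo$n_in, topo$n_hidden)
  if (is.null(theta)) theta <- numeric(P)
  if (length(theta) != P) stop("parameter vector length ", length(theta),
                               " does not match topology (", P, ")")
  structure(list(topo = topo, theta = theta, scaling = fit_scaling(X, y),
                 feature_names = colnames(X)),
            class = "bp_network")
}

#' Flat parameter access
#' @param net A `bp_network`.
#' @return Numeric parameter vector.
#' @export
get_params <- function(net) net$theta

#' @rdname get_params
#' @param theta Replacement flat parameter vector (must match the topology
#'   and contain only finite values).
#' @return The network with parameters replaced.
#' @export
set_params <- function(net, theta) {
  if (length(theta) != length(net$theta)) stop("parameter length mismatch")
  if (!all(is.finite(theta))) stop("non-finite parameter values")
  net$theta <- theta
  net
}

unpack_params <- function(theta, topo) {
  m <- topo$n_hidden; n <- topo$n_in
  W1 <- matrix(theta[seq_len(m * n)], nrow = m, ncol = n)
  b1 <- theta[m * n + seq_len(m)]
  w2 <- theta[m * n + m + seq_len(m)]
  b2 <- theta[m * n + 2 * m + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

# forward pass in scaled space; Xs is rows-as-samples, already scaled
forward_scaled <- function(theta, topo, Xs) {
  p <- unpack_params(theta, topo)
  Z <- Xs %*% t(p$W1)
  Z <- sweep(Z, 2, p$b1, "+")
  H <- tanh(Z)
  list(yhat = as.numeric(H %*% p$w2 + p$b2), H = H)
}

#' Network prediction
#'
#' Scales the input per the stored records, propagates through the tanh hidden
#' layer and linear output, and de-scales back to mmHg.
#'
#' @param object A `bp_network`.
#' @param X Feature matrix or single feature vector (original scale).
#' @param ... Unused.
#' @return Numeric vector of predictions, mmHg.
#' @export
predict.bp_network <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != object$topo$n_in) stop("dimension mismatch: expected ",
                                        object$topo$n_in, " features")
  Xs <- scale_x(X, object$scaling)
  descale_y(forward_scaled(object$theta, object$topo, Xs)$yhat, object$scaling)
}

#' @export
print.bp_network <- function(x, ...) {
  cat(sprintf("<bp_network> %d-%d-%d (tansig/purelin), %d parameters\n",
              x$topo$n_in, x$topo$n_hidden, x$topo$n_out, length(x$theta)))
  invisible(x)
}

#' Root-mean-square error of a network on a data set
#'
#' @param net A `bp_network`.
#' @param X Feature matrix (original scale).
#' @param y Target vector, mmHg.
#' @return RMSE in mmHg: `sqrt(sum((y - yhat)^2) / n)`.
#' @export
rmse_fitness <- function(net, X, y) {
  if (length(y) == 0) stop("empty input")
  rmse(y, predict(net, X))
}

#' Levenberg-Marquardt network training
#'
#' Trains the single-hidden-layer network by damped Gauss-Newton
#' (Levenberg-Marquardt) with an analytic Jacobian: the damping factor starts
#' at 1e-3, is multiplied by 10 on a rejected step and divided by 10 on an
#' accepted one, so the training SSE is non-increasing over accepted steps.
#' A plain batch-gradient algorithm is available for cross-checking.
#'
#' @param X Training feature matrix (rows = samples).
#' @param y Training targets, mmHg.
#' @param n_hidden Hidden-layer size.
#' @param cfg A [train_config()].
#' @param theta0 Optional initial flat parameter vector (e.g. from the genetic
#'   optimizer); default is a seeded uniform draw in \[-0.5, 0.5\].
#' @return A trained `bp_network` with attributes `epochs` and `train_mse`
#'   (scaled-space MSE trace).
#' @export
train_lm <- function(X, y, n_hidden, cfg = train_config(), theta0 = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("NA in training data")
  net <- new_network(X, y, n_hidden)
  P <- length(net$theta)
  if (nrow(X) < P / 2)
    warning("fewer samples (", nrow(X), ") than half the parameter count (", P, ")")
  theta <- theta0 %||% with_seed(derive_seed(cfg$seed, 31L),
                                 stats::runif(P, -0.5, 0.5))
  if (length(theta) != P) stop("theta0 length mismatch")
  Xs <- scale_x(X, net$scaling)
  ys <- scale_y(y, net$scaling)
  n <- nrow(Xs); m <- n_hidden; ni <- ncol(Xs)

  jac <- function(theta) {
    p <- unpack_params(theta, net$topo)
    fw <- forward_scaled(theta, net$topo, Xs)
    S <- (1 - fw$H^2) * matrix(p$w2, n, m, byrow = TRUE)
    JW1 <- Xs[, rep(seq_len(ni), each = m), drop = FALSE] *
      S[, rep(seq_len(m), ni), drop = FALSE]
    list(J = cbind(JW1, S, fw$H, rep(1, n)), r = fw$yhat - ys)
  }

  mse_trace <- numeric(0)
  if (cfg$algorithm == "gradient") {
    for (ep in seq_len(cfg$max_epochs)) {
      jr <- jac(theta)
      theta <- theta - cfg$learning_rate * 2 / n * drop(crossprod(jr$J, jr$r))
      mse <- mean(jac(theta)$r^2)
      mse_trace <- c(mse_trace, mse)
      if (mse <= cfg$goal_mse) break
    }
  } else {
    lambda <- 1e-3
    jr <- jac(theta)
    sse <- sum(jr$r^2)
    for (ep in seq_len(cfg$max_epochs)) {
      A <- crossprod(jr$J)
      g <- drop(crossprod(jr$J, jr$r))
      accepted <- FALSE
      for (tries in 1:30) {
        step <- tryCatch(solve(A + lambda * diag(ncol(A)), g),
                         error = function(e) NULL)
        if (!is.null(step)) {
          cand <- theta - step
          fw <- forward_scaled(cand, net$topo, Xs)
          sse_new <- sum((fw$yhat - ys)^2)
          if (is.finite(sse_new) && sse_new < sse) {
            theta <- cand
            improve <- (sse - sse_new) / max(sse, .Machine$double.eps)
            sse <- sse_new
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
      mse_trace <- c(mse_trace, sse / n)
      if (!accepted) break
      if (sse / n <= cfg$goal_mse) break
      jr <- jac(theta)
    }
  }
  net <- set_params(net, theta)
  attr(net, "epochs") <- length(mse_trace)
  attr(net, "train_mse") <- mse_trace
  net
}

#' Root-mean-square error of paired vectors
#' @param y Measured values.
#' @param yhat Predicted values.
#' @return `sqrt(sum((y - yhat)^2)/n)`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) stop("empty or mismatched input")
  sqrt(mean((y - yhat)^2))
}

#' Serialize / restore a network as structured text
#'
#' @param net A `bp_network`.
#' @param path JSON file path.
#' @return `write_network` invisibly returns `path`; `read_network` returns
#'   the restored `bp_network`.
#' @export
write_network <- function(net, path) {
  jsonlite::write_json(list(topo = net$topo, theta = net$theta,
                            scaling = net$scaling,
                            feature_names = net$feature_names),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(topo = as.list(o$topo), theta = as.numeric(o$theta),
                 scaling = list(x_min = as.numeric(o$scaling$x_min),
                                x_max = as.numeric(o$scaling$x_max),
                                y_min = o$scaling$y_min, y_max = o$scaling$y_max),
                 feature_names = o$feature_names),
            class = "bp_network")
}
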