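# Periodized orthogonal wavelet-packet transform.
#
# No wavelet package ships with the declared dependencies, so the transform is
# implemented directly: circular (periodized) analysis/synthesis with an
# orthonormal filter pair, a full packet tree to a fixed depth, best-basis
# selection by an additive SURE-entropy cost, and universal soft thresholding
# of the detail nodes.

# Coiflet-5 scaling (lowpass decomposition) filter, 30 taps.
.coif5_lo <- c(
  -9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
  3.7007277113394796e-06, -2.1270221672515614e-05, -4.1219861924265501e-05,
  1.4035632812373243e-04, 3.0185794166824478e-04, -6.3755892612588115e-04,
  -1.6616273039298788e-03, 2.4315754425382886e-03, 6.7615202206204169e-03,
  -9.1595073386761625e-03, -1.9758391600965465e-02, 3.2674799467057355e-02,
  4.1287530472117834e-02, -1.0556315130733723e-01, -6.2037751574981960e-02,
  4.3798230665916338e-01, 7.7429362286032744e-01, 4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.1921588060086087e-02, 2.8169744270532353e-02,
  2.3408322118927783e-02, -1.0131584846900276e-02, -4.1593126275786402e-03,
  2.1782943778456947e-03, 3.5857774116175768e-04, -2.1208186206749400e-04
)

wp_filters <- function(wavelet = "coif5") {
  if (!identical(wavelet, "coif5"))
    stop("unsupported wavelet basis: ", wavelet)
  lo <- .coif5_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # QMF pair
  list(lo = lo, hi = hi, L = L)
}

# circular correlation: y[n] = sum_j f[j] * x[(n + j - 2) mod N + 1]
circ_corr <- function(x, f) {
  N <- length(x); L <- length(f)
  xp <- c(x, x[seq_len(min(L - 1, N))])
  while (length(xp) < N + L - 1) xp <- c(xp, xp[seq_len(N)])[seq_len(N + L - 1)]
  out <- as.numeric(stats::filter(xp, rev(f), method = "convolution", sides = 1))
  out[L:(N + L - 1)]
}

# one analysis step: even-phase decimation of the circular correlations
wp_analyze <- function(x, flt) {
  a <- circ_corr(x, flt$lo)
  d <- circ_corr(x, flt$hi)
  idx <- seq(1, length(x), by = 2)
  list(a = a[idx], d = d[idx])
}

# adjoint of wp_analyze (orthogonal transform: adjoint = inverse)
wp_synthesize <- function(a, d, flt) {
  N <- 2 * length(a)
  au <- numeric(N); du <- numeric(N)
  au[seq(1, N, by = 2)] <- a
  du[seq(1, N, by = 2)] <- d
  # x[n] = sum_j lo[j]*au[(n - j) mod N] + hi[j]*du[(n - j) mod N]
  conv_circ <- function(u, f) {
    L <- length(f)
    up <- c(u[(N - L + 2):N], u)
    out <- as.numeric(stats::filter(up, f, method = "convolution", sides = 1))
    out[L:(N + L - 1)]
  }
  conv_circ(au, flt$lo) + conv_circ(du, flt$hi)
}

# Full packet tree to `levels`; node (j, p) stored as tree[[j + 1]][[p + 1]],
# j = 0 (root) .. levels, p = 0 .. 2^j - 1.
wp_decompose <- function(x, levels, flt) {
  tree <- vector("list", levels + 1)
  tree[[1]] <- list(x)
  for (j in seq_len(levels)) {
    prev <- tree[[j]]
    cur <- vector("list", 2 * length(prev))
    for (p in seq_along(prev)) {
      ad <- wp_analyze(prev[[p]], flt)
      cur[[2 * p - 1]] <- ad$a
      cur[[2 * p]] <- ad$d
    }
    tree[[j + 1]] <- cur
  }
  tree
}

# SURE-entropy additive cost of a coefficient vector
sure_cost <- function(s) {
  n <- length(s)
  t2 <- 2 * log(n)
  n - 2 * sum(s^2 <= t2) + sum(pmin(s^2, t2))
}

# Coifman-Wickerhauser best basis: bottom-up; ties kept at the parent
# (shallower node). The root is never a basis leaf (at least one split is
# retained so that detail coefficients exist to threshold). Returns logical
# "keep" per node, TRUE = node is a leaf of the chosen basis.
wp_best_basis <- function(tree) {
  levels <- length(tree) - 1
  cost <- lapply(tree, function(lv) vapply(lv, sure_cost, numeric(1)))
  keep <- lapply(tree, function(lv) rep(FALSE, length(lv)))
  best <- cost[[levels + 1]]
  keep[[levels + 1]] <- rep(TRUE, length(best))
  for (j in rev(seq_len(levels))) {     # j indexes parent level j-1 (1-based j)
    if (j == 1 && levels >= 1) break    # never merge into the root
    nb <- numeric(length(tree[[j]]))
    for (p in seq_along(tree[[j]])) {
      child_sum <- best[2 * p - 1] + best[2 * p]
      if (cost[[j]][p] <= child_sum) {  # tie -> shallower
        nb[p] <- cost[[j]][p]
        keep[[j]][p] <- TRUE
        # prune descendants
        keep <- wp_prune(keep, j, p)
      } else {
        nb[p] <- child_sum
      }
    }
    best <- nb
  }
  keep
}

wp_prune <- function(keep, j, p) {
  levels <- length(keep)
  lo <- p; hi <- p
  jj <- j
  while (jj < levels) {
    lo <- 2 * lo - 1; hi <- 2 * hi
    jj <- jj + 1
    keep[[jj]][lo:hi] <- FALSE
  }
  keep
}

# Reconstruct the root signal from a (possibly modified) tree restricted to the
# basis leaves in `keep`.
wp_reconstruct <- function(tree, keep, flt) {
  levels <- length(tree) - 1
  acc <- tree
  for (j in rev(seq_len(levels))) {
    for (p in seq_along(acc[[j]])) {
      if (!keep[[j]][p]) {
        acc[[j]][[p]] <- wp_synthesize(acc[[j + 1]][[2 * p - 1]],
                                       acc[[j + 1]][[2 * p]], flt)
      }
    }
    keep[[j]] <- rep(TRUE, length(keep[[j]]))  # now materialized
  }
  acc[[1]][[1]]
}

soft_threshold <- function(s, t) sign(s) * pmax(abs(s) - t, 0)
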