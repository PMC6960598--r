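#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: all randomness in the package flows from one
# integer seed; per-subject / per-record / per-stage streams are derived with a
# small multiplicative hash kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ks) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# trapezoidal integral on a uniform grid with spacing dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
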