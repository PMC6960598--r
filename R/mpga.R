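#' Multiple-population GA configuration
#'
#' Control parameters of the multiple-population genetic algorithm: several
#' populations evolve in parallel, each drawing its own crossover and mutation
#' probability from the configured ranges at initialization; populations are
#' coupled once per generation by a unidirectional ring immigration operator
#' (the best individual of population i replaces the worst of population
#' i+1), and an artificial-selection operator archives the best individual of
#' every population each generation. The run terminates when the overall best
#' individual has persisted for `min_preserve_generations` generations (or at
#' the `max_generations` safety cap).
#'
#' @param n_populations Number of co-evolving populations (default 5).
#' @param pop_size Individuals per population (default 20).
#' @param bits_per_variable Binary-code length per real variable (default 10).
#' @param var_range Length-2 numeric `(low, high)` decoding range
#'   (default `c(-0.5, 0.8)`).
#' @param pc_range Crossover-probability range (default `c(0.7, 0.9)`).
#' @param pm_range Mutation-probability range (default `c(0.001, 0.05)`).
#' @param min_preserve_generations Termination criterion (default 3).
#' @param max_generations Safety cap (default 200).
#' @param coding Chromosome bit coding: `"gray"` (default; adjacent
#'   quantization levels differ by one bit, so mutation performs local
#'   refinement without Hamming cliffs) or `"binary"` (plain positional code).
#' @param migration_interval Generations between ring-immigration events
#'   (default 1: once per generation).
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(n_populations = 5, pop_size = 20, bits_per_variable = 10,
                      var_range = c(-0.5, 0.8), pc_range = c(0.7, 0.9),
                      pm_range = c(0.001, 0.05), min_preserve_generations = 3,
                      max_generations = 200, coding = c("gray", "binary"),
                      migration_interval = 1, seed = 1) {
  coding <- match.arg(coding)
  stopifnot(n_populations >= 1, pop_size >= 2, bits_per_variable >= 1,
            var_range[1] < var_range[2],
            all(pc_range >= 0), all(pc_range < 1),
            all(pm_range >= 0), all(pm_range < 1),
            min_preserve_generations >= 1, max_generations >= 1,
            migration_interval >= 1)
  structure(list(n_populations = as.integer(n_populations),
                 pop_size = as.integer(pop_size),
                 bits_per_variable = as.integer(bits_per_variable),
                 var_range = var_range, pc_range = pc_range,
                 pm_range = pm_range,
                 min_preserve_generations = as.integer(min_preserve_generations),
                 max_generations = as.integer(max_generations),
                 coding = coding,
                 migration_interval = as.integer(migration_interval),
                 seed = seed),
            class = "ga_config")
}

#' Binary encoding / decoding of real vectors
#'
#' Linear fixed-point code: a block of `bits_per_variable` bits encodes an
#' integer level that maps to `low + level * (high - low) / (2^b - 1)`;
#' encoding rounds to the nearest code, so the decode-encode round trip errs
#' by at most half a quantization step. With `cfg$coding = "gray"` (the
#' default) the bit pattern is the reflected Gray code of the level; with
#' `"binary"` it is the plain positional code.
#'
#' @param x Real vector within `cfg$var_range`.
#' @param cfg A [ga_config()].
#' @return `ga_encode`: integer 0/1 vector of length
#'   `length(x) * bits_per_variable`; `ga_decode`: the decoded real vector.
#' @export
ga_encode <- function(x, cfg) {
  lo <- cfg$var_range[1]; hi <- cfg$var_range[2]; b <- cfg$bits_per_variable
  if (any(x < lo | x > hi)) stop("value outside var_range")
  ints <- round((x - lo) / (hi - lo) * (2^b - 1))
  bits <- integer(0)
  for (v in ints) {
    bin <- as.integer(intToBits(v)[seq_len(b)] != 0)[b:1]   # MSB first
    if (identical(cfg$coding %||% "gray", "gray")) {
      bin <- c(bin[1], (bin[-1] + bin[-b]) %% 2)
    }
    bits <- c(bits, bin)
  }
  as.integer(bits)
}

#' @rdname ga_encode
#' @param bits Integer 0/1 vector, length a multiple of `bits_per_variable`.
#' @export
ga_decode <- function(bits, cfg) {
  lo <- cfg$var_range[1]; hi <- cfg$var_range[2]; b <- cfg$bits_per_variable
  nv <- length(bits) / b
  stopifnot(nv == floor(nv))
  M <- matrix(bits, nrow = b)
  if (identical(cfg$coding %||% "gray", "gray")) {
    M <- apply(M, 2, function(col) cumsum(col) %% 2)
    M <- matrix(M, nrow = b)
  }
  ints <- as.numeric(2^((b - 1):0) %*% M)
  lo + ints * (hi - lo) / (2^b - 1)
}

# linear-ranking fitness (selective pressure 2) + stochastic universal
# sampling; fitness is minimized, so the best (lowest) objective gets the
# highest rank value
sus_select <- function(obj, n_pick) {
  n <- length(obj)
  # rank 1 = worst ... n = best; linear ranking with pressure sp = 2
  r <- rank(-obj, ties.method = "first")
  fit <- 2 * (r - 1) / (n - 1)            # in [0, 2], mean 1
  cum <- cumsum(fit)
  total <- cum[n]
  ptr <- stats::runif(1, 0, total / n_pick) + (seq_len(n_pick) - 1) * total / n_pick
  idx <- findInterval(ptr, cum) + 1L
  idx[sample.int(n_pick)]                  # shuffle mating order
}

#' Multiple-population genetic algorithm
#'
#' Minimizes `objective` over `[low, high]^n_variables` using binary-coded
#' chromosomes. Per generation and population: linear-ranking fitness with
#' stochastic universal sampling, single-point crossover, bit-flip mutation,
#' elitist reinsertion of the population's previous best, ring immigration,
#' and artificial selection into an elite archive. An objective returning
#' `NaN` is treated as `+Inf` with a warning.
#'
#' @param objective Function: real vector -> scalar objective (minimized).
#' @param n_variables Number of decision variables.
#' @param cfg A [ga_config()].
#' @param init Optional list of real vectors injected into the initial
#'   populations (encoded to the nearest code); elitism then guarantees the
#'   result is never worse than the best injected point.
#' @return List: `best` (decoded best vector), `fitness` (its objective),
#'   `history` (data.frame: generation, population, best, mean),
#'   `generations` (count run).
#' @export
mpga_evolve <- function(objective, n_variables, cfg = ga_config(), init = NULL) {
  b <- cfg$bits_per_variable
  nbits <- n_variables * b
  nan_warned <- FALSE
  eval_obj <- function(bits) {
    v <- objective(ga_decode(bits, cfg))
    if (is.na(v) || is.nan(v)) {
      if (!nan_warned) {
        warning("objective returned NaN; treated as +Inf")
        nan_warned <<- TRUE
      }
      v <- Inf
    }
    v
  }
  with_seed(derive_seed(cfg$seed, 77L), {
    pops <- lapply(seq_len(cfg$n_populations), function(i) {
      list(chrom = matrix(sample(0:1, cfg$pop_size * nbits, replace = TRUE),
                          nrow = cfg$pop_size),
           pc = stats::runif(1, cfg$pc_range[1], cfg$pc_range[2]),
           pm = stats::runif(1, cfg$pm_range[1], cfg$pm_range[2]))
    })
    if (!is.null(init)) {
      for (k in seq_along(init)) {
        p <- (k - 1) %% cfg$n_populations + 1
        row <- (k - 1) %/% cfg$n_populations + 1
        if (row <= cfg$pop_size)
          pops[[p]]$chrom[row, ] <- ga_encode(init[[k]], cfg)
      }
    }
    for (i in seq_along(pops)) {
      pops[[i]]$obj <- apply(pops[[i]]$chrom, 1, eval_obj)
    }

    history <- list()
    overall_best <- NULL; overall_fit <- Inf
    pop_best_fit <- rep(Inf, cfg$n_populations)
    preserved <- rep(0L, cfg$n_populations)
    gen <- 0L
    repeat {
      gen <- gen + 1L
      for (i in seq_along(pops)) {
        pop <- pops[[i]]
        prev_best_i <- which.min(pop$obj)
        prev_best <- pop$chrom[prev_best_i, ]
        prev_best_obj <- pop$obj[prev_best_i]
        parents <- sus_select(pop$obj, cfg$pop_size)
        chrom <- pop$chrom[parents, , drop = FALSE]
        # single-point crossover on consecutive pairs
        for (k in seq(1, cfg$pop_size - 1, by = 2)) {
          if (stats::runif(1) < pop$pc) {
            cut <- sample.int(nbits - 1, 1)
            tail1 <- chrom[k, (cut + 1):nbits]
            chrom[k, (cut + 1):nbits] <- chrom[k + 1, (cut + 1):nbits]
            chrom[k + 1, (cut + 1):nbits] <- tail1
          }
        }
        # bit-flip mutation
        flip <- matrix(stats::runif(cfg$pop_size * nbits) < pop$pm,
                       nrow = cfg$pop_size)
        chrom[flip] <- 1L - chrom[flip]
        obj <- apply(chrom, 1, eval_obj)
        # elitist reinsertion: previous best replaces the worst offspring
        # unless the offspring already contain something at least as good
        if (min(obj) > prev_best_obj) {
          worst <- which.max(obj)
          chrom[worst, ] <- prev_best
          obj[worst] <- prev_best_obj
        }
        pops[[i]]$chrom <- chrom
        pops[[i]]$obj <- obj
      }
      # immigration: best of population i replaces worst of population i+1
      # (unidirectional ring, every migration_interval generations)
      if (cfg$n_populations > 1 && gen %% (cfg$migration_interval %||% 1L) == 0) {
        bests <- lapply(pops, function(p) {
          j <- which.min(p$obj); list(chrom = p$chrom[j, ], obj = p$obj[j])
        })
        for (i in seq_along(pops)) {
          dst <- i %% cfg$n_populations + 1L
          worst <- which.max(pops[[dst]]$obj)
          pops[[dst]]$chrom[worst, ] <- bests[[i]]$chrom
          pops[[dst]]$obj[worst] <- bests[[i]]$obj
        }
      }
      # artificial selection into the elite archive; each population keeps
      # its own preservation counter, and the run stops only when the least
      # preserved count reaches the threshold (all populations stalled)
      for (i in seq_along(pops)) {
        j <- which.min(pops[[i]]$obj)
        if (pops[[i]]$obj[j] < pop_best_fit[i]) {
          pop_best_fit[i] <- pops[[i]]$obj[j]
          preserved[i] <- 1L
        } else {
          preserved[i] <- preserved[i] + 1L
        }
        if (pops[[i]]$obj[j] < overall_fit) {
          overall_fit <- pops[[i]]$obj[j]
          overall_best <- pops[[i]]$chrom[j, ]
        }
        history[[length(history) + 1]] <- data.frame(
          generation = gen, population = i,
          best = min(pops[[i]]$obj), mean = mean(pops[[i]]$obj))
      }
      if (min(preserved) >= cfg$min_preserve_generations ||
          gen >= cfg$max_generations)
        break
    }
    list(best = ga_decode(overall_best, cfg), fitness = overall_fit,
         history = do.call(rbind, history), generations = gen)
  })
}

#' MPGA-optimized network initialization
#'
#' Uses the multiple-population GA to determine the initial weights and
#' thresholds of the blood-pressure network: each chromosome encodes the full
#' flat parameter vector; the fitness of a chromosome is the training-set RMSE
#' of the decoded network. The best decoded parameter vector then seeds
#' Levenberg-Marquardt fine-tuning (disable with `finetune = FALSE` to obtain
#' the raw GA-initialized network).
#'
#' @param X Training feature matrix.
#' @param y Training targets, mmHg.
#' @param n_hidden Hidden-layer size.
#' @param ga_cfg A [ga_config()].
#' @param train_cfg A [train_config()] for the fine-tuning stage.
#' @param finetune Logical, default `TRUE`.
#' @return A `bp_network` with attribute `ga` (the [mpga_evolve()] result).
#' @export
optimize_network <- function(X, y, n_hidden, ga_cfg = ga_config(),
                             train_cfg = train_config(), finetune = TRUE) {
  X <- as.matrix(X)
  proto <- new_network(X, y, n_hidden)
  Xs <- scale_x(X, proto$scaling)
  ys <- scale_y(y, proto$scaling)
  sc <- proto$scaling
  obj <- function(theta) {
    yh <- forward_scaled(theta, proto$topo, Xs)$yhat
    rmse(descale_y(ys, sc), descale_y(yh, sc))
  }
  ga <- mpga_evolve(obj, length(proto$theta), ga_cfg)
  net <- if (finetune) {
    train_lm(X, y, n_hidden, train_cfg, theta0 = ga$best)
  } else {
    set_params(proto, ga$best)
  }
  attr(net, "ga") <- ga
  net
}

#' Write an MPGA evolution history as CSV
#' @param ga Result of [mpga_evolve()] (or the `ga` attribute of an optimized
#'   network).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ga_history <- function(ga, path) {
  utils::write.csv(ga$history, path, row.names = FALSE)
  invisible(path)
}
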