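#' Default concentration bounds for the nine medium components
#'
#' The search box for the optimizer, in g/L: glucose 0--40, maltose 0--40,
#' mannitol 0--40, corn powder 0--100, yeast 0--100, cupric sulfate
#' 0--0.5, sodium chloride 0--10, ferrous sulfate 0--0.5, vitamin B1
#' 0--0.1. Note that several training-table columns (cupric sulfate,
#' ferrous sulfate, vitamin B1) lie far outside this box — a unit/column
#' inconsistency inherited from the source data — so the box cannot be
#' assumed to contain the training data in those dimensions. The optional
#' `envelope` mode widens each upper bound to the training-data column
#' maximum where that exceeds the stated bound.
#'
#' @param envelope Logical; widen upper bounds to cover `data` (default
#'   `FALSE`).
#' @param data Training data.frame used when `envelope = TRUE`.
#' @return A 9 x 2 matrix with columns `lower`, `upper`, rownames the
#'   canonical component names.
#' @export
default_bounds <- function(envelope = FALSE, data = NULL) {
  b <- cbind(lower = rep(0, 9),
             upper = c(40, 40, 40, 100, 100, 0.5, 10, 0.5, 0.1))
  rownames(b) <- medium_components()
  if (envelope) {
    if (is.null(data)) stop("envelope = TRUE requires `data`")
    data <- validate_dataset(data)
    b[, "upper"] <- pmax(b[, "upper"],
                         apply(as.matrix(data[medium_components()]), 2, max))
  }
  b
}

#' Genetic-algorithm configuration
#'
#' Hyperparameters of the real-coded GA: population size 300, arithmetic
#' crossover with probability 0.8 (midpoint of the conventional 0.6--1
#' range), per-gene uniform-reset mutation with probability 0.05 (midpoint
#' of 0.01--0.1), 200 generations (from the tried presets 100/150/200/500),
#' one elite copied unchanged per generation, and the component bounds box.
#'
#' @param population_size Number of individuals (>= 2; default 300).
#' @param generations Number of generations (default 200; 0 evaluates the
#'   initial population only).
#' @param crossover_prob Per-mating probability of arithmetic crossover.
#' @param mutation_prob Per-gene probability of uniform-reset mutation.
#' @param bounds 9 x 2 bounds matrix as from [default_bounds()].
#' @param elitism Number of top individuals copied unchanged (default 1).
#' @param seed Integer seed for the whole GA run.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 300L, generations = 200L,
                      crossover_prob = 0.8, mutation_prob = 0.05,
                      bounds = default_bounds(), elitism = 1L, seed = NULL) {
  if (population_size < 2L) stop("population_size must be >= 2")
  if (generations < 0L) stop("generations must be >= 0")
  if (crossover_prob < 0 || crossover_prob > 1) stop("crossover_prob must be in [0, 1]")
  if (mutation_prob < 0 || mutation_prob > 1) stop("mutation_prob must be in [0, 1]")
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || nrow(bounds) != 9L) stop("bounds must be a 9 x 2 matrix")
  if (any(bounds[, 1] > bounds[, 2])) stop("lower bound exceeds upper bound for gene(s): ",
                                           paste(which(bounds[, 1] > bounds[, 2]), collapse = ", "))
  if (elitism < 0L || elitism >= population_size) stop("elitism must be in [0, population_size)")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 bounds = bounds, elitism = as.integer(elitism), seed = seed),
            class = "ga_config")
}

.random_population <- function(config) {
  n <- config$population_size
  b <- config$bounds
  pop <- matrix(0, n, nrow(b), dimnames = list(NULL, rownames(b)))
  for (j in seq_len(nrow(b))) pop[, j] <- stats::runif(n, b[j, 1], b[j, 2])
  pop
}

#' Initialize a random GA population
#'
#' Draws `population_size` real-coded chromosomes, each gene uniform over
#' its bound interval; a degenerate interval (lower == upper) yields a
#' constant gene.
#'
#' @param config A [ga_config()]; its `seed`, when set, makes the draw
#'   reproducible.
#' @return An `n x 9` matrix, one chromosome per row.
#' @export
init_population <- function(config) {
  if (!inherits(config, "ga_config")) stop("`config` must be a ga_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  .random_population(config)
}

#' Roulette-wheel selection probabilities
#'
#' Fitness-proportional selection: `p_i = f_i / sum(f)`. All fitness
#' values must be non-negative (shift first if the objective can go
#' negative); when every fitness is exactly zero the wheel is undefined
#' and a uniform distribution is returned with a warning.
#'
#' @param fitnesses Numeric vector of non-negative fitness values.
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' roulette_probabilities(c(2, 1, 1))  # 0.5, 0.25, 0.25
roulette_probabilities <- function(fitnesses) {
  if (length(fitnesses) == 0L) stop("empty fitness vector")
  if (any(!is.finite(fitnesses))) stop("fitness values must be finite")
  if (any(fitnesses < 0)) stop("negative fitness; shift the objective to >= 0 before the wheel")
  s <- sum(fitnesses)
  if (s == 0) {
    warning("all fitness values are zero; falling back to uniform selection")
    return(rep(1 / length(fitnesses), length(fitnesses)))
  }
  fitnesses / s
}

#' Draw a parent pair from the roulette wheel
#'
#' Two independent draws (with replacement) from the categorical
#' distribution defined by the selection probabilities.
#'
#' @param population Chromosome matrix, one individual per row.
#' @param probabilities Vector from [roulette_probabilities()].
#' @return A `2 x 9` matrix of the selected parents, with the selected row
#'   indices attached as attribute `"indices"`.
#' @export
select_parents <- function(population, probabilities) {
  if (nrow(population) != length(probabilities)) {
    stop("probabilities do not match the population size")
  }
  idx <- sample.int(nrow(population), 2L, replace = TRUE, prob = probabilities)
  out <- population[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Whole-arithmetic (blend) crossover
#'
#' With probability `crossover_prob`, draws a single mixing weight
#' `lambda ~ U(0, 1)` and returns the convex combinations
#' `lambda a + (1 - lambda) b` and `(1 - lambda) a + lambda b`; otherwise
#' the children are copies of the parents. Convexity keeps offspring
#' inside the bounds box automatically.
#'
#' @param a,b Parent chromosomes (length-9 numeric vectors).
#' @param config A [ga_config()].
#' @return A `2 x 9` matrix of children.
#' @export
ga_crossover <- function(a, b, config) {
  if (stats::runif(1) < config$crossover_prob) {
    lam <- stats::runif(1)
    rbind(lam * a + (1 - lam) * b, (1 - lam) * a + lam * b)
  } else {
    rbind(a, b)
  }
}

#' Uniform-reset mutation
#'
#' Each gene independently, with probability `mutation_prob`, is resampled
#' uniformly within its bound interval; the result always satisfies the
#' bounds.
#'
#' @param ind Chromosome (length-9 numeric vector).
#' @param config A [ga_config()].
#' @return Mutated chromosome.
#' @export
ga_mutate <- function(ind, config) {
  hit <- stats::runif(length(ind)) < config$mutation_prob
  if (any(hit)) {
    b <- config$bounds
    ind[hit] <- b[hit, 1] + stats::runif(sum(hit)) * (b[hit, 2] - b[hit, 1])
  }
  ind
}

#' Run the real-coded genetic algorithm
#'
#' Generational GA over the bounds box: evaluate fitness, copy the
#' `elitism` best unchanged, then fill the next generation by
#' roulette-wheel parent selection, arithmetic crossover and uniform-reset
#' mutation. Because the surrogate objective can be negative, fitness
#' values are shifted by the generation minimum (with a small positive
#' floor) before the wheel; the returned fitness values are the raw
#' objective. The best individual ever seen is returned, so with
#' `elitism >= 1` the per-generation best is non-decreasing.
#'
#' @param fitness_fn Objective to maximize. Called with an `n x 9` matrix
#'   of chromosomes and must return a length-`n` numeric vector (use
#'   [Vectorize()]-style wrappers for scalar objectives, or pass
#'   `vectorized = FALSE`).
#' @param config A [ga_config()].
#' @param vectorized Logical; if `FALSE`, `fitness_fn` is treated as a
#'   chromosome-to-scalar function and applied row-wise.
#' @return Object of class `ga_result`: `best` (list with `genes` and
#'   `fitness`), `fitness_history` (data.frame: generation, best, mean),
#'   `generations_run`, `seed`, `config`.
#' @export
#' @examples
#' cfg <- ga_config(population_size = 40, generations = 30, seed = 1)
#' ctr <- rowMeans(cfg$bounds)
#' res <- run_ga(function(m) -colSums((t(m) - ctr)^2), cfg)
#' res$best$fitness
run_ga <- function(fitness_fn, config = ga_config(), vectorized = TRUE) {
  if (!inherits(config, "ga_config")) stop("`config` must be a ga_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  evalfit <- if (vectorized) fitness_fn else function(m) apply(m, 1, fitness_fn)
  b <- config$bounds
  pop <- .random_population(config)
  n <- config$population_size
  history <- data.frame(generation = integer(0), best = numeric(0), mean = numeric(0))
  best_ever <- NULL

  score <- function(pop) {
    f <- evalfit(pop)
    if (length(f) != nrow(pop)) stop("fitness_fn must return one value per chromosome")
    bad <- which(!is.finite(f))
    if (length(bad)) {
      stop("non-finite fitness for chromosome [",
           paste(signif(pop[bad[1], ], 6), collapse = ", "), "]")
    }
    f
  }

  fit <- score(pop)
  for (gen in 0:config$generations) {
    if (gen > 0L) {
      w <- pmax(fit - min(fit), 1e-12)           # shift to >= 0, small floor
      probs <- w / sum(w)
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
      newpop <- pop[elite_idx, , drop = FALSE]
      while (nrow(newpop) < n) {
        idx <- sample.int(n, 2L, replace = TRUE, prob = probs)
        kids <- ga_crossover(pop[idx[1], ], pop[idx[2], ], config)
        kids[1, ] <- ga_mutate(kids[1, ], config)
        kids[2, ] <- ga_mutate(kids[2, ], config)
        newpop <- rbind(newpop, kids)
      }
      pop <- newpop[seq_len(n), , drop = FALSE]
      fit <- score(pop)
    }
    gbest <- which.max(fit)
    if (is.null(best_ever) || fit[gbest] > best_ever$fitness) {
      best_ever <- list(genes = stats::setNames(pop[gbest, ], rownames(b)),
                        fitness = fit[gbest])
    }
    history <- rbind(history, data.frame(generation = gen,
                                         best = best_ever$fitness,
                                         mean = mean(fit)))
  }
  structure(list(best = best_ever, fitness_history = history,
                 generations_run = config$generations, seed = config$seed,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: %d generations, population %d, seed %s\n",
              x$generations_run, x$config$population_size,
              if (is.null(x$seed)) "unset" else x$seed))
  cat(sprintf("  best fitness: %.6g\n", x$best$fitness))
  cat("  best chromosome (g/L):\n")
  print(round(x$best$genes, 4))
  invisible(x)
}

#' @export
plot.ga_result <- function(x, ...) {
  h <- x$fitness_history
  graphics::plot(h$generation, h$best, type = "l", xlab = "generation",
                 ylab = "fitness", main = "GA convergence",
                 ylim = range(c(h$best, h$mean)), ...)
  graphics::lines(h$generation, h$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best-so-far", "population mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
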