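test_that("roulette probabilities follow fitness proportions", {
  expect_equal(roulette_probabilities(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(roulette_probabilities(rep(3, 6)), rep(1 / 6, 6))
  expect_equal(roulette_probabilities(c(0, 3)), c(0, 1))
  expect_warning(p <- roulette_probabilities(c(0, 0, 0)), "uniform")
  expect_equal(p, rep(1 / 3, 3))
  expect_error(roulette_probabilities(c(-1, 2)), "negative")
  expect_error(roulette_probabilities(c(1, NA)), "finite")
  set.seed(8)
  f <- runif(20)
  expect_lt(abs(sum(roulette_probabilities(f)) - 1), 1e-12)
})

test_that("selection frequencies converge to the wheel probabilities", {
  pop <- matrix(runif(27), 3, 9)
  p <- roulette_probabilities(c(2, 1, 1))
  set.seed(42)
  n_pairs <- 20000
  idx <- unlist(lapply(seq_len(n_pairs), function(i) {
    attr(select_parents(pop, p), "indices")
  }))
  n <- length(idx)
  freq <- tabulate(idx, 3) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("a degenerate wheel always selects the same parent", {
  pop <- matrix(seq_len(27), 3, 9)
  for (i in 1:20) {
    expect_equal(attr(select_parents(pop, c(1, 0, 0)), "indices"), c(1L, 1L))
  }
})

test_that("arithmetic crossover is convex and honours its probability", {
  cfg <- ga_config(seed = 1)
  b <- cfg$bounds
  set.seed(2)
  a <- b[, 1] + runif(9) * (b[, 2] - b[, 1])
  d <- b[, 1] + runif(9) * (b[, 2] - b[, 1])
  cfg0 <- cfg; cfg0$crossover_prob <- 0
  kids <- ga_crossover(a, d, cfg0)
  expect_equal(kids[1, ], a)
  expect_equal(kids[2, ], d)
  kids <- ga_crossover(a, a, cfg)     # identical parents: fixed point
  expect_equal(kids[1, ], a)
  expect_equal(kids[2, ], a)
  for (i in 1:50) {
    kids <- ga_crossover(a, d, cfg)
    expect_true(all(kids >= rep(b[, 1], each = 2) - 1e-12))
    expect_true(all(kids <= rep(b[, 2], each = 2) + 1e-12))
    expect_equal(colSums(kids), a + d)  # blend preserves the parental sum
  }
})

test_that("uniform-reset mutation stays in bounds at the configured rate", {
  cfg <- ga_config(seed = 1)
  ind <- rowMeans(cfg$bounds)
  cfg0 <- cfg; cfg0$mutation_prob <- 0
  expect_identical(ga_mutate(ind, cfg0), ind)
  cfg1 <- ga_config(bounds = cbind(rep(2, 9), rep(2, 9)), mutation_prob = 1)
  expect_equal(unname(ga_mutate(rep(2, 9), cfg1)), rep(2, 9))
  set.seed(9)
  trials <- 2000
  hits <- 0
  for (i in seq_len(trials)) {
    m <- ga_mutate(ind, cfg)
    expect_true(all(m >= cfg$bounds[, 1] & m <= cfg$bounds[, 2]))
    hits <- hits + sum(m != ind)
  }
  p <- cfg$mutation_prob
  n <- trials * 9
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the GA recovers a known box-interior optimum", {
  cfg <- ga_config(population_size = 50, generations = 19, seed = 5)
  ctr <- rowMeans(cfg$bounds)
  w <- cfg$bounds[, 2] - cfg$bounds[, 1]
  fitness <- function(m) -colSums(((t(m) - ctr) / w)^2)
  res <- run_ga(fitness, cfg)
  expect_true(all(abs(res$best$genes - ctr) / w <= 0.05))
  # random-search baseline with the same evaluation budget
  budget <- cfg$population_size * (cfg$generations + 1)
  set.seed(5)
  rs <- matrix(runif(budget * 9), budget, 9)
  rs <- sweep(sweep(rs, 2, w, "*"), 2, cfg$bounds[, 1], "+")
  expect_gte(res$best$fitness, max(fitness(rs)))
})

test_that("every chromosome ever evaluated satisfies the bounds", {
  cfg <- ga_config(population_size = 30, generations = 15, seed = 3)
  seen <- new.env()
  seen$ok <- TRUE
  fitness <- function(m) {
    inb <- m >= rep(cfg$bounds[, 1], each = nrow(m)) &
      m <= rep(cfg$bounds[, 2], each = nrow(m))
    if (!all(inb)) seen$ok <- FALSE
    rowSums(m)
  }
  run_ga(fitness, cfg)
  expect_true(seen$ok)
})

test_that("elitism makes the best fitness non-decreasing", {
  cfg <- ga_config(population_size = 40, generations = 25, seed = 6, elitism = 1)
  res <- run_ga(function(m) -colSums((t(m) - 5)^2), cfg)
  expect_true(all(diff(res$fitness_history$best) >= 0))
})

test_that("GA runs are reproducible and degenerate cases behave", {
  cfg <- ga_config(population_size = 20, generations = 10, seed = 12)
  f <- function(m) rowSums(m)
  a <- run_ga(f, cfg)
  b <- run_ga(f, cfg)
  expect_identical(a$best, b$best)
  expect_identical(a$fitness_history, b$fitness_history)

  cfg0 <- ga_config(population_size = 20, generations = 0, seed = 12)
  r0 <- run_ga(f, cfg0)
  expect_equal(nrow(r0$fitness_history), 1)
  p0 <- init_population(cfg0)
  expect_equal(r0$best$fitness, max(f(p0)))

  rc <- run_ga(function(m) rep(7, nrow(m)),
               ga_config(population_size = 10, generations = 3, seed = 1))
  expect_equal(rc$best$fitness, 7)

  expect_error(run_ga(function(m) rep(NaN, nrow(m)), cfg0), "non-finite fitness")
  # scalar (non-vectorized) objectives are applied row-wise
  rs <- run_ga(function(g) sum(g), cfg, vectorized = FALSE)
  expect_identical(rs$best, a$best)
})

test_that("population initialization respects bounds, seeds and degeneracy", {
  cfg <- ga_config(population_size = 25, seed = 4)
  p1 <- init_population(cfg)
  p2 <- init_population(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1 >= rep(cfg$bounds[, 1], each = 25)))
  expect_true(all(p1 <= rep(cfg$bounds[, 2], each = 25)))
  bdeg <- default_bounds(); bdeg["glucose", ] <- c(3, 3)
  pd <- init_population(ga_config(population_size = 10, bounds = bdeg, seed = 1))
  expect_true(all(pd[, "glucose"] == 3))
})

test_that("configuration validation and envelope bounds work", {
  expect_error(ga_config(population_size = 1), "population_size")
  bad <- default_bounds(); bad[1, ] <- c(5, 1)
  expect_error(ga_config(bounds = bad), "lower bound exceeds")
  expect_error(ga_config(elitism = 300), "elitism")
  env <- default_bounds(envelope = TRUE, data = table1_fixture())
  expect_equal(unname(env["ferrous_sulfate", "upper"]), 25)  # widened to data max
  expect_equal(unname(env["glucose", "upper"]), 40)          # stated bound kept
  expect_error(default_bounds(envelope = TRUE), "requires")
})
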