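test_that("init_population honors length mode, distinctness and seed", {
  cfg <- ga_config(population_size = 100, length_mode = length_fixed(2),
                   rng_seed = 3)
  pop <- init_population(cfg, 176)
  expect_length(pop$individuals, 100)
  for (g in pop$individuals) {
    expect_length(g, 2)
    expect_equal(anyDuplicated(g), 0)
    expect_true(all(g >= 1 & g <= 176))
  }
  cfgv <- ga_config(population_size = 50,
                    length_mode = length_variable(1, 5), rng_seed = 4)
  popv <- init_population(cfgv, 10)
  lens <- lengths(popv$individuals)
  expect_true(all(lens >= 1 & lens <= 5))
  for (g in popv$individuals) expect_equal(anyDuplicated(g), 0)
  # determinism
  expect_identical(init_population(cfg, 176)$individuals,
                   init_population(cfg, 176)$individuals)
  expect_error(init_population(
    ga_config(length_mode = length_fixed(11)), 10), "exceeds V")
})

test_that("roulette selection follows score proportions", {
  pop <- structure(list(individuals = list(3L, 7L), generation_index = 0L),
                   class = "ga_population")
  st <- rng_stream(99)
  # degenerate wheel (1, 0): always the first individual
  for (i in 1:20)
    expect_identical(roulette_select(pop, c(1, 0), st), pop$individuals[[1]])
  expect_error(roulette_select(pop, c(-1, 2), st), "negative")
  # equal scores: empirical frequencies uniform within binomial tolerance
  st2 <- rng_stream(100)
  picks <- vapply(1:4000, function(i)
    identical(roulette_select(pop, c(1, 1), st2), pop$individuals[[1]]),
    logical(1))
  expect_equal(mean(picks), 0.5, tolerance = 0.05)
  # all-zero scores fall back to uniform, not an error
  expect_silent(roulette_select(pop, c(0, 0), st2))
})

test_that("uniform crossover mixes positions and preserves structure", {
  st <- rng_stream(7)
  # identical parents reproduce themselves
  ch <- uniform_crossover(c(3L, 9L), c(3L, 9L), 20, st)
  expect_identical(ch[[1]], c(3L, 9L))
  expect_identical(ch[[2]], c(3L, 9L))
  # children of disjoint parents are subsets of the union, pre-repair
  for (i in 1:50) {
    ch <- uniform_crossover(c(1L, 2L), c(3L, 4L), 4, st)
    for (child in ch) {
      expect_length(child, 2)
      expect_equal(anyDuplicated(child), 0)
      expect_true(all(child %in% 1:4))
    }
  }
  # variable-length parents keep their lengths; tail goes to same-length child
  ch <- uniform_crossover(c(1L, 2L, 5L, 7L), c(8L, 9L), 10, st)
  expect_length(ch[[1]], 4)
  expect_length(ch[[2]], 2)
  expect_equal(ch[[1]][4], 7L) # tail beyond the shorter parent is inherited
})

test_that("uniform mutation respects rate, pool and distinctness", {
  st <- rng_stream(8)
  expect_identical(uniform_mutate(c(2L, 6L), 0, 10, st), c(2L, 6L))
  # rate 1 on [5]: replacement pool excludes the current gene
  for (i in 1:25) expect_false(uniform_mutate(5L, 1, 10, st) == 5L)
  # saturated individual cannot mutate
  expect_identical(uniform_mutate(1:5, 1, 5, st), 1:5)
  # distinctness preserved under heavy mutation
  for (i in 1:50) {
    g <- uniform_mutate(c(1L, 2L, 3L), 0.8, 6, st)
    expect_equal(anyDuplicated(g), 0)
    expect_length(g, 3)
  }
})

test_that("positional convergence detection", {
  mk <- function(inds) structure(list(individuals = inds,
                                      generation_index = 0L),
                                 class = "ga_population")
  same <- mk(rep(list(c(4L, 9L)), 10))
  expect_true(check_convergence(same, 0.95))
  split <- mk(c(rep(list(c(1L, 9L)), 5), rep(list(c(2L, 9L)), 5)))
  expect_false(check_convergence(split, 0.95))
  mostly <- mk(c(rep(list(c(4L, 9L)), 96), rep(list(c(1L, 2L)), 4)))
  expect_true(check_convergence(mostly, 0.95))
  varlen <- mk(list(c(1L, 2L), c(3L)))
  expect_false(check_convergence(varlen, 0.95))
})

test_that("evolve optimizes a trivial variable-length objective", {
  cfg <- ga_config(population_size = 30, max_generations = 15,
                   length_mode = length_variable(1, 6), rng_seed = 6)
  res <- evolve(cfg, 12, function(g) abs(length(g) - 3))
  expect_equal(res$best_individuals$fitness[1], 0)
  expect_s3_class(res, "ga_result")
})

test_that("evolve is bitwise repeatable and keeps its invariants", {
  cfg <- ga_config(population_size = 20, max_generations = 12,
                   length_mode = length_fixed(2), rng_seed = 11)
  # fitness wrapper asserting every evaluated individual is valid
  fit <- function(g) {
    expect_length(g, 2)
    expect_equal(anyDuplicated(g), 0)
    expect_true(all(g >= 1 & g <= 15))
    sum(g) / 30
  }
  r1 <- evolve(cfg, 15, fit)
  r2 <- evolve(cfg, 15, fit)
  expect_identical(r1$best_individuals, r2$best_individuals)
  expect_identical(r1$fitness_trace, r2$fitness_trace)
  expect_identical(r1$termination_reason, r2$termination_reason)
  # with elitism the best trace is monotone non-increasing
  expect_true(all(diff(r1$fitness_trace$best) <= 0))
  # minimal pair [1, 2] should be found on this trivial landscape
  expect_equal(r1$best_individuals$genes[1], "1,2")
})

test_that("evolve stops on stagnation and convergence", {
  cfg <- ga_config(population_size = 10, max_generations = 50,
                   length_mode = length_fixed(1), rng_seed = 12,
                   stagnation_window = 3)
  res <- evolve(cfg, 5, function(g) 1) # constant fitness never improves
  expect_equal(res$termination_reason, "stagnated")
  expect_lt(nrow(res$fitness_trace), 50)
  # strong selection with zero mutation converges positionally
  cfg2 <- ga_config(population_size = 20, max_generations = 50,
                    mutation_rate = 0, length_mode = length_fixed(1),
                    rng_seed = 13)
  res2 <- evolve(cfg2, 5, function(g) as.numeric(g))
  expect_true(res2$termination_reason %in% c("converged", "max_generations"))
  expect_equal(res2$best_individuals$genes[1], "1")
})

test_that("a failing fitness function aborts with the genes reported", {
  cfg <- ga_config(population_size = 5, max_generations = 3,
                   length_mode = length_fixed(2), rng_seed = 14)
  expect_error(evolve(cfg, 10, function(g) stop("boom")),
               "fitness evaluation failed for individual \\[")
})
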