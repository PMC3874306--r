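#' Fixed-length chromosome mode
#' @param L subset size every individual must have.
#' @return length-mode descriptor.
#' @export
length_fixed <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) config_error("length_fixed: L must be >= 1")
  structure(list(mode = "fixed", L = L), class = "ga_length_mode")
}

#' Variable-length chromosome mode
#' @param min,max inclusive bounds on individual length.
#' @return length-mode descriptor.
#' @export
length_variable <- function(min, max) {
  min <- as.integer(min); max <- as.integer(max)
  if (is.na(min) || is.na(max) || min < 1 || max < min)
    config_error("length_variable: need 1 <= min <= max")
  structure(list(mode = "variable", min = min, max = max),
            class = "ga_length_mode")
}

#' Genetic algorithm configuration
#'
#' Defaults reproduce the canonical simple-GA setup used for wavelength
#' selection: 100 individuals, 100 generations, wheel-roulette selection,
#' uniform crossover at rate 0.90, uniform mutation at rate 0.10,
#' generational replacement with single-individual elitism.
#'
#' @param population_size number of individuals (>= 2).
#' @param max_generations generation cap.
#' @param crossover_rate per-pair probability of applying crossover.
#' @param mutation_rate per-gene probability of mutation.
#' @param length_mode \code{\link{length_fixed}} or
#'   \code{\link{length_variable}}.
#' @param elitism keep the best-so-far individual by replacing the worst
#'   child each generation (gives a monotone best-fitness trace).
#' @param rng_seed master seed; named substreams (init, selection, crossover,
#'   mutation) are derived from it.
#' @param convergence_threshold positional convergence fraction: the run
#'   stops early when at every gene position at least this fraction of the
#'   population carries the same index (fixed-length mode only).
#' @param stagnation_window stop after this many generations without
#'   improvement greater than 1e-12; \code{NULL} (default) disables it.
#' @param selection,crossover,mutation operator names; only the defaults
#'   (\code{"roulette"}, \code{"uniform"}, \code{"uniform"}) are available.
#' @return object of class \code{ga_config}.
#' @export
ga_config <- function(population_size = 100, max_generations = 100,
                      crossover_rate = 0.90, mutation_rate = 0.10,
                      length_mode = length_fixed(2), elitism = TRUE,
                      rng_seed = 1L, convergence_threshold = 0.95,
                      stagnation_window = NULL,
                      selection = "roulette", crossover = "uniform",
                      mutation = "uniform") {
  if (!identical(selection, "roulette") || !identical(crossover, "uniform") ||
      !identical(mutation, "uniform"))
    config_error("ga_config: only roulette selection and uniform crossover/mutation are implemented")
  if (population_size < 2) config_error("ga_config: population_size must be >= 2")
  for (r in c(crossover_rate, mutation_rate, convergence_threshold))
    if (!is.numeric(r) || r < 0 || r > 1)
      config_error("ga_config: rates/thresholds must lie in [0, 1]")
  stopifnot(inherits(length_mode, "ga_length_mode"))
  if (!is.null(stagnation_window) && stagnation_window < 1)
    config_error("ga_config: stagnation_window must be >= 1 or NULL")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 length_mode = length_mode, elitism = isTRUE(elitism),
                 rng_seed = as.integer(rng_seed),
                 convergence_threshold = convergence_threshold,
                 stagnation_window = stagnation_window),
            class = "ga_config")
}

validate_individual <- function(genes, V) {
  genes <- as.integer(genes)
  if (length(genes) < 1 || anyDuplicated(genes) ||
      any(genes < 1L | genes > V))
    stop(sprintf("invalid individual: [%s] for V=%d",
                 paste(genes, collapse = ","), V))
  genes
}

#' Initialize a GA population of distinct-index subsets
#'
#' Each individual's genes are drawn uniformly from \code{1..V} and the whole
#' combination is redrawn until all genes are distinct (the rejection
#' procedure keeps the distribution uniform over ordered distinct tuples).
#' Lengths follow \code{config$length_mode}.
#'
#' @param config a \code{\link{ga_config}}.
#' @param V number of available variables.
#' @param stream optional \code{\link{rng_stream}}; defaults to the
#'   config-seed-derived \code{"init"} substream.
#' @return object of class \code{ga_population}: list with
#'   \code{individuals} and \code{generation_index}.
#' @export
init_population <- function(config, V, stream = NULL) {
  stopifnot(inherits(config, "ga_config"))
  V <- as.integer(V)
  lm <- config$length_mode
  max_len <- if (lm$mode == "fixed") lm$L else lm$max
  if (max_len > V)
    config_error(sprintf("init_population: subset length %d exceeds V=%d",
                         max_len, V))
  if (is.null(stream))
    stream <- rng_stream(derive_seed(config$rng_seed, "init"))
  inds <- stream_do(stream, function() {
    lapply(seq_len(config$population_size), function(i) {
      len <- if (lm$mode == "fixed") lm$L
             else lm$min + floor(runif(1) * (lm$max - lm$min + 1L))
      repeat {
        g <- 1L + floor(runif(len) * V)
        if (!anyDuplicated(g)) return(as.integer(g))
      }
    })
  })
  structure(list(individuals = inds, generation_index = 0L),
            class = "ga_population")
}

# index drawn with probability score_i / sum(scores); all-zero -> uniform
roulette_index <- function(scores, stream) {
  if (any(scores < 0)) config_error("roulette: negative selection score")
  total <- sum(scores)
  u <- stream_do(stream, function() runif(1))
  if (total == 0) return(1L + as.integer(floor(u * length(scores))) %% length(scores))
  cum <- cumsum(scores)
  which(u * total <= cum)[1]
}

#' Wheel-roulette (fitness-proportional) selection
#'
#' Returns one individual with probability \code{scores[i] / sum(scores)}.
#' All-zero scores fall back to uniform selection (documented degenerate
#' case); a negative score is an error.
#'
#' @param pop a \code{ga_population}.
#' @param scores non-negative per-individual selection scores.
#' @param stream an \code{\link{rng_stream}}.
#' @return the selected individual (integer gene vector).
#' @export
roulette_select <- function(pop, scores, stream) {
  stopifnot(inherits(pop, "ga_population"),
            length(scores) == length(pop$individuals))
  pop$individuals[[roulette_index(scores, stream)]]
}

# replace duplicate genes (after the first occurrence) by uniform draws from
# the indices absent from the child
repair_duplicates <- function(genes, V) {
  seen <- logical(V)
  for (k in seq_along(genes)) {
    g <- genes[k]
    if (seen[g]) {
      pool <- which(!seen)
      pool <- pool[!pool %in% genes[-k]] # also avoid yet-unprocessed genes
      genes[k] <- if (length(pool) == 1L) pool else
        pool[1L + floor(runif(1) * length(pool))]
    }
    seen[genes[k]] <- TRUE
  }
  genes
}

#' Uniform crossover of two subsets
#'
#' Positions up to the shorter parent's length are exchanged with
#' probability 1/2 (complementary assignment to the two children); tail
#' positions of the longer parent go to the same-length child, so children
#' keep their parents' lengths. Duplicate genes arising in a child are
#' repaired by redrawing uniformly from indices absent from that child.
#'
#' @param p1,p2 integer gene vectors (distinct indices in \code{1..V}).
#' @param V number of available variables (defines the repair pool).
#' @param stream an \code{\link{rng_stream}}.
#' @return list of two children, \code{list(child1, child2)} with
#'   \code{length(child1) == length(p1)}.
#' @export
uniform_crossover <- function(p1, p2, V, stream) {
  p1 <- validate_individual(p1, V)
  p2 <- validate_individual(p2, V)
  m <- min(length(p1), length(p2))
  stream_do(stream, function() {
    take1 <- runif(m) < 0.5 # TRUE: child1 takes p1's gene at this position
    c1 <- p1
    c2 <- p2
    c1[seq_len(m)] <- ifelse(take1, p1[seq_len(m)], p2[seq_len(m)])
    c2[seq_len(m)] <- ifelse(take1, p2[seq_len(m)], p1[seq_len(m)])
    list(repair_duplicates(c1, V), repair_duplicates(c2, V))
  })
}

#' Uniform mutation of a subset
#'
#' Each gene independently, with probability \code{mutation_rate}, is
#' replaced by an index drawn uniformly from the indices not currently in
#' the individual, so distinctness and length are preserved. If the
#' individual already uses all \code{V} indices there is no replacement pool
#' and it is returned unchanged.
#'
#' @param ind integer gene vector.
#' @param mutation_rate per-gene mutation probability.
#' @param V number of available variables.
#' @param stream an \code{\link{rng_stream}}.
#' @return mutated individual, same length.
#' @export
uniform_mutate <- function(ind, mutation_rate, V, stream) {
  ind <- validate_individual(ind, V)
  if (length(ind) >= V) return(ind)
  stream_do(stream, function() {
    hit <- runif(length(ind)) < mutation_rate
    for (k in which(hit)) {
      pool <- setdiff(seq_len(V), ind)
      ind[k] <- if (length(pool) == 1L) pool else
        pool[1L + floor(runif(1) * length(pool))]
    }
    ind
  })
}

#' Positional convergence test
#'
#' In fixed-length mode, TRUE when at every gene position at least
#' \code{threshold} of the population carries the same variable index. In
#' variable-length mode (unequal lengths present) returns FALSE.
#'
#' @param pop a \code{ga_population}.
#' @param threshold fraction in \[0, 1\].
#' @return logical.
#' @export
check_convergence <- function(pop, threshold = 0.95) {
  lens <- lengths(pop$individuals)
  if (length(unique(lens)) != 1L) return(FALSE)
  G <- do.call(rbind, pop$individuals)
  n <- nrow(G)
  all(apply(G, 2, function(col) max(tabulate(col)) / n >= threshold))
}

#' Run the generational GA over variable subsets
#'
#' Evaluate, select parent pairs by roulette on shifted fitness
#' (\code{score_i = worst - fitness_i + 1e-12}: the GA minimizes, roulette
#' needs non-negative goodness; an all-equal generation degrades to uniform
#' selection), cross with probability \code{crossover_rate} (otherwise copy
#' parents), mutate, and replace the generation wholesale. With elitism the
#' best-so-far individual replaces the worst child, making the best-fitness
#' trace monotone non-increasing. Stops on the generation cap, positional
#' convergence, or stagnation.
#'
#' @param config a \code{\link{ga_config}}.
#' @param V number of available variables.
#' @param fitness_fn function(genes) -> real, minimized. An error raised by
#'   \code{fitness_fn} aborts the run with the offending genes reported.
#' @return object of class \code{ga_result}: \code{best_individuals}
#'   (data.frame of deduplicated subsets ranked by fitness, genes as
#'   comma-joined sorted indices), \code{fitness_trace} (per-generation
#'   \code{generation}, \code{best}, \code{mean}, \code{best_genes}),
#'   \code{termination_reason}, \code{seed}.
#' @export
evolve <- function(config, V, fitness_fn) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness_fn))
  V <- as.integer(V)
  streams <- list(
    init = rng_stream(derive_seed(config$rng_seed, "init")),
    selection = rng_stream(derive_seed(config$rng_seed, "selection")),
    crossover = rng_stream(derive_seed(config$rng_seed, "crossover")),
    mutation = rng_stream(derive_seed(config$rng_seed, "mutation")))
  pop <- init_population(config, V, streams$init)
  n <- config$population_size

  eval_one <- function(genes) {
    val <- tryCatch(fitness_fn(genes), error = function(e)
      stop(sprintf("fitness evaluation failed for individual [%s]: %s",
                   paste(genes, collapse = ","), conditionMessage(e)),
           call. = FALSE))
    if (!is.finite(val))
      stop(sprintf("non-finite fitness for individual [%s]",
                   paste(genes, collapse = ",")), call. = FALSE)
    val
  }

  archive <- new.env(parent = emptyenv())
  remember <- function(genes, fit) {
    key <- paste(sort(genes), collapse = ",")
    old <- get0(key, envir = archive, inherits = FALSE)
    if (is.null(old) || fit < old$fit)
      assign(key, list(genes = genes, fit = fit), envir = archive)
  }

  elite <- NULL
  elite_fit <- Inf
  trace <- vector("list", config$max_generations)
  reason <- "max_generations"
  stagnant <- 0L

  for (gen in seq_len(config$max_generations) - 1L) {
    pop$generation_index <- gen
    fits <- vapply(pop$individuals, eval_one, numeric(1))
    if (config$elitism && !is.null(elite) && min(fits) > elite_fit) {
      worst <- which.max(fits)
      pop$individuals[[worst]] <- elite
      fits[worst] <- elite_fit
    }
    for (i in seq_len(n)) remember(pop$individuals[[i]], fits[i])
    best_i <- which.min(fits)
    improved <- fits[best_i] < elite_fit - 1e-12
    if (fits[best_i] < elite_fit) {
      elite <- pop$individuals[[best_i]]
      elite_fit <- fits[best_i]
    }
    trace[[gen + 1L]] <- data.frame(
      generation = gen, best = min(fits), mean = mean(fits),
      best_genes = paste(pop$individuals[[best_i]], collapse = ","))
    stagnant <- if (improved) 0L else stagnant + 1L
    if (gen > 0L && config$length_mode$mode == "fixed" &&
        check_convergence(pop, config$convergence_threshold)) {
      reason <- "converged"; break
    }
    if (!is.null(config$stagnation_window) &&
        stagnant >= config$stagnation_window) {
      reason <- "stagnated"; break
    }
    if (gen == config$max_generations - 1L) break

    scores <- (max(fits) - fits) + 1e-12
    children <- vector("list", n)
    k <- 0L
    while (k < n) {
      i1 <- roulette_index(scores, streams$selection)
      i2 <- roulette_index(scores, streams$selection)
      p1 <- pop$individuals[[i1]]
      p2 <- pop$individuals[[i2]]
      do_cx <- stream_do(streams$crossover, function() runif(1)) <
        config$crossover_rate
      pair <- if (do_cx) uniform_crossover(p1, p2, V, streams$crossover)
              else list(p1, p2)
      for (child in pair) {
        if (k >= n) break
        k <- k + 1L
        children[[k]] <- uniform_mutate(child, config$mutation_rate, V,
                                        streams$mutation)
      }
    }
    pop$individuals <- children
  }

  ranked <- eapply(archive, identity)
  fit_vec <- vapply(ranked, function(r) r$fit, numeric(1))
  key_vec <- names(ranked)
  ord <- order(fit_vec, key_vec) # fitness, then lexicographic key: stable
  best_individuals <- data.frame(
    genes = vapply(ranked[ord], function(r)
      paste(sort(r$genes), collapse = ","), character(1)),
    fitness = fit_vec[ord], row.names = NULL)
  structure(list(best_individuals = best_individuals,
                 fitness_trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
                 termination_reason = reason,
                 seed = config$rng_seed),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations, stopped: %s, seed %d\n",
              nrow(x$fitness_trace), x$termination_reason, x$seed))
  cat("top subsets:\n")
  print(utils::head(x$best_individuals, 5))
  invisible(x)
}
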