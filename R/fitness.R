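#' Fitness specification for SVM-guided subset selection
#'
#' Two variants of the wrapper fitness (both minimized):
#' \describe{
#'   \item{mse_train}{sum over classes of the one-vs-rest binary training
#'     MSE on the projected training partition.}
#'   \item{mse_train_plus_test}{the training sum plus the same sum evaluated
#'     on the projected test partition; requires a non-empty test partition.}
#' }
#' SVM hyperparameters are fixed for the whole GA run (chosen beforehand,
#' e.g. by \code{\link{random_parameter_search}}), not re-tuned per
#' individual.
#'
#' @param variant \code{"mse_train"} or \code{"mse_train_plus_test"}.
#' @param svm_params an \code{\link{svm_params}}.
#' @param rng_seed integer, passed to SVM training (recorded; training is
#'   deterministic).
#' @return object of class \code{fitness_spec}.
#' @export
fitness_spec <- function(variant = c("mse_train", "mse_train_plus_test"),
                         svm_params, rng_seed = 0L) {
  variant <- match.arg(variant)
  stopifnot(inherits(svm_params, "svm_params"))
  structure(list(variant = variant, svm_params = svm_params,
                 rng_seed = as.integer(rng_seed)),
            class = "fitness_spec")
}

#' Evaluate the SVM fitness of one variable subset
#'
#' Projects the training (and, for \code{mse_train_plus_test}, the test)
#' partition onto the individual's variables, trains a one-vs-rest model on
#' the projected training data with the spec's fixed hyperparameters, and
#' returns the summed per-class binary MSE. Lower is better; 0 means every
#' machine separates its partition(s) perfectly. Fitness depends on the
#' subset, not the gene order.
#'
#' @param ind integer vector of distinct variable indices.
#' @param train training-partition \code{sample_set} (all classes present).
#' @param test test-partition \code{sample_set} (may be empty under
#'   \code{mse_train}).
#' @param spec a \code{\link{fitness_spec}}.
#' @return non-negative real fitness.
#' @export
evaluate_fitness <- function(ind, train, test, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (spec$variant == "mse_train_plus_test" &&
      (is.null(test) || n_samples(test) == 0))
    data_error("evaluate_fitness: mse_train_plus_test requires a non-empty test partition")
  ptrain <- project_variables(train, ind)
  model <- withCallersGenes(ind, train_ovr(ptrain, spec$svm_params,
                                           spec$rng_seed))
  fit <- ovr_mse(model, ptrain)
  if (spec$variant == "mse_train_plus_test") {
    ptest <- project_variables(test, ind)
    fit <- fit + ovr_mse(model, ptest)
  }
  fit
}

# attach the individual's genes to any propagated svm_core error
withCallersGenes <- function(ind, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[genes %s] %s", paste(ind, collapse = ","),
                 conditionMessage(e)), call. = FALSE))
}

#' Build a cached GA fitness function
#'
#' Returns a closure suitable for \code{\link{evolve}}. Evaluations are
#' cached keyed by the sorted gene tuple, so a subset re-encountered during
#' the run is not retrained; since fitness is deterministic and
#' order-invariant, the cache cannot change any result, only its cost.
#'
#' @param train,test partitions as in \code{\link{evaluate_fitness}}.
#' @param spec a \code{\link{fitness_spec}}.
#' @return function(genes) -> fitness, with attribute access to its cache.
#' @export
make_fitness_fn <- function(train, test, spec) {
  cache <- new.env(parent = emptyenv())
  fn <- function(genes) {
    key <- paste(sort(as.integer(genes)), collapse = ",")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- evaluate_fitness(genes, train, test, spec)
    assign(key, val, envir = cache)
    val
  }
  attr(fn, "cache") <- cache
  fn
}

#' Strict-error report for one subset over the three partitions
#'
#' Trains on the projected training partition and reports strict one-vs-rest
#' error counts on train, test and commercial — one row of the method's
#' standard results table. An empty partition is reported as \code{NA}
#' (not applicable), never as zero errors.
#'
#' @param ind integer vector of distinct variable indices.
#' @param train,test,commercial partition \code{sample_set}s.
#' @param spec a \code{\link{fitness_spec}}.
#' @return one-row data.frame: \code{genes}, \code{n_train},
#'   \code{err_train}, \code{n_test}, \code{err_test}, \code{n_commercial},
#'   \code{err_commercial}.
#' @export
evaluate_report <- function(ind, train, test, commercial, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  ptrain <- project_variables(train, ind)
  model <- withCallersGenes(ind, train_ovr(ptrain, spec$svm_params,
                                           spec$rng_seed))
  count_part <- function(part) {
    if (is.null(part) || n_samples(part) == 0) return(NA_integer_)
    count_strict_errors(model, project_variables(part, ind))
  }
  data.frame(genes = paste(ind, collapse = ","),
             n_train = n_samples(train), err_train = count_part(train),
             n_test = if (is.null(test)) 0L else n_samples(test),
             err_test = count_part(test),
             n_commercial = if (is.null(commercial)) 0L else n_samples(commercial),
             err_commercial = count_part(commercial))
}
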