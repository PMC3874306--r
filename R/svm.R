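#' Soft-margin SVM hyperparameters
#'
#' \code{C} is the penalty weighting the sum of slack variables against the
#' margin norm: larger \code{C} gives a narrower margin and fewer training
#' errors. \code{epsilon} is the optimizer's duality-gap stopping tolerance
#' (the task is classification; there is no regression tube). The default
#' kernel is Gaussian, whose width corresponds to the "radial" parameter of
#' chemometric SVM parameter tables.
#'
#' @param C positive penalty.
#' @param epsilon positive convergence tolerance of the SMO solver.
#' @param kernel a \code{\link{kernel_spec}}.
#' @return object of class \code{svm_params}.
#' @export
svm_params <- function(C, epsilon = 1e-6,
                       kernel = kernel_spec("gaussian", sigma = 5)) {
  if (!is.numeric(C) || length(C) != 1 || C <= 0)
    config_error("svm_params: C must be a positive real")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    config_error("svm_params: epsilon must be a positive real")
  stopifnot(inherits(kernel, "kernel_spec"))
  structure(list(C = C, epsilon = epsilon, kernel = kernel),
            class = "svm_params")
}

MAX_SMO_ITER <- 1e7

# y from a binary sample_set; labels must be coercible to {-1, +1}
binary_labels <- function(set) {
  y <- suppressWarnings(as.numeric(as.character(set$label)))
  if (any(is.na(y)) || !all(y %in% c(-1, 1)))
    data_error("binary SVM training requires labels in {-1, +1}")
  y
}

standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1 # constant columns pass through
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Train a binary soft-margin SVM
#'
#' Solves the dual of
#' \deqn{\min_{w,\xi} \ \tfrac12 w^T w + C \sum_i \xi_i}
#' by deterministic sequential minimal optimization (maximal-violating-pair
#' working set, lowest-index tie break), to duality-gap tolerance
#' \code{params$epsilon}. Features are standardized (zero mean, unit variance,
#' statistics from this training set) before kernel evaluation; the
#' standardizer is stored in the model and applied to all future inputs.
#'
#' The solver is fully deterministic; \code{rng_seed} is accepted for
#' interface uniformity and recorded, but no random draws occur.
#'
#' @param train a \code{sample_set} whose labels are \code{-1}/\code{+1},
#'   with both classes present.
#' @param params an \code{\link{svm_params}}.
#' @param rng_seed integer, recorded in the model.
#' @return object of class \code{binary_svm} with fields
#'   \code{support_vectors} (rows, standardized space),
#'   \code{dual_coefficients} (\eqn{\alpha_i y_i}), \code{bias},
#'   \code{kernel}, \code{standardize} and \code{training_summary}.
#' @export
train_binary_svm <- function(train, params, rng_seed = 0L) {
  stopifnot(inherits(train, "sample_set"), inherits(params, "svm_params"))
  if (n_samples(train) < 2)
    data_error("train_binary_svm: need at least two samples")
  y <- binary_labels(train)
  if (length(unique(y)) < 2)
    data_error("train_binary_svm: both classes (+1 and -1) must be present")
  std <- standardizer(train$spectra)
  X <- apply_standardizer(std, train$spectra)
  K <- kernel_matrix(params$kernel, X)
  binary_from_solution(X, K, y, std, params, rng_seed)
}

# assemble a binary_svm from a precomputed standardized design and kernel
binary_from_solution <- function(X, K, y, std, params, rng_seed) {
  sol <- .smo_solve(K, y, params$C, params$epsilon, MAX_SMO_ITER)
  sv <- which(sol$alpha > 0)
  if (!length(sv)) sv <- 1L # degenerate guard; cannot occur with two classes
  dual_full <- sol$alpha * y
  model <- structure(list(
    support_vectors = X[sv, , drop = FALSE],
    dual_coefficients = dual_full[sv],
    bias = sol$b,
    kernel = params$kernel,
    standardize = std,
    n_vars = ncol(X),
    params = params,
    rng_seed = as.integer(rng_seed),
    dual_full = dual_full,
    training_summary = NULL), class = "binary_svm")
  f <- drop(K %*% dual_full) + sol$b
  model$training_summary <- list(n_train = length(y),
                                 n_misclassified = sum(y * f <= 0))
  model
}

#' Decision values of a binary SVM
#'
#' \eqn{f(x) = \sum_i \alpha_i y_i K(s_i, x) + b}; the sign of \eqn{f} is the
#' predicted class.
#'
#' @param model a \code{binary_svm}.
#' @param x a numeric vector (one spectrum) or matrix (one spectrum per row)
#'   in the model's original (unstandardized) input space.
#' @return numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "binary_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_vars)
    data_error(sprintf("decision_value: input has %d variables, model expects %d",
                       ncol(x), model$n_vars))
  Xs <- apply_standardizer(model$standardize, x)
  K <- kernel_matrix(model$kernel, Xs, model$support_vectors)
  drop(K %*% model$dual_coefficients) + model$bias
}

#' Classification mean squared error of a binary SVM
#'
#' The mean over all evaluation samples of \eqn{(f(x_i) - y_i)^2} restricted
#' to misclassified samples (\eqn{y_i f(x_i) \le 0}); correctly classified
#' samples contribute 0. The value is 0 exactly when every sample lies on its
#' correct side, grows with both the number and the depth of
#' misclassifications, and is deterministic — the three properties the GA
#' fitness relies on.
#'
#' @param model a \code{binary_svm}.
#' @param eval_set non-empty \code{sample_set} with \code{-1}/\code{+1} labels.
#' @return non-negative real.
#' @export
classification_mse <- function(model, eval_set) {
  stopifnot(inherits(eval_set, "sample_set"))
  if (n_samples(eval_set) == 0)
    data_error("classification_mse: evaluation set is empty")
  y <- binary_labels(eval_set)
  f <- decision_value(model, eval_set$spectra)
  mis <- y * f <= 0
  sum((f[mis] - y[mis])^2) / length(y)
}

# relabel a multiclass set as {-1,+1} for class `cls`
relabel_one_vs_rest <- function(set, cls) {
  y <- ifelse(as.character(set$label) == cls, "1", "-1")
  sample_set(set$spectra, y, as.character(set$role),
             class_levels = c("-1", "1"))
}

#' Train a one-vs-rest multiclass SVM
#'
#' One binary machine per class: that class relabeled \code{+1}, all others
#' \code{-1}. Deterministic under fixed inputs.
#'
#' @param train a \code{sample_set} with at least two classes, all present.
#' @param params an \code{\link{svm_params}} shared by all machines.
#' @param rng_seed integer, recorded.
#' @return object of class \code{ovr_svm}: list with \code{per_class} (named
#'   list of \code{binary_svm}) and \code{class_levels}.
#' @export
train_ovr <- function(train, params, rng_seed = 0L) {
  stopifnot(inherits(train, "sample_set"))
  lev <- class_levels(train)
  if (length(lev) < 2)
    data_error("train_ovr: need at least two class levels")
  present <- unique(as.character(train$label))
  absent <- setdiff(lev, present)
  if (length(absent))
    data_error(sprintf("train_ovr: class '%s' absent from training set",
                       absent[1]))
  # the standardized design and kernel matrix are label-independent, so they
  # are computed once and shared by all per-class machines
  std <- standardizer(train$spectra)
  X <- apply_standardizer(std, train$spectra)
  K <- kernel_matrix(params$kernel, X)
  per_class <- lapply(lev, function(cls) {
    y <- ifelse(as.character(train$label) == cls, 1, -1)
    binary_from_solution(X, K, y, std, params, rng_seed)
  })
  structure(list(per_class = setNames(per_class, lev), class_levels = lev,
                 params = params, standardize = std, kernel = params$kernel,
                 train_X_std = X),
            class = "ovr_svm")
}

#' Per-class decision values of a one-vs-rest model
#'
#' @param model an \code{ovr_svm}.
#' @param x spectrum vector or matrix of spectra (rows).
#' @return matrix, one row per input spectrum, one column per class level.
#' @export
ovr_decision_values <- function(model, x) {
  stopifnot(inherits(model, "ovr_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.null(model$train_X_std)) {
    # fast path: one kernel evaluation against the shared training design;
    # zero dual coefficients contribute exactly 0, so this equals the
    # per-machine support-vector expansion
    Xs <- apply_standardizer(model$standardize, x)
    Ke <- kernel_matrix(model$kernel, Xs, model$train_X_std)
    D <- vapply(model$per_class, function(m) m$dual_full,
                numeric(nrow(model$train_X_std)))
    b <- vapply(model$per_class, function(m) m$bias, numeric(1))
    f <- Ke %*% D
    return(sweep(f, 2, b, "+"))
  }
  vapply(model$per_class, function(m) decision_value(m, x), numeric(nrow(x)))
}

#' Predict by largest one-vs-rest decision value
#'
#' Ties are broken by class order in \code{class_levels} (first wins), for
#' determinism.
#'
#' @param model an \code{ovr_svm}.
#' @param x spectrum vector or matrix of spectra.
#' @return character vector of predicted class labels.
#' @export
predict_argmax <- function(model, x) {
  f <- ovr_decision_values(model, x)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  model$class_levels[apply(f, 1, which.max)]
}

#' Strict one-vs-rest error count
#'
#' A sample is counted correct only if every binary machine places it on the
#' right side: its own class's machine must say \code{+1} and every other
#' machine \code{-1}. This is stricter than argmax prediction, so the strict
#' correct count never exceeds the argmax correct count.
#'
#' @param model an \code{ovr_svm}.
#' @param eval_set non-empty \code{sample_set}.
#' @return integer number of samples failing strict correctness.
#' @export
count_strict_errors <- function(model, eval_set) {
  stopifnot(inherits(eval_set, "sample_set"))
  if (n_samples(eval_set) == 0)
    data_error("count_strict_errors: evaluation set is empty")
  f <- ovr_decision_values(model, eval_set$spectra)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  lab <- as.character(eval_set$label)
  target <- outer(lab, model$class_levels, "==") # TRUE where f must be > 0
  ok <- ifelse(target, f > 0, f < 0)
  sum(rowSums(ok) < length(model$class_levels))
}

#' Argmax error count (companion to strict counting)
#'
#' @param model an \code{ovr_svm}.
#' @param eval_set non-empty \code{sample_set}.
#' @return integer number of samples whose argmax prediction is wrong.
#' @export
count_argmax_errors <- function(model, eval_set) {
  stopifnot(inherits(eval_set, "sample_set"))
  if (n_samples(eval_set) == 0)
    data_error("count_argmax_errors: evaluation set is empty")
  sum(predict_argmax(model, eval_set$spectra) !=
        as.character(eval_set$label))
}

# summed per-class one-vs-rest binary classification MSE on eval_set
ovr_mse <- function(model, eval_set) {
  f <- ovr_decision_values(model, eval_set$spectra)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  lab <- as.character(eval_set$label)
  total <- 0
  for (k in seq_along(model$class_levels)) {
    y <- ifelse(lab == model$class_levels[k], 1, -1)
    mis <- y * f[, k] <= 0
    total <- total + sum((f[mis, k] - y[mis])^2) / length(y)
  }
  total
}

default_search_ranges <- function() {
  list(log10_C = c(-1, 5), log10_epsilon = c(-7, -2), sigma = c(0.5, 20))
}

#' Random search over SVM hyperparameters
#'
#' Draws \code{n_combinations} triples (C, epsilon, sigma) — C and epsilon
#' log-uniform, sigma uniform — trains a full one-vs-rest Gaussian-kernel
#' model per triple on \code{train}, scores each by the summed per-class
#' training MSE, and returns the table sorted ascending by that score
#' (stable; ties keep draw order). Deterministic under \code{rng_seed}.
#'
#' @param train a multiclass \code{sample_set}.
#' @param n_combinations number of random triples (default 100).
#' @param ranges list with \code{log10_C}, \code{log10_epsilon} (log10
#'   bounds) and \code{sigma} (linear bounds), each \code{c(min, max)}.
#' @param rng_seed integer seed.
#' @return data.frame with columns \code{rank}, \code{C}, \code{epsilon},
#'   \code{sigma}, \code{mse_train}.
#' @export
random_parameter_search <- function(train, n_combinations = 100,
                                    ranges = default_search_ranges(),
                                    rng_seed = 1L) {
  if (!is.numeric(n_combinations) || n_combinations < 1)
    config_error("random_parameter_search: n_combinations must be >= 1")
  n_combinations <- as.integer(n_combinations)
  for (nm in c("log10_C", "log10_epsilon", "sigma")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      config_error(sprintf(
        "random_parameter_search: invalid range for %s (need c(min, max), min <= max)", nm))
  }
  if (ranges$sigma[1] <= 0)
    config_error("random_parameter_search: sigma range must be positive")
  stream <- rng_stream(derive_seed(rng_seed, "parameter_search"))
  draws <- stream_do(stream, function() {
    data.frame(
      C = 10^runif(n_combinations, ranges$log10_C[1], ranges$log10_C[2]),
      epsilon = 10^runif(n_combinations, ranges$log10_epsilon[1],
                         ranges$log10_epsilon[2]),
      sigma = runif(n_combinations, ranges$sigma[1], ranges$sigma[2]))
  })
  mse <- vapply(seq_len(n_combinations), function(i) {
    p <- svm_params(draws$C[i], draws$epsilon[i],
                    kernel_spec("gaussian", sigma = draws$sigma[i]))
    ovr_mse(train_ovr(train, p, rng_seed), train)
  }, numeric(1))
  ord <- order(mse) # stable radix-style order: ties keep draw order
  out <- draws[ord, , drop = FALSE]
  out$mse_train <- mse[ord]
  out <- cbind(rank = seq_len(n_combinations), out)
  rownames(out) <- NULL
  out
}
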