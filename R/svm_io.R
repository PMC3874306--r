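#' Save a trained SVM model as a self-describing JSON document
#'
#' Serializes a \code{binary_svm} or \code{ovr_svm} — kernel specification,
#' standardization statistics, support vectors, dual coefficients, bias and
#' training summary — with 17 significant digits so that
#' \code{load_svm_model(save_svm_model(m))} reproduces decision values
#' bitwise.
#'
#' @param model a \code{binary_svm} or \code{ovr_svm}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
save_svm_model <- function(model, path) {
  doc <- if (inherits(model, "binary_svm")) {
    c(list(type = "binary_svm"), binary_to_list(model))
  } else if (inherits(model, "ovr_svm")) {
    list(type = "ovr_svm",
         class_levels = model$class_levels,
         params = params_to_list(model$params),
         standardize = model$standardize,
         train_X_std = model$train_X_std,
         per_class = lapply(model$per_class, binary_to_list))
  } else {
    config_error("save_svm_model: not a binary_svm or ovr_svm")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load an SVM model saved by \code{\link{save_svm_model}}
#'
#' @param path JSON path.
#' @return the reconstructed \code{binary_svm} or \code{ovr_svm}.
#' @export
load_svm_model <- function(path) {
  if (!file.exists(path))
    data_error(sprintf("load_svm_model: file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "binary_svm")) return(binary_from_list(doc))
  if (identical(doc$type, "ovr_svm")) {
    per_class <- lapply(doc$per_class, binary_from_list)
    params <- params_from_list(doc$params)
    return(structure(list(per_class = per_class,
                          class_levels = doc$class_levels,
                          params = params,
                          standardize = lapply(doc$standardize, as.numeric),
                          kernel = params$kernel,
                          train_X_std = as_matrix(doc$train_X_std)),
                     class = "ovr_svm"))
  }
  data_error("load_svm_model: unrecognized model document")
}

params_to_list <- function(p) {
  list(C = p$C, epsilon = p$epsilon, kernel = unclass(p$kernel))
}

params_from_list <- function(l) {
  k <- l$kernel
  svm_params(l$C, l$epsilon,
             kernel_spec(k$kind, sigma = k$sigma, order = k$order))
}

binary_to_list <- function(m) {
  list(support_vectors = m$support_vectors,
       dual_coefficients = m$dual_coefficients,
       bias = m$bias,
       kernel = unclass(m$kernel),
       standardize = m$standardize,
       n_vars = m$n_vars,
       params = params_to_list(m$params),
       rng_seed = m$rng_seed,
       dual_full = m$dual_full,
       training_summary = m$training_summary)
}

as_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

binary_from_list <- function(l) {
  params <- params_from_list(l$params)
  structure(list(
    support_vectors = as_matrix(l$support_vectors),
    dual_coefficients = as.numeric(l$dual_coefficients),
    bias = as.numeric(l$bias),
    kernel = params$kernel,
    standardize = lapply(l$standardize, as.numeric),
    n_vars = as.integer(l$n_vars),
    params = params,
    rng_seed = as.integer(l$rng_seed),
    dual_full = as.numeric(l$dual_full),
    training_summary = list(
      n_train = as.integer(l$training_summary$n_train),
      n_misclassified = as.integer(l$training_summary$n_misclassified))),
    class = "binary_svm")
}
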