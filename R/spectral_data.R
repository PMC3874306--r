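#' @useDynLib wavesel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils count.fields read.csv
NULL

ROLES <- c("train", "test", "commercial")

config_error <- function(msg) {
  stop(structure(class = c("wavesel_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

data_error <- function(msg) {
  stop(structure(class = c("wavesel_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Labeled spectral sample set
#'
#' Container for a samples-by-variables absorbance matrix with one
#' concentration-class label and one role (\code{train}, \code{test} or
#' \code{commercial}) per sample. Variable indexing is 1-based everywhere in
#' the package: variable \code{j} is column \code{j} of \code{spectra}.
#'
#' @param spectra numeric matrix, one row per sample, one column per variable;
#'   all values must be finite.
#' @param label vector of class labels (coerced to character); treated as
#'   opaque categories.
#' @param role character vector of roles, each one of
#'   \code{"train"}, \code{"test"}, \code{"commercial"}.
#' @param class_levels optional character vector fixing the ordered set of
#'   admissible labels; defaults to the labels present, in order of first
#'   appearance.
#' @return an object of class \code{sample_set} with fields \code{spectra},
#'   \code{label} (factor over \code{class_levels}) and \code{role}.
#' @export
sample_set <- function(spectra, label, role, class_levels = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  n <- nrow(spectra)
  label <- as.character(label)
  role <- as.character(role)
  if (length(label) != n || length(role) != n)
    data_error("sample_set: label/role length must equal the number of spectra")
  if (n > 0 && any(!is.finite(spectra)))
    data_error("sample_set: all absorbance values must be finite")
  bad_role <- setdiff(unique(role), ROLES)
  if (length(bad_role))
    data_error(sprintf("sample_set: unknown role(s): %s",
                       paste(bad_role, collapse = ", ")))
  if (is.null(class_levels)) class_levels <- unique(label)
  class_levels <- as.character(class_levels)
  if (anyDuplicated(class_levels))
    data_error("sample_set: class_levels must be distinct")
  bad_lab <- setdiff(unique(label), class_levels)
  if (length(bad_lab))
    data_error(sprintf("sample_set: label(s) not in class_levels: %s",
                       paste(bad_lab, collapse = ", ")))
  colnames(spectra) <- paste0("v", seq_len(ncol(spectra)))
  structure(list(spectra = spectra,
                 label = factor(label, levels = class_levels),
                 role = factor(role, levels = ROLES)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples x %d variables, %d class level(s)\n",
              n_samples(x), variable_count(x), length(class_levels(x))))
  if (n_samples(x) > 0) {
    tb <- table(x$label, x$role)
    print(tb)
  }
  invisible(x)
}

#' Number of samples in a sample set
#' @param set a \code{sample_set}.
#' @return integer count.
#' @export
n_samples <- function(set) nrow(set$spectra)

#' Number of spectral variables (V)
#' @param set a \code{sample_set}.
#' @return integer V.
#' @export
variable_count <- function(set) ncol(set$spectra)

#' Ordered class levels of a sample set
#' @param set a \code{sample_set}.
#' @return character vector.
#' @export
class_levels <- function(set) levels(set$label)

# row subset keeping V and class_levels
subset_samples <- function(set, idx) {
  sample_set(set$spectra[idx, , drop = FALSE],
             as.character(set$label)[idx],
             as.character(set$role)[idx],
             class_levels = class_levels(set))
}

#' Read a labeled spectral sample set from CSV
#'
#' Expected layout: a header row naming columns \code{label, role, v1..vV},
#' then one row per sample. Decimal separator is \code{'.'}. Rows whose width
#' does not match the header are rejected.
#'
#' @param path path to the CSV file.
#' @param fmt format tag; only \code{"csv"} is supported.
#' @return a \code{sample_set}.
#' @export
load_spectra <- function(path, fmt = "csv") {
  if (!identical(fmt, "csv"))
    config_error(sprintf("load_spectra: unsupported format '%s'", fmt))
  if (!file.exists(path))
    data_error(sprintf("load_spectra: file not found: %s", path))
  widths <- count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1])[1]
    data_error(sprintf(
      "load_spectra: row %d has %d fields, expected %d (ragged CSV)",
      bad, widths[bad], widths[1]))
  }
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 comment.char = "#")
  for (col in c("label", "role")) {
    if (!col %in% names(df))
      data_error(sprintf("load_spectra: missing required column '%s'", col))
  }
  vcols <- setdiff(names(df), c("label", "role"))
  V <- length(vcols)
  n <- nrow(df)
  spectra <- matrix(NA_real_, n, V)
  for (j in seq_len(V)) {
    raw <- df[[vcols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad))
      data_error(sprintf(
        "load_spectra: non-numeric absorbance '%s' at row %d, column %s",
        raw[bad[1]], bad[1], vcols[j]))
    spectra[, j] <- num
  }
  miss <- which(is.na(df$label) | !nzchar(df$label))
  if (length(miss))
    data_error(sprintf("load_spectra: missing label at row %d", miss[1]))
  bad_role <- which(!df$role %in% ROLES)
  if (length(bad_role))
    data_error(sprintf("load_spectra: unparsable role '%s' at row %d",
                       df$role[bad_role[1]], bad_role[1]))
  sample_set(spectra, df$label, df$role)
}

#' Write a sample set to CSV
#'
#' Numbers are printed with 17 significant digits so that
#' \code{load_spectra(save_spectra(x))} round-trips doubles exactly and a
#' save/load/save cycle is byte-identical.
#'
#' @param set a \code{sample_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_spectra <- function(set, path) {
  stopifnot(inherits(set, "sample_set"))
  V <- variable_count(set)
  header <- paste(c("label", "role", paste0("v", seq_len(V))), collapse = ",")
  rows <- character(n_samples(set))
  for (i in seq_len(n_samples(set))) {
    rows[i] <- paste(c(as.character(set$label)[i], as.character(set$role)[i],
                       sprintf("%.17g", set$spectra[i, ])), collapse = ",")
  }
  con <- tryCatch(file(path, "wb"), error = function(e)
    data_error(sprintf("save_spectra: cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Partition a sample set by role
#'
#' @param set a \code{sample_set}.
#' @return a list with elements \code{train}, \code{test}, \code{commercial};
#'   the parts share \code{variable_count} and \code{class_levels} with the
#'   input and their sizes sum to the input size. Empty parts are allowed.
#' @export
split_by_role <- function(set) {
  stopifnot(inherits(set, "sample_set"))
  out <- lapply(ROLES, function(r) subset_samples(set, which(set$role == r)))
  setNames(out, ROLES)
}

#' Project a sample set onto a subset of variables
#'
#' Column \code{j} of the result is column \code{subset[j]} of the input, so
#' the result's variable count equals \code{length(subset)}. Labels and roles
#' are unchanged. Used to evaluate a genetic individual's wavelength subset.
#'
#' @param set a \code{sample_set}.
#' @param subset integer vector of 1-based variable indices.
#' @return a \code{sample_set} with \code{length(subset)} variables.
#' @export
project_variables <- function(set, subset) {
  stopifnot(inherits(set, "sample_set"))
  subset <- as.integer(subset)
  V <- variable_count(set)
  bad <- subset[subset < 1L | subset > V | is.na(subset)]
  if (length(bad))
    data_error(sprintf(
      "project_variables: index %s out of range 1..%d", bad[1], V))
  sample_set(set$spectra[, subset, drop = FALSE],
             as.character(set$label), as.character(set$role),
             class_levels = class_levels(set))
}
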