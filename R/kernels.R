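#' Kernel specification
#'
#' The three kernels used for spectral classification:
#' \describe{
#'   \item{linear}{\eqn{K(x,y) = \langle x, y\rangle}}
#'   \item{gaussian}{\eqn{K(x,y) = \exp(-\|x-y\|^2 / (2\sigma^2))}; the
#'     "radial" width \eqn{\sigma} must be positive}
#'   \item{polynomial}{\eqn{K(x,y) = (\langle x, y\rangle + 1)^n} with
#'     positive integer order \eqn{n}}
#' }
#'
#' @param kind one of \code{"linear"}, \code{"gaussian"}, \code{"polynomial"}.
#' @param sigma Gaussian width; required iff \code{kind = "gaussian"}.
#' @param order polynomial order; required iff \code{kind = "polynomial"}.
#' @return object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(kind = c("gaussian", "linear", "polynomial"),
                        sigma = NULL, order = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma) || !is.numeric(sigma) || length(sigma) != 1 ||
        sigma <= 0)
      config_error("kernel_spec: gaussian kernel requires sigma > 0")
    order <- NULL
  } else if (kind == "polynomial") {
    if (is.null(order) || !is.numeric(order) || length(order) != 1 ||
        order < 1 || order != round(order))
      config_error("kernel_spec: polynomial kernel requires integer order >= 1")
    order <- as.integer(order)
    sigma <- NULL
  } else {
    sigma <- NULL
    order <- NULL
  }
  structure(list(kind = kind, sigma = sigma, order = order),
            class = "kernel_spec")
}

#' Evaluate a kernel on a pair of spectra
#'
#' @param spec a \code{kernel_spec}.
#' @param x,y numeric vectors of equal length.
#' @return the kernel value, a single real.
#' @export
kernel_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y))
    data_error(sprintf("kernel_eval: length mismatch (%d vs %d)",
                       length(x), length(y)))
  switch(spec$kind,
         linear = sum(x * y),
         gaussian = exp(-sum((x - y)^2) / (2 * spec$sigma^2)),
         polynomial = (sum(x * y) + 1)^spec$order)
}

# Kernel matrix K[i, j] = K(X[i, ], Y[j, ]); vectorized over rows.
kernel_matrix <- function(spec, X, Y = X) {
  XY <- X %*% t(Y)
  switch(spec$kind,
         linear = XY,
         polynomial = (XY + 1)^spec$order,
         gaussian = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * XY
           d2[d2 < 0] <- 0 # guard round-off
           exp(-d2 / (2 * spec$sigma^2))
         })
}
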