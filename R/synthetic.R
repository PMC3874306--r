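#' Configuration of the synthetic IR-like spectrum generator
#'
#' The generator emulates the statistical structure of mid-infrared
#' absorbance spectra of diluted juice: 176 variables per spectrum, a small
#' number of truly informative wavelengths whose absorbance grows linearly
#' with juice concentration (Beer-Lambert), correlated redundant neighbors,
#' a smooth class-independent baseline, and white measurement noise.
#'
#' @param variable_count number of spectral variables V (default 176).
#' @param class_levels ordered concentration levels in percent.
#' @param counts_per_class_per_role integer matrix, one row per class level,
#'   columns \code{train}, \code{test}, \code{commercial}.
#' @param informative_indices variables carrying the concentration signal
#'   (default \code{c(94, 95)}, the pair a Procrustes-rotation analysis of
#'   the original juice data singled out).
#' @param band_width Gaussian band spread, in index units, shaping relative
#'   amplitudes across the informative indices.
#' @param redundancy_spread how many neighbor variables on each side of an
#'   informative one receive a scaled copy of its signal (factor 0.8 per
#'   index step, plus independent jitter), so selection must distinguish
#'   informative from merely correlated variables.
#' @param noise_sd white-noise standard deviation in absorbance units,
#'   applied to every variable (also used as the neighbor jitter sd).
#' @param amplitude_slope,amplitude_intercept affine concentration-to-
#'   amplitude map \code{a*c + b} with \code{a > 0}: absorbance linear in
#'   concentration, strictly increasing with class.
#' @param baseline_coef coefficients of the fixed low-order polynomial
#'   baseline \code{b0 + b1*v + b2*v^2 + ...} shared by all samples
#'   (class-independent, so it cannot leak label information).
#' @param rng_seed integer master seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(variable_count = 176,
                             class_levels = c(20, 25, 50, 70, 100),
                             counts_per_class_per_role = NULL,
                             informative_indices = c(94, 95),
                             band_width = 2, redundancy_spread = 2,
                             noise_sd = 0.01,
                             amplitude_slope = 0.01,
                             amplitude_intercept = 0.1,
                             baseline_coef = c(0.1, 2e-3, -8e-6),
                             rng_seed = 1L) {
  variable_count <- as.integer(variable_count)
  if (variable_count < 1)
    config_error("synthetic_config: variable_count must be >= 1")
  informative_indices <- as.integer(informative_indices)
  if (length(informative_indices) < 1)
    config_error("synthetic_config: need at least one informative index")
  if (any(informative_indices < 1 | informative_indices > variable_count))
    config_error("synthetic_config: informative_indices must lie in 1..variable_count")
  if (is.null(counts_per_class_per_role)) {
    counts_per_class_per_role <- default_role_counts(class_levels)
  }
  counts_per_class_per_role <- as.matrix(counts_per_class_per_role)
  if (nrow(counts_per_class_per_role) != length(class_levels) ||
      !all(c("train", "test", "commercial") %in%
             colnames(counts_per_class_per_role)))
    config_error("synthetic_config: counts_per_class_per_role needs one row per class and columns train/test/commercial")
  if (any(counts_per_class_per_role < 0))
    config_error("synthetic_config: counts_per_class_per_role must be non-negative")
  if (noise_sd < 0) config_error("synthetic_config: noise_sd must be >= 0")
  if (band_width <= 0) config_error("synthetic_config: band_width must be > 0")
  if (redundancy_spread < 0)
    config_error("synthetic_config: redundancy_spread must be >= 0")
  if (amplitude_slope <= 0)
    config_error("synthetic_config: amplitude_slope must be > 0")
  structure(list(variable_count = variable_count,
                 class_levels = as.numeric(class_levels),
                 counts_per_class_per_role = counts_per_class_per_role,
                 informative_indices = informative_indices,
                 band_width = band_width,
                 redundancy_spread = as.integer(redundancy_spread),
                 noise_sd = noise_sd,
                 amplitude_slope = amplitude_slope,
                 amplitude_intercept = amplitude_intercept,
                 baseline_coef = baseline_coef,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# per-class train/test/commercial counts of the two juice-dilution designs
default_role_counts <- function(class_levels) {
  high <- rbind("20" = c(20, 6, 0), "25" = c(19, 18, 2), "50" = c(16, 13, 0),
                "70" = c(14, 1, 0), "100" = c(17, 6, 19))
  low <- rbind("2" = c(19, 1, 0), "4" = c(17, 1, 0), "6" = c(16, 13, 0),
               "8" = c(22, 6, 0), "10" = c(21, 6, 1), "16" = c(20, 6, 1),
               "20" = c(19, 6, 0))
  colnames(high) <- colnames(low) <- c("train", "test", "commercial")
  key <- paste(class_levels, collapse = ",")
  if (identical(key, "20,25,50,70,100")) return(high)
  if (identical(key, "2,4,6,8,10,16,20")) return(low)
  m <- matrix(c(rep(16L, length(class_levels)), rep(6L, length(class_levels)),
                rep(2L, length(class_levels))), ncol = 3,
              dimnames = list(as.character(class_levels),
                              c("train", "test", "commercial")))
  m
}

#' High-concentration preset (juices, 20--100 percent)
#'
#' Five levels (20/25/50/70/100 percent) with 86 training, 44 test and 21
#' commercial samples.
#' @param ... overrides passed to \code{\link{synthetic_config}}.
#' @return a \code{synthetic_config}.
#' @export
synthetic_config_high <- function(...) {
  synthetic_config(class_levels = c(20, 25, 50, 70, 100), ...)
}

#' Low-concentration preset (soft drinks, 2--20 percent)
#'
#' Seven levels (2/4/6/8/10/16/20 percent) with 134 training, 39 test and 2
#' commercial samples.
#' @param ... overrides passed to \code{\link{synthetic_config}}.
#' @return a \code{synthetic_config}.
#' @export
synthetic_config_low <- function(...) {
  synthetic_config(class_levels = c(2, 4, 6, 8, 10, 16, 20), ...)
}

#' Generate a synthetic labeled spectral dataset
#'
#' For a sample of concentration class \eqn{c}:
#' \deqn{x_v = \mathrm{baseline}(v) + \sum_j a_j(c) [v = j]
#'       + \sum_j \sum_{d=1}^{s} 0.8^d (a_j(c) + \mathrm{jitter}) [v = j \pm d]
#'       + \varepsilon_v}
#' where the sum over \eqn{j} runs over the informative indices,
#' \eqn{a_j(c) = (\mathrm{slope}\cdot c + \mathrm{intercept})\,g_j} with
#' \eqn{g_j} a Gaussian band profile over the informative indices, \eqn{s}
#' is \code{redundancy_spread} and \eqn{\varepsilon_v} is white noise. The
#' class signal is confined to the informative indices and their redundancy
#' neighbors; with \code{noise_sd = 0} and \code{redundancy_spread = 0},
#' absorbance at each informative index is an exact strictly increasing
#' function of class and every other variable carries zero class
#' information.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{set} (a \code{\link{sample_set}}) and
#'   \code{informative} (the planted ground-truth indices).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  V <- config$variable_count
  v <- seq_len(V)
  baseline <- rep(0, V)
  for (p in seq_along(config$baseline_coef))
    baseline <- baseline + config$baseline_coef[p] * v^(p - 1)
  info <- config$informative_indices
  center <- mean(info)
  g <- exp(-(info - center)^2 / (2 * config$band_width^2))

  counts <- config$counts_per_class_per_role
  roles <- c("train", "test", "commercial")
  lab <- character(0); rol <- character(0); conc <- numeric(0)
  for (ci in seq_along(config$class_levels)) {
    for (r in roles) {
      k <- counts[ci, r]
      lab <- c(lab, rep(as.character(config$class_levels[ci]), k))
      rol <- c(rol, rep(r, k))
      conc <- c(conc, rep(config$class_levels[ci], k))
    }
  }
  n <- length(lab)
  stream <- rng_stream(derive_seed(config$rng_seed, "generate"))
  spectra <- stream_do(stream, function() {
    X <- matrix(rep(baseline, each = n), n, V)
    amp <- config$amplitude_slope * conc + config$amplitude_intercept
    for (jj in seq_along(info)) {
      j <- info[jj]
      sig <- amp * g[jj]
      X[, j] <- X[, j] + sig
      s <- config$redundancy_spread
      if (s > 0) {
        for (d in seq_len(s)) {
          for (vn in c(j - d, j + d)) {
            if (vn >= 1 && vn <= V && !(vn %in% info)) {
              jitter <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd)
                        else 0
              X[, vn] <- X[, vn] + 0.8^d * (sig + jitter)
            }
          }
        }
      }
    }
    if (config$noise_sd > 0)
      X <- X + matrix(rnorm(n * V, 0, config$noise_sd), n, V)
    X
  })
  list(set = sample_set(spectra, lab, rol,
                        class_levels = as.character(config$class_levels)),
       informative = info)
}

#' Generate a sequence of datasets over a noise grid
#'
#' One dataset per noise level, all other parameters and the seed-derived
#' substreams shared, for power-style characterization of the selector
#' (recovery of the planted indices as noise grows).
#'
#' @param base a \code{\link{synthetic_config}}.
#' @param noise_grid numeric vector of noise standard deviations.
#' @return list of \code{generate_dataset} results, one per grid value.
#' @export
difficulty_sweep <- function(base, noise_grid) {
  stopifnot(inherits(base, "synthetic_config"))
  if (length(noise_grid) < 1)
    config_error("difficulty_sweep: noise_grid must be non-empty")
  lapply(noise_grid, function(sd) {
    cfg <- base
    cfg$noise_sd <- sd
    generate_dataset(cfg)
  })
}

#' Write the generator's answer key
#'
#' Sidecar JSON recording the full configuration and the planted informative
#' indices, so any third party can re-derive the dataset and score recovery.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_answer_key <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  key <- unclass(config)
  key$counts_per_class_per_role <- as.data.frame(config$counts_per_class_per_role)
  key$planted_informative_indices <- config$informative_indices
  jsonlite::write_json(key, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
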