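# Fixtures are generated in code; nothing is read from disk.

# two Gaussian blobs labeled -1 / +1, optionally with flipped labels
make_binary_blobs <- function(seed, n_per = 25, sep = 2, sd = 1, flip = 0L,
                              role = "train") {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, -sep, sd), n_per, 2),
             matrix(rnorm(n_per * 2, sep, sd), n_per, 2))
  y <- rep(c(-1, 1), each = n_per)
  if (flip > 0) y[seq_len(flip)] <- -y[seq_len(flip)]
  sample_set(X, y, rep(role, 2 * n_per), class_levels = c("-1", "1"))
}

# k well-separated 2-D clusters labeled A, B, C, ...
make_multiclass_set <- function(seed, n_classes = 3, n_per = 15, sd = 0.4,
                                radius = 4, role = "train") {
  set.seed(seed)
  ang <- 2 * pi * seq_len(n_classes) / n_classes
  X <- do.call(rbind, lapply(seq_len(n_classes), function(k)
    cbind(rnorm(n_per, radius * cos(ang[k]), sd),
          rnorm(n_per, radius * sin(ang[k]), sd))))
  lab <- rep(LETTERS[seq_len(n_classes)], each = n_per)
  sample_set(X, lab, rep(role, n_classes * n_per),
             class_levels = LETTERS[seq_len(n_classes)])
}

# a binary_svm whose decision function is identically `bias`
# (one zero support vector, zero dual coefficient, linear kernel)
constant_binary_model <- function(bias, n_vars = 2) {
  structure(list(
    support_vectors = matrix(0, 1, n_vars),
    dual_coefficients = 0,
    bias = bias,
    kernel = kernel_spec("linear"),
    standardize = list(center = rep(0, n_vars), scale = rep(1, n_vars)),
    n_vars = n_vars,
    params = svm_params(1, 1e-6, kernel_spec("linear")),
    rng_seed = 0L,
    dual_full = 0,
    training_summary = list(n_train = 1L, n_misclassified = 0L)),
    class = "binary_svm")
}

toy_gaussian_params <- function(C = 10, epsilon = 1e-6, sigma = 2) {
  svm_params(C, epsilon, kernel_spec("gaussian", sigma = sigma))
}

# small noiseless synthetic config for fast fitness tests
quiet_synth_config <- function(...) {
  synthetic_config(variable_count = 30, class_levels = c(20, 50, 100),
                   counts_per_class_per_role = matrix(
                     c(8, 8, 8, 3, 3, 3, 1, 1, 1), ncol = 3,
                     dimnames = list(c("20", "50", "100"),
                                     c("train", "test", "commercial"))),
                   informative_indices = c(14, 15), noise_sd = 0,
                   redundancy_spread = 0, rng_seed = 42L, ...)
}
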