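test_that("kernels match their closed forms and are symmetric", {
  lin <- kernel_spec("linear")
  gau <- kernel_spec("gaussian", sigma = 1.5)
  pol <- kernel_spec("polynomial", order = 2)
  expect_equal(kernel_eval(lin, c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_eval(pol, c(1, 0), c(1, 0)), 4)
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(4); y <- rnorm(4)
    expect_identical(kernel_eval(gau, x, x), 1)
    for (k in list(lin, gau, pol))
      expect_identical(kernel_eval(k, x, y), kernel_eval(k, y, x))
    # gaussian bounds: 0 < K <= 1, equality iff x == y
    expect_gt(kernel_eval(gau, x, y), 0)
    expect_lt(kernel_eval(gau, x, y), 1)
  }
  expect_error(kernel_eval(lin, 1:2, 1:3), "length mismatch")
  expect_error(kernel_spec("gaussian"), "sigma")
  expect_error(kernel_spec("polynomial", order = 1.5), "order")
})

test_that("a separable toy problem is solved exactly and deterministically", {
  s <- make_binary_blobs(seed = 10, sep = 2.5)
  p <- svm_params(10000, 1e-6, kernel_spec("gaussian", sigma = 2))
  m1 <- train_binary_svm(s, p, rng_seed = 1)
  expect_equal(m1$training_summary$n_misclassified, 0)
  expect_equal(classification_mse(m1, s), 0)
  m2 <- train_binary_svm(s, p, rng_seed = 1)
  expect_identical(m1$dual_coefficients, m2$dual_coefficients)
  expect_identical(m1$bias, m2$bias)
  # deep-interior +1 point scores positive
  expect_gt(decision_value(m1, c(2.5, 2.5)), 0)
  expect_identical(decision_value(m1, c(0.3, -0.2)),
                   decision_value(m1, c(0.3, -0.2)))
  expect_error(decision_value(m1, c(1, 2, 3)), "variables")
})

test_that("free support vectors satisfy |f| = 1 (KKT)", {
  s <- make_binary_blobs(seed = 11, sep = 1.5)
  m <- train_binary_svm(s, svm_params(10, 1e-8,
                                      kernel_spec("gaussian", sigma = 2)))
  # recover which training rows are free SVs via the full dual vector
  free <- which(m$dual_full != 0 & abs(m$dual_full) < 10)
  expect_gt(length(free), 0)
  f <- decision_value(m, s$spectra)
  expect_equal(abs(f[free]), rep(1, length(free)), tolerance = 1e-5)
})

test_that("larger C cannot increase training errors on the flipped-label set", {
  s <- make_binary_blobs(seed = 11, sep = 2, flip = 1L)
  errs <- vapply(c(1e-3, 1e6), function(C)
    train_binary_svm(s, toy_gaussian_params(C = C))$training_summary$n_misclassified,
    numeric(1))
  expect_lte(errs[2], errs[1])
})

test_that("classification_mse matches its definition and a loop oracle", {
  # constant model f(x) = -1 against a single +1 sample: (-1 - 1)^2 / 1 = 4
  m <- constant_binary_model(-1)
  one <- sample_set(matrix(c(0.2, 0.4), 1, 2), "1", "train",
                    class_levels = c("-1", "1"))
  expect_equal(classification_mse(m, one), 4)
  # perfectly separated set gives exactly 0
  s <- make_binary_blobs(seed = 12, sep = 3)
  ms <- train_binary_svm(s, toy_gaussian_params(C = 1000))
  expect_identical(classification_mse(ms, s), 0)
  # independent sample-by-sample loop on a noisy model/set
  noisy <- make_binary_blobs(seed = 13, sep = 0.5)
  mn <- train_binary_svm(noisy, toy_gaussian_params(C = 1))
  y <- as.numeric(as.character(noisy$label))
  acc <- 0
  for (i in seq_len(n_samples(noisy))) {
    fi <- decision_value(mn, noisy$spectra[i, ])
    if (y[i] * fi <= 0) acc <- acc + (fi - y[i])^2
  }
  expect_equal(classification_mse(mn, noisy), acc / n_samples(noisy))
  expect_gt(classification_mse(mn, noisy), 0)
  expect_error(classification_mse(mn, sample_set(matrix(numeric(0), 0, 2),
                                                 character(0), character(0),
                                                 class_levels = c("-1", "1"))),
               "empty")
})

test_that("single-class input is rejected", {
  X <- matrix(rnorm(20), 10, 2)
  s <- sample_set(X, rep("1", 10), rep("train", 10),
                  class_levels = c("-1", "1"))
  expect_error(train_binary_svm(s, toy_gaussian_params()), "both classes")
})

test_that("one-vs-rest training builds one machine per class", {
  s3 <- make_multiclass_set(seed = 20, n_classes = 3)
  m <- train_ovr(s3, toy_gaussian_params(C = 100))
  expect_named(m$per_class, c("A", "B", "C"))
  # missing class is named in the error
  keep <- as.character(s3$label) != "B"
  s_miss <- sample_set(s3$spectra[keep, ], as.character(s3$label)[keep],
                       as.character(s3$role)[keep],
                       class_levels = c("A", "B", "C"))
  expect_error(train_ovr(s_miss, toy_gaussian_params()), "class 'B' absent")
  # two-class symmetry: the two machines are near-mirror images
  s2 <- make_multiclass_set(seed = 21, n_classes = 2)
  m2 <- train_ovr(s2, toy_gaussian_params(C = 10))
  f <- ovr_decision_values(m2, s2$spectra)
  expect_equal(f[, 1], -f[, 2], tolerance = 1e-4)
})

test_that("argmax prediction follows the largest decision value, first-tie", {
  s3 <- make_multiclass_set(seed = 22, n_classes = 3)
  m <- train_ovr(s3, toy_gaussian_params(C = 100))
  # deep inside cluster A
  centers <- t(vapply(c("A", "B", "C"), function(cl)
    colMeans(s3$spectra[s3$label == cl, ]), numeric(2)))
  expect_equal(predict_argmax(m, centers["A", ]), "A")
  # brute-force enumeration oracle over a random batch
  idx <- seq_len(n_samples(s3))
  f <- ovr_decision_values(m, s3$spectra)
  oracle <- m$class_levels[apply(f, 1, function(r) which(r == max(r))[1])]
  expect_identical(predict_argmax(m, s3$spectra), oracle)
  # all decision values equal -> first class wins
  tie <- structure(list(per_class = list(A = constant_binary_model(0.5),
                                         B = constant_binary_model(0.5)),
                        class_levels = c("A", "B")), class = "ovr_svm")
  expect_equal(predict_argmax(tie, c(0, 0)), "A")
})

test_that("strict error counting is at least as severe as argmax", {
  s3 <- make_multiclass_set(seed = 23, n_classes = 3)
  m <- train_ovr(s3, toy_gaussian_params(C = 1000))
  expect_equal(count_strict_errors(m, s3), 0)
  # a sample whose own machine says -1 is an error even if argmax is right
  far <- matrix(c(50, 50), 1, 2)
  s_far <- sample_set(far, "A", "train", class_levels = c("A", "B", "C"))
  f <- ovr_decision_values(m, far)
  if (all(f < 0)) expect_equal(count_strict_errors(m, s_far), 1)
  # property over random sloppy sets
  for (seed in 1:20) {
    noisy <- make_multiclass_set(seed = 100 + seed, n_classes = 3, sd = 3)
    mm <- train_ovr(noisy, toy_gaussian_params(C = 1))
    expect_gte(count_strict_errors(mm, noisy), count_argmax_errors(mm, noisy))
  }
})

test_that("random_parameter_search ranks ascending, deterministically", {
  s3 <- make_multiclass_set(seed = 30, n_classes = 3)
  r <- random_parameter_search(s3, n_combinations = 8, rng_seed = 7)
  expect_equal(nrow(r), 8)
  expect_true(!is.unsorted(r$mse_train))
  expect_equal(r$rank, 1:8)
  # easy separable fixture admits a perfect triple
  expect_equal(r$mse_train[1], 0)
  r2 <- random_parameter_search(s3, n_combinations = 8, rng_seed = 7)
  expect_identical(r, r2)
  r1 <- random_parameter_search(s3, n_combinations = 1, rng_seed = 7)
  expect_equal(nrow(r1), 1)
  expect_error(random_parameter_search(s3, n_combinations = 0), "n_combinations")
  expect_error(random_parameter_search(s3, ranges = list(
    log10_C = c(5, -1), log10_epsilon = c(-7, -2), sigma = c(0.5, 20))),
    "invalid range")
  expect_error(random_parameter_search(s3, ranges = list(
    log10_C = c(-1, 5), log10_epsilon = c(-7, -2), sigma = c(-1, 20))),
    "positive")
})

test_that("model serialization round-trips decision values exactly", {
  s <- make_binary_blobs(seed = 40, sep = 1.2)
  m <- train_binary_svm(s, toy_gaussian_params(C = 50))
  p <- tempfile(fileext = ".json")
  save_svm_model(m, p)
  m2 <- load_svm_model(p)
  expect_identical(decision_value(m2, s$spectra), decision_value(m, s$spectra))
  expect_identical(m2$bias, m$bias)
  expect_identical(m2$dual_coefficients, m$dual_coefficients)
  # one-vs-rest document
  s3 <- make_multiclass_set(seed = 41, n_classes = 3)
  mo <- train_ovr(s3, toy_gaussian_params(C = 100))
  po <- tempfile(fileext = ".json")
  save_svm_model(mo, po)
  mo2 <- load_svm_model(po)
  expect_identical(ovr_decision_values(mo2, s3$spectra),
                   ovr_decision_values(mo, s3$spectra))
  expect_identical(count_strict_errors(mo2, s3), count_strict_errors(mo, s3))
  expect_error(load_svm_model(tempfile()), "file not found")
})
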