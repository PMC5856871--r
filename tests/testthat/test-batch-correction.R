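test_that("the drift smoother reproduces lines and constants exactly", {
  orders <- c(2, 5, 9, 14, 20, 26, 31)
  line <- 3 + 0.7 * orders
  fit <- fit_loess_drift(line, orders, rlsc_params(degree = 1))
  expect_equal(fit$anchor_fitted, line, tolerance = 1e-6)
  # interpolation at intermediate orders stays on the line
  expect_equal(predict(fit, c(3, 7, 17)), 3 + 0.7 * c(3, 7, 17), tolerance = 1e-6)
  # constant extrapolation beyond the anchors
  expect_equal(predict(fit, c(-5, 100)), 3 + 0.7 * c(2, 31), tolerance = 1e-6)

  const <- fit_loess_drift(rep(4.2, 7), orders, rlsc_params())
  expect_equal(predict(const, seq(0, 40, by = 5)), rep(4.2, 9), tolerance = 1e-12)

  expect_error(fit_loess_drift(c(1, 2, 3), c(1, 2, 3), rlsc_params(degree = 2)),
               "degree \\+ 2")
})

test_that("anchor fits agree with an explicit weighted-least-squares oracle", {
  set.seed(303)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    x <- sort(sample(1:200, n))
    y <- 50 + 0.3 * x + rnorm(n, 0, 5)
    span <- sample(c(0.5, 0.75, 1), 1)
    degree <- sample(1:2, 1)
    iters <- sample(0:4, 1)
    fit <- fit_loess_drift(y, x, rlsc_params(span = span, degree = degree,
                                             robust_iterations = iters))
    expect_equal(fit$anchor_fitted,
                 oracle_loess_points(x, y, span, degree, iters),
                 tolerance = 1e-6)
  }
})

drifty_dataset <- function(seed) generate_dataset(synth_preset("drifty", seed))

test_that("RLSC is the identity on drift-free data", {
  set.seed(12)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  types <- rep("STUDY", n); types[seq(5, n, 5)] <- "QC"
  samples <- make_samples(ids, types)
  base <- runif(10, 100, 1000)
  m <- matrix(rep(base, each = n), n, 10, dimnames = list(ids, sprintf("f%02d", 1:10)))
  jitter <- matrix(runif(n * 10, 0.8, 1.2), n, 10)
  jitter[types == "QC", ] <- 1         # constant anchors
  m <- m * jitter
  res <- correct_rlsc(m, samples, rlsc_params())
  expect_equal(res$matrix, m, tolerance = 1e-9)
  expect_identical(res$report$n_cells_invalidated, 0L)
})

test_that("RLSC is scale-equivariant and depends only on the feature itself", {
  ds <- drifty_dataset(1)
  res <- correct_rlsc(ds$matrix, ds$samples, rlsc_params())
  # scale equivariance for one feature
  m2 <- ds$matrix; m2[, 3] <- m2[, 3] * 5
  res2 <- correct_rlsc(m2, ds$samples, rlsc_params())
  expect_equal(res2$matrix[, 3], res$matrix[, 3] * 5, tolerance = 1e-9)
  # permuting other features leaves a feature's correction unchanged
  m3 <- ds$matrix[, c(1, sample(2:ncol(ds$matrix)))]
  res3 <- correct_rlsc(m3, ds$samples, rlsc_params())
  expect_equal(res3$matrix[, 1], res$matrix[, 1], tolerance = 1e-12)
})

test_that("QC-anchored RLSC removes injection-order drift", {
  ds <- drifty_dataset(42)
  res <- correct_rlsc(ds$matrix, ds$samples, rlsc_params())
  qc_ids <- ds$samples$sample_id[ds$samples$sample_type == "QC"]
  before <- feature_rsd(ds$matrix, qc_ids)
  after <- feature_rsd(res$matrix, qc_ids)
  expect_gt(mean(after < before), 0.95)
  # corrected study values track the true (drift-free) signal better
  gt <- ds$ground_truth
  study <- ds$samples$sample_id[ds$samples$sample_type == "STUDY"]
  truthful <- gt$true_intensities[study, ] * gt$dilution[study]
  cor_before <- cor(as.vector(ds$matrix[study, ]), as.vector(truthful))
  cor_after <- cor(as.vector(res$matrix[study, ]), as.vector(truthful))
  expect_gt(cor_after, cor_before)
})

test_that("per-batch RLSC merges analytical blocks with a step offset", {
  ds <- generate_dataset(synth_preset("two-batch", 7))
  res <- correct_rlsc(ds$matrix, ds$samples, rlsc_params(per_batch = TRUE))
  meta <- ds$samples
  qc1 <- meta$sample_id[meta$sample_type == "QC" & meta$batch == "batch1"]
  qc2 <- meta$sample_id[meta$sample_type == "QC" & meta$batch == "batch2"]
  m1 <- colMeans(res$matrix[qc1, ])
  m2 <- colMeans(res$matrix[qc2, ])
  rel_diff <- abs(m1 - m2) / ((m1 + m2) / 2)
  expect_lt(max(rel_diff), 0.05)
})

test_that("batches with too few anchors fall back to median scaling", {
  ids <- sprintf("s%02d", 1:10)
  types <- rep("STUDY", 10); types[c(4, 8)] <- "QC"   # 2 QCs < degree + 2
  samples <- make_samples(ids, types)
  m <- matrix(runif(10 * 3, 100, 200), 10, 3, dimnames = list(ids, c("f1", "f2", "f3")))
  res <- correct_rlsc(m, samples, rlsc_params())
  expect_length(res$report$median_scaling_fallbacks, 3L)
  # single batch: the batch anchor median equals the run anchor median, so the
  # fallback correction cancels exactly
  expect_equal(res$matrix, m, tolerance = 1e-12)
})
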