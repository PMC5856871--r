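test_that("feature_rsd matches hand computations and degenerate contracts", {
  m <- feature_matrix(rbind(c(100, 50, 100, 0), c(120, 50, NA, 0), c(80, 50, NA, 0)),
                      sample_ids = c("q1", "q2", "q3"),
                      feature_ids = c("f_var", "f_const", "f_one", "f_zero"))
  r <- feature_rsd(m, c("q1", "q2", "q3"))
  expect_equal(unname(r["f_var"]), 20)      # sd of (100,120,80) is exactly 20
  expect_equal(unname(r["f_const"]), 0)
  expect_true(is.na(r["f_one"]))            # single observation
  expect_true(is.na(r["f_zero"]))           # mean zero
  expect_error(feature_rsd(m, character()), "at least one")
})

test_that("QC filter applies strict thresholds at the documented defaults", {
  # 6 QCs; f_miss missing in 4/6 (66.7% > 50) -> deleted;
  # f_edge missing in exactly 3/6 (50%) with tiny RSD -> retained;
  # f_rsd20 has RSD exactly 20 -> retained (strict inequality);
  # f_rsd21 slightly above -> deleted
  qc <- sprintf("q%d", 1:6)
  m <- cbind(f_miss = c(100, 110, NA, NA, NA, NA),
             f_edge = c(100, 101, 99, NA, NA, NA),
             f_rsd20 = rep(c(100, 120, 80), 2),
             f_rsd21 = c(100, 130, 75, 100, 130, 75))
  rownames(m) <- qc
  samples <- make_samples(qc, rep("QC", 6))
  res <- filter_by_qc(m, samples)
  kept <- colnames(res$matrix)
  expect_true("f_edge" %in% kept)
  expect_true("f_rsd20" %in% kept)
  expect_false("f_miss" %in% kept)
  expect_false("f_rsd21" %in% kept)
  expect_identical(res$report$n_features_out,
                   res$report$n_features_in - length(res$report$removed_feature_ids))
})

test_that("QC filter 'and' rule only deletes features failing both criteria", {
  qc <- sprintf("q%d", 1:4)
  m <- cbind(f_missonly = c(100, NA, NA, NA),          # miss 75%, RSD undefined... fails both
             f_rsdonly = c(100, 200, 50, 150),          # present everywhere, high RSD
             f_both = c(NA, NA, NA, c(100)))            # 75% missing, 1 obs
  rownames(m) <- qc
  samples <- make_samples(qc, rep("QC", 4))
  res_or <- filter_by_qc(m, samples, qc_filter_params(rule = "or"))
  res_and <- filter_by_qc(m, samples, qc_filter_params(rule = "and"))
  expect_false("f_rsdonly" %in% colnames(res_or$matrix))
  expect_true("f_rsdonly" %in% colnames(res_and$matrix))  # passes missingness
  expect_false("f_both" %in% colnames(res_and$matrix))
})

test_that("QC filter requires QCs and never inspects study intensities", {
  m <- random_feature_matrix(10, 15, 0.2)
  samples_noqc <- make_samples(rownames(m), rep("STUDY", 10))
  expect_error(filter_by_qc(m, samples_noqc), "blank")

  set.seed(11)
  types <- c(rep("QC", 4), rep("STUDY", 6))
  samples <- make_samples(rownames(m), types)
  res1 <- filter_by_qc(m, samples)
  m2 <- m
  study_rows <- rownames(m)[types == "STUDY"]
  m2[study_rows, ] <- m2[sample(study_rows), sample(ncol(m))]
  res2 <- filter_by_qc(m2, samples)
  expect_identical(colnames(res1$matrix), colnames(res2$matrix))
})

test_that("blank filter applies the fold rule and missingness rule", {
  ids <- c("b1", "b2", "s1", "s2", "s3")
  #                 blanks        study
  m <- cbind(f_keep = c(200, 200, 900, 1000, 1100),   # mean 1000 > 3*200
             f_drop = c(200, 200, 400, 500, 600),     # mean 500 <= 600
             f_noblank = c(NA, NA, 50, 60, 70),       # blank mean 0 -> retained
             f_sparse = c(NA, NA, 800, NA, NA))       # missing 66.7% of study > 50
  rownames(m) <- ids
  samples <- make_samples(ids, c("BLANK", "BLANK", "STUDY", "STUDY", "STUDY"))
  res <- filter_by_blank(m, samples, blank_filter_params(fold_factor = 3))
  expect_setequal(colnames(res$matrix), c("f_keep", "f_noblank"))
  expect_error(filter_by_blank(m, make_samples(ids, rep("STUDY", 5)),
                               blank_filter_params(3)), "BLANK")
})

test_that("filters agree with the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(6:20, 1); p <- sample(5:30, 1)
    m <- random_feature_matrix(n, p, runif(1, 0, 0.5))
    n_qc <- sample(2:max(2, n %/% 3), 1)
    n_blank <- sample(1:2, 1)
    types <- c(rep("QC", n_qc), rep("BLANK", n_blank),
               rep("STUDY", n - n_qc - n_blank))
    samples <- make_samples(rownames(m), types)
    max_miss <- sample(c(0, 25, 50, 80), 1)
    max_rsd <- sample(c(10, 20, 50, 100), 1)
    rule <- sample(c("or", "and"), 1)
    res <- filter_by_qc(m, samples, qc_filter_params(max_miss, max_rsd, rule))
    expect_identical(kept_ids(res$matrix),
                     oracle_qc_keep(m, rownames(m)[types == "QC"],
                                    max_miss, max_rsd, rule))
    fold <- sample(c(1, 3, 5), 1)
    resb <- filter_by_blank(m, samples, blank_filter_params(fold, max_miss))
    expect_identical(kept_ids(resb$matrix),
                     oracle_blank_keep(m, rownames(m)[types == "STUDY"],
                                       rownames(m)[types == "BLANK"],
                                       fold, max_miss))
  }
})

test_that("retained set grows monotonically with both QC thresholds", {
  set.seed(5)
  m <- random_feature_matrix(12, 40, 0.3)
  samples <- make_samples(rownames(m), c(rep("QC", 6), rep("STUDY", 6)))
  prev <- character()
  for (thr in c(5, 10, 20, 40, 80)) {
    kept <- colnames(filter_by_qc(m, samples, qc_filter_params(50, thr))$matrix)
    expect_true(all(prev %in% kept))
    prev <- kept
  }
  prev <- character()
  for (thr in c(0, 20, 50, 90, 100)) {
    kept <- colnames(filter_by_qc(m, samples, qc_filter_params(thr, 1e6))$matrix)
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})
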