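test_that("feature_matrix enforces its invariants", {
  m <- feature_matrix(matrix(c(1, 2, NA, 4), 2, 2),
                      sample_ids = c("s1", "s2"), feature_ids = c("f1", "f2"))
  expect_identical(dim(m), c(2L, 2L))
  expect_error(feature_matrix(matrix(1, 2, 2), c("s1", "s1"), c("f1", "f2")),
               "duplicate sample ids")
  expect_error(feature_matrix(matrix(c(1, -2, 3, 4), 2, 2), c("s1", "s2"), c("f1", "f2")),
               "negative")
  expect_error(feature_matrix(matrix(c(1, Inf, 3, 4), 2, 2), c("s1", "s2"), c("f1", "f2")),
               "finite")
  # a stored zero is not missing
  m0 <- feature_matrix(matrix(c(0, 1, 2, 3), 2, 2), c("s1", "s2"), c("f1", "f2"))
  expect_false(anyNA(m0))
})

write_tiny_table <- function(path, sep = ",", blank_at_f2_s1 = TRUE) {
  lines <- c(paste(c("mz", "rt", "s1", "s2"), collapse = sep),
             paste(c("100.5", "30", "11", "12"), collapse = sep),
             paste(c("200.25", "60", if (blank_at_f2_s1) "" else "21", "22"), collapse = sep),
             paste(c("300.125", "90", "31", "32"), collapse = sep))
  writeLines(lines, path)
}

test_that("read_feature_table parses layout, missing cells and ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_table(path)
  res <- read_feature_table(path)
  expect_identical(dim(res$matrix), c(2L, 3L))
  expect_identical(rownames(res$matrix), c("s1", "s2"))
  expect_identical(sum(is.na(res$matrix)), 1L)
  expect_true(is.na(res$matrix["s1", 2]))
  # ids synthesized from m/z and RT
  expect_identical(res$features$feature_id[1], "M100.5000T30.0")
  expect_identical(unname(res$matrix["s2", 3]), 32)
})

test_that("read_feature_table error contracts: absent columns, duplicates, zeros flag", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_table(path)
  expect_error(read_feature_table(path, column_mapping(mz = "mass")), "mass")
  expect_error(read_feature_table(path, column_mapping(mz = "absent_mz")), "absent_mz")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,s1,s1", "100,30,1,2"), dup)
  expect_error(read_feature_table(dup), "duplicate column")

  zeros <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,s1,s2", "100,30,0,5"), zeros)
  expect_true(is.na(read_feature_table(zeros)$matrix["s1", 1]))
  m_keep0 <- read_feature_table(zeros, column_mapping(zeros_as_missing = FALSE))$matrix
  expect_identical(unname(m_keep0["s1", 1]), 0)

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,s1", "100,30,-4"), neg)
  expect_error(read_feature_table(neg), "negative")
})

test_that("sample metadata parsing maps types and enforces uniqueness", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,sample_type,batch,injection_order,class",
               "S1,QC,b1,1,",
               "S2,Sample,b1,2,case",
               "S3,blank,b1,3,",
               "S4,homebrew,b1,4,control"), path)
  s <- read_sample_metadata(path)
  expect_identical(s$sample_type, c("QC", "STUDY", "BLANK", "STUDY"))
  expect_identical(s$class_label[2], "case")
  # vocabulary override
  s2 <- read_sample_metadata(path, type_vocabulary = c(homebrew = "QC"))
  expect_identical(s2$sample_type[4], "QC")

  dup_ord <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,sample_type,batch,injection_order",
               "S1,QC,b1,5", "S2,QC,b1,5"), dup_ord)
  expect_error(read_sample_metadata(dup_ord), "injection_order")

  dup_id <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,sample_type,batch,injection_order",
               "S1,QC,b1,1", "S1,QC,b1,2"), dup_id)
  expect_error(read_sample_metadata(dup_id), "sample_id")
})

test_that("write/read round trip is the identity on intensities, mask and ids", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:8, 1); p <- sample(2:10, 1)
    m <- random_feature_matrix(n, p, miss_rate = runif(1, 0, 0.3))
    features <- data.frame(feature_id = colnames(m),
                           mz = sort(runif(p, 80, 900)), rt = runif(p, 1, 600),
                           stringsAsFactors = FALSE)
    path <- tempfile(fileext = if (rep %% 2) ".csv" else ".tsv")
    write_feature_table(m, features, path)
    back <- read_feature_table(path, column_mapping(id = "feature_id"))
    expect_identical(back$matrix, m)
    expect_equal(back$features$mz, features$mz)
    unlink(path)
  }
})

test_that("stage transforms never mutate their input matrix", {
  set.seed(7)
  m <- random_feature_matrix(8, 10, 0.1)
  snapshot <- m + 0
  samples <- make_samples(rownames(m), c(rep("QC", 3), rep("STUDY", 5)))
  invisible(filter_by_qc(m, samples))
  invisible(impute_small_value(m))
  invisible(normalize_sum(m))
  expect_identical(m, snapshot)
})

test_that("an empty feature list writes a header-only file", {
  m <- matrix(numeric(0), nrow = 2, ncol = 0,
              dimnames = list(c("s1", "s2"), NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(m, data.frame(feature_id = character()), path)
  expect_identical(readLines(path), "feature_id,mz,rt,s1,s2")
})

test_that("stage report invariant and JSONL serialization hold", {
  expect_error(stage_report("x", n_features_in = 10, n_features_out = 8,
                            n_samples_in = 2, n_samples_out = 2,
                            removed_feature_ids = "f1"),
               "inconsistency")
  r <- stage_report("qc_filter", list(max = 50), 10, 8, 2, 2,
                    removed_feature_ids = c("f1", "f2"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_reports_jsonl(list(r, r), path)
  lines <- readLines(path)
  expect_length(lines, 2)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$stage_name, "qc_filter")
  expect_identical(parsed$n_features_out, 8L)
})
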