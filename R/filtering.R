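#' QC filter parameters
#'
#' Pooled QC samples are injected periodically and should contain every signal
#' present in the study samples; a feature that is often missing in QCs or
#' varies strongly across them is inconsistently detected (unstable metabolite
#' or contaminant) and is removed. Defaults are 50% maximum QC missingness and
#' 20% maximum QC RSD. Both criteria use strict inequality for deletion, so a
#' feature sitting exactly on a threshold is retained.
#'
#' @param max_missing_pct delete when missing in *more than* this percentage
#'   of QCs (default 50).
#' @param max_rsd_pct delete when the QC RSD% is *higher than* this threshold
#'   (default 20). Features whose RSD is undefined (fewer than two QC
#'   observations, or mean zero) fail this criterion.
#' @param rule `"or"` (default): a feature is deleted when it fails either
#'   criterion. `"and"`: deleted only when it fails both.
#' @return a `qc_filter_params` list.
#' @export
qc_filter_params <- function(max_missing_pct = 50, max_rsd_pct = 20,
                             rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(max_missing_pct >= 0, max_missing_pct <= 100, max_rsd_pct > 0)
  structure(list(max_missing_pct = max_missing_pct, max_rsd_pct = max_rsd_pct,
                 rule = rule), class = "qc_filter_params")
}

#' Blank filter parameters
#'
#' @param fold_factor a feature is retained only when its mean study intensity
#'   exceeds `fold_factor` times its mean blank intensity. Must be > 0; there
#'   is no universal default, 3 is a common choice.
#' @param max_sample_missing_pct additionally delete features missing in more
#'   than this percentage of study samples (default 50).
#' @param sample_scope which samples the missingness rule and the study mean
#'   use: `"study"` (default) or `"study_qc"`.
#' @return a `blank_filter_params` list.
#' @export
blank_filter_params <- function(fold_factor, max_sample_missing_pct = 50,
                                sample_scope = c("study", "study_qc")) {
  stopifnot(is.numeric(fold_factor), fold_factor > 0,
            max_sample_missing_pct >= 0, max_sample_missing_pct <= 100)
  structure(list(fold_factor = fold_factor,
                 max_sample_missing_pct = max_sample_missing_pct,
                 sample_scope = match.arg(sample_scope)),
            class = "blank_filter_params")
}

#' Per-feature relative standard deviation over a sample subset
#'
#' RSD% = 100 * sd / mean over the subset's non-missing values, using the
#' sample (n-1) standard deviation. Features with fewer than two non-missing
#' values in the subset, or mean 0, get `NA` (undefined).
#'
#' @param m samples x features matrix.
#' @param subset character vector of sample ids (rows of `m`).
#' @return named numeric vector, one RSD% (or `NA`) per feature.
#' @export
feature_rsd <- function(m, subset) {
  if (length(subset) == 0L) stop("`subset` must contain at least one sample id", call. = FALSE)
  absent <- setdiff(subset, rownames(m))
  if (length(absent)) stop("subset samples not in matrix: ", paste(absent, collapse = ", "),
                           call. = FALSE)
  sub <- m[subset, , drop = FALSE]
  apply(sub, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    mu <- mean(x)
    if (mu == 0) return(NA_real_)
    100 * sd(x) / mu
  })
}

#' Filter features on pooled-QC missingness and RSD
#'
#' Deletes features whose signal is missing in more than
#' `params$max_missing_pct` percent of QC samples, or whose relative standard
#' deviation across the QCs exceeds `params$max_rsd_pct` percent (see
#' [qc_filter_params()] for the `rule = "and"` variant). The decision uses QC
#' intensities only; study and blank columns are never inspected.
#'
#' @param m samples x features matrix.
#' @param samples sample metadata (see [read_sample_metadata()]).
#' @param params a [qc_filter_params()].
#' @return list with the filtered `matrix` and a [stage_report()] carrying
#'   per-feature `qc_missing_pct` and `qc_rsd_pct`.
#' @export
filter_by_qc <- function(m, samples, params = qc_filter_params()) {
  validate_feature_matrix(m)
  qc_ids <- intersect(rownames(m), samples_of_type(samples, "QC"))
  if (!length(qc_ids)) {
    stop("no QC samples in the matrix; use filter_by_blank() for QC-free designs",
         call. = FALSE)
  }
  miss_pct <- 100 * colMeans(is.na(m[qc_ids, , drop = FALSE]))
  rsd <- feature_rsd(m, qc_ids)
  fail_miss <- miss_pct > params$max_missing_pct
  fail_rsd <- is.na(rsd) | rsd > params$max_rsd_pct
  drop <- if (params$rule == "or") fail_miss | fail_rsd else fail_miss & fail_rsd
  keep <- !drop
  report <- stage_report(
    "qc_filter",
    parameters = list(max_missing_pct = params$max_missing_pct,
                      max_rsd_pct = params$max_rsd_pct, rule = params$rule,
                      n_qc = length(qc_ids)),
    n_features_in = ncol(m), n_features_out = sum(keep),
    n_samples_in = nrow(m), n_samples_out = nrow(m),
    removed_feature_ids = colnames(m)[drop],
    per_feature_metrics = data.frame(feature_id = colnames(m),
                                     qc_missing_pct = unname(miss_pct),
                                     qc_rsd_pct = unname(rsd),
                                     removed = unname(drop),
                                     stringsAsFactors = FALSE)
  )
  list(matrix = m[, keep, drop = FALSE], report = report)
}

#' Filter features against blank samples
#'
#' For QC-free designs (or as an additional background filter): a feature is
#' retained only when its mean intensity across study samples is strictly
#' higher than its mean blank intensity multiplied by `params$fold_factor`,
#' and it is missing in no more than `params$max_sample_missing_pct` percent
#' of study samples. A feature entirely missing in blanks has blank mean 0 and
#' always passes the fold test; a feature entirely missing in study samples
#' has study mean 0 and fails it.
#'
#' @inheritParams filter_by_qc
#' @param params a [blank_filter_params()].
#' @return list with the filtered `matrix` and a [stage_report()] carrying
#'   per-feature `study_mean`, `blank_mean` and `sample_missing_pct`.
#' @export
filter_by_blank <- function(m, samples, params) {
  validate_feature_matrix(m)
  stopifnot(inherits(params, "blank_filter_params"))
  blank_ids <- intersect(rownames(m), samples_of_type(samples, "BLANK"))
  if (!length(blank_ids)) stop("no BLANK samples in the matrix", call. = FALSE)
  study_ids <- intersect(rownames(m), samples_of_type(samples, "STUDY"))
  if (params$sample_scope == "study_qc") {
    study_ids <- c(study_ids, intersect(rownames(m), samples_of_type(samples, "QC")))
  }
  if (!length(study_ids)) stop("no study samples in the matrix", call. = FALSE)

  mean0 <- function(x) { x <- x[!is.na(x)]; if (length(x)) mean(x) else 0 }
  study_mean <- apply(m[study_ids, , drop = FALSE], 2L, mean0)
  blank_mean <- apply(m[blank_ids, , drop = FALSE], 2L, mean0)
  miss_pct <- 100 * colMeans(is.na(m[study_ids, , drop = FALSE]))

  keep <- (study_mean > params$fold_factor * blank_mean) &
    (miss_pct <= params$max_sample_missing_pct)
  report <- stage_report(
    "blank_filter",
    parameters = list(fold_factor = params$fold_factor,
                      max_sample_missing_pct = params$max_sample_missing_pct,
                      sample_scope = params$sample_scope,
                      n_blank = length(blank_ids), n_study = length(study_ids)),
    n_features_in = ncol(m), n_features_out = sum(keep),
    n_samples_in = nrow(m), n_samples_out = nrow(m),
    removed_feature_ids = colnames(m)[!keep],
    per_feature_metrics = data.frame(feature_id = colnames(m),
                                     study_mean = unname(study_mean),
                                     blank_mean = unname(blank_mean),
                                     sample_missing_pct = unname(miss_pct),
                                     removed = unname(!keep),
                                     stringsAsFactors = FALSE)
  )
  list(matrix = m[, keep, drop = FALSE], report = report)
}
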