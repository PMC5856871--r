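#' Compute a PQN reference spectrum
#'
#' The reference spectrum is the per-feature median intensity over a reference
#' sample set: the pooled QCs when available (the default), or the entire set
#' of samples. Medians are taken over non-missing values; with an even count
#' the median is the mean of the two middle order statistics. Features whose
#' reference value is 0 are flagged and later excluded from the quotient list.
#'
#' @param m samples x features matrix.
#' @param samples sample metadata; required when `source = "qc"`.
#' @param source `"qc"`, `"all"`, or `"auto"` (QCs when present, else all).
#' @return a `reference_spectrum` list with `feature_ids`, `values`, `source`
#'   and the reference `sample_ids`.
#' @export
compute_reference_spectrum <- function(m, samples = NULL,
                                       source = c("auto", "qc", "all")) {
  validate_feature_matrix(m)
  source <- match.arg(source)
  qc_ids <- if (!is.null(samples)) intersect(rownames(m), samples_of_type(samples, "QC")) else character()
  if (source == "auto") source <- if (length(qc_ids)) "qc" else "all"
  if (source == "qc") {
    if (!length(qc_ids)) stop("reference source \"qc\" requires QC samples", call. = FALSE)
    ref_ids <- qc_ids
  } else {
    ref_ids <- rownames(m)
  }
  values <- apply(m[ref_ids, , drop = FALSE], 2L, median, na.rm = TRUE)
  values[!is.finite(values)] <- NA_real_
  structure(list(feature_ids = colnames(m), values = unname(values),
                 source = toupper(source), sample_ids = ref_ids),
            class = "reference_spectrum")
}

#' Probabilistic quotient normalization
#'
#' Estimates a dilution factor per sample and divides it out: (i) a reference
#' spectrum is computed (or supplied); (ii) each observed intensity is divided
#' by the reference value of the same feature, giving a list of quotients per
#' sample; (iii) the sample is divided by the median of its quotients. A
#' sample that is a scalar multiple of the reference is mapped exactly onto
#' the reference. Features with reference value 0 (or missing reference) carry
#' no dilution information and are excluded from the quotient list, but are
#' still divided by the dilution factor so the whole sample stays on one
#' scale. Missing cells stay missing.
#'
#' @param m samples x features matrix.
#' @param reference a [compute_reference_spectrum()] result; computed from `m`
#'   (source `"auto"`) when `NULL`.
#' @param samples sample metadata, used only when `reference` is `NULL`.
#' @return list with the normalized `matrix` and a [stage_report()] recording
#'   each sample's dilution factor.
#' @export
normalize_pqn <- function(m, reference = NULL, samples = NULL) {
  validate_feature_matrix(m)
  if (is.null(reference)) reference <- compute_reference_spectrum(m, samples)
  if (!identical(reference$feature_ids, colnames(m))) {
    stop("reference spectrum is not aligned to the matrix features", call. = FALSE)
  }
  ref <- reference$values
  usable <- !is.na(ref) & ref > 0
  if (!any(usable)) stop("all reference values are 0; PQN is undefined", call. = FALSE)

  d <- vapply(seq_len(nrow(m)), function(s) {
    x <- m[s, ]
    q <- x[usable] / ref[usable]
    q <- q[!is.na(q)]
    if (!length(q)) {
      stop("sample \"", rownames(m)[s], "\" has no usable quotients for PQN", call. = FALSE)
    }
    median(q)
  }, numeric(1))
  out <- m / d
  report <- identity_report(
    "normalize_pqn", m, out,
    parameters = list(method = "pqn", reference_source = reference$source,
                      n_reference_samples = length(reference$sample_ids),
                      n_usable_features = sum(usable)),
    extra = list(dilution_factors = setNames(as.list(d), rownames(m)))
  )
  list(matrix = out, report = report)
}

#' Sum normalization
#'
#' Each feature intensity in a sample is divided by the total non-missing
#' intensity of that sample and multiplied by 100, so every sample's
#' non-missing intensities sum to 100. Missing cells stay missing.
#'
#' @param m samples x features matrix; every sample must have a positive
#'   non-missing total.
#' @return list with the normalized `matrix` and a [stage_report()] recording
#'   each sample's pre-normalization total.
#' @export
normalize_sum <- function(m) {
  validate_feature_matrix(m)
  totals <- rowSums(m, na.rm = TRUE)
  bad <- rownames(m)[totals <= 0]
  if (length(bad)) {
    stop("sample(s) with non-positive total intensity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- 100 * m / totals
  report <- identity_report(
    "normalize_sum", m, out,
    parameters = list(method = "sum", scale = 100),
    extra = list(sample_totals = setNames(as.list(totals), rownames(m)))
  )
  list(matrix = out, report = report)
}
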