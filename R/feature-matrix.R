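#' Construct and validate a feature-intensity matrix
#'
#' The central data structure of the package: a numeric matrix of non-negative
#' intensities oriented samples x features, with row names holding sample ids,
#' column names holding feature ids, and `NA` marking missing (undetected)
#' values. `NA` is distinguishable from a stored intensity of 0: a zero is a
#' measured zero, an `NA` means no value was recorded for that cell.
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#' @param sample_ids,feature_ids character vectors of unique identifiers;
#'   default to the matrix dimnames.
#' @return the validated matrix with dimnames set.
#' @examples
#' m <- feature_matrix(matrix(c(1, 2, NA, 4), 2, 2),
#'                     sample_ids = c("s1", "s2"),
#'                     feature_ids = c("f1", "f2"))
#' @export
feature_matrix <- function(intensities,
                           sample_ids = rownames(intensities),
                           feature_ids = colnames(intensities)) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix (samples x features)", call. = FALSE)
  }
  rownames(intensities) <- sample_ids
  colnames(intensities) <- feature_ids
  validate_feature_matrix(intensities)
  intensities
}

#' Validate the feature-matrix invariants
#'
#' Checks that sample and feature ids are present, unique and non-empty, the
#' matrix is numeric, and every non-missing intensity is finite and >= 0.
#'
#' @param m a samples x features matrix as built by [feature_matrix()].
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_feature_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("feature matrix must be a numeric matrix", call. = FALSE)
  }
  sid <- rownames(m)
  fid <- colnames(m)
  if (is.null(sid) || is.null(fid) || nrow(m) == 0L || ncol(m) == 0L) {
    stop("feature matrix needs non-empty sample ids (rownames) and feature ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "),
         call. = FALSE)
  }
  obs <- m[!is.na(m)]
  if (any(!is.finite(obs))) {
    stop("non-missing intensities must be finite", call. = FALSE)
  }
  if (any(obs < 0)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  invisible(m)
}

# sample ids of a given type, validating presence of required metadata columns
samples_of_type <- function(samples, type) {
  stopifnot(is.data.frame(samples))
  samples$sample_id[samples$sample_type == type]
}

# order-preserving intersection of metadata with matrix rows; errors on samples
# present in the matrix but absent from the metadata
align_samples <- function(m, samples) {
  missing_meta <- setdiff(rownames(m), samples$sample_id)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  samples[match(rownames(m), samples$sample_id), , drop = FALSE]
}
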