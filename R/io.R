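#' Column mapping for deconvolution exports
#'
#' Deconvolution software disagrees on column naming, so the reader takes an
#' explicit mapping from logical roles to column names. `intensity_columns`
#' may be an explicit character vector of sample columns, a single glob
#' pattern (e.g. `"S*"`), or `NULL`, in which case every column not claimed by
#' another role is treated as a sample column.
#'
#' @param mz,rt names of the m/z and retention-time columns.
#' @param drift optional drift-time column (ion-mobility data), or `NULL`.
#' @param id optional feature-id column; when `NULL` ids are synthesized as
#'   `M<mz>T<rt>` with a numeric suffix on collision.
#' @param intensity_columns explicit vector, glob, or `NULL` (see above).
#' @param missing_strings cell values read as missing, besides empty cells.
#' @param zeros_as_missing should stored zeros be interpreted as missing?
#'   Defaults to `TRUE` because most deconvolution tools write 0 for
#'   "not detected"; set to `FALSE` when zeros are measured intensities.
#' @return a `column_mapping` list.
#' @export
column_mapping <- function(mz = "mz", rt = "rt", drift = NULL, id = NULL,
                           intensity_columns = NULL,
                           missing_strings = c("", "NA", "NaN"),
                           zeros_as_missing = TRUE) {
  structure(list(mz = mz, rt = rt, drift = drift, id = id,
                 intensity_columns = intensity_columns,
                 missing_strings = missing_strings,
                 zeros_as_missing = isTRUE(zeros_as_missing)),
            class = "column_mapping")
}

table_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

# header read ahead of read.table so duplicate column names are caught before
# R mangles them with make.unique
read_header <- function(path, sep) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path, call. = FALSE)
  scan(text = first, what = character(), sep = sep, quiet = TRUE,
       strip.white = TRUE, quote = "\"")
}

#' Read a deconvoluted feature table
#'
#' Reads a CSV/TSV with one row per feature (the layout exported by XCMS-style
#' and vendor deconvolution tools) and returns the intensity matrix transposed
#' to samples x features plus a per-feature descriptor table. Empty cells,
#' configured sentinel strings and -- by default -- zeros become `NA`.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param mapping a [column_mapping()].
#' @return a list with elements `matrix` (samples x features, see
#'   [feature_matrix()]) and `features` (data frame with `feature_id`, `mz`,
#'   `rt` and, when mapped, `drift_time`).
#' @export
read_feature_table <- function(path, mapping = column_mapping()) {
  sep <- table_sep(path)
  header <- read_header(path, sep)
  if (anyDuplicated(header)) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "), call. = FALSE)
  }
  for (role in c("mz", "rt", "drift", "id")) {
    col <- mapping[[role]]
    if (!is.null(col) && !col %in% header) {
      stop(sprintf("mapped column \"%s\" (role: %s) not found in %s", col, role, path),
           call. = FALSE)
    }
  }
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   na.strings = mapping$missing_strings, quote = "\"",
                   comment.char = "", stringsAsFactors = FALSE)

  meta_cols <- unlist(mapping[c("mz", "rt", "drift", "id")], use.names = FALSE)
  ic <- mapping$intensity_columns
  if (is.null(ic)) {
    sample_cols <- setdiff(header, meta_cols)
  } else if (length(ic) == 1L && grepl("[*?]", ic)) {
    sample_cols <- grep(utils::glob2rx(ic), header, value = TRUE)
    sample_cols <- setdiff(sample_cols, meta_cols)
  } else {
    absent <- setdiff(ic, header)
    if (length(absent)) {
      stop("intensity columns not found: ", paste(absent, collapse = ", "), call. = FALSE)
    }
    sample_cols <- ic
  }
  if (!length(sample_cols)) stop("no intensity (sample) columns identified in ", path, call. = FALSE)

  mz <- as.numeric(df[[mapping$mz]])
  rt <- as.numeric(df[[mapping$rt]])
  if (any(is.na(mz)) || any(mz <= 0)) stop("m/z values must be positive and non-missing", call. = FALSE)
  if (any(is.na(rt)) || any(rt < 0)) stop("retention times must be >= 0 and non-missing", call. = FALSE)

  if (!is.null(mapping$id)) {
    fid <- as.character(df[[mapping$id]])
  } else {
    fid <- sprintf("M%.4fT%.1f", mz, rt)
  }
  fid <- disambiguate_ids(fid)

  features <- data.frame(feature_id = fid, mz = mz, rt = rt, stringsAsFactors = FALSE)
  if (!is.null(mapping$drift)) features$drift_time <- as.numeric(df[[mapping$drift]])

  intens <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(intens) <- "double"
  if (any(intens[!is.na(intens)] < 0)) {
    stop("negative intensities found in ", path, call. = FALSE)
  }
  if (mapping$zeros_as_missing) intens[intens == 0] <- NA_real_
  m <- t(intens)
  dimnames(m) <- list(sample_cols, fid)
  validate_feature_matrix(m)
  list(matrix = m, features = features)
}

# "M123.4567T12.3" collides for co-eluting isomers; suffix _2, _3, ...
disambiguate_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  out <- ids
  for (dup in unique(ids[duplicated(ids)])) {
    idx <- which(ids == dup)
    out[idx[-1L]] <- paste0(dup, "_", seq_along(idx[-1L]) + 1L)
  }
  out
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]: features as rows, descriptor columns
#' (`feature_id`, `mz`, `rt`, optional `drift_time`) first, then one intensity
#' column per sample. Missing cells are written empty. Numeric values are
#' written with 17 significant digits so that a write/read round trip
#' reproduces every intensity exactly.
#'
#' @param m samples x features matrix.
#' @param features per-feature descriptor data frame aligned with `colnames(m)`.
#' @param path output CSV/TSV path (separator chosen from the extension).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(m, features, path) {
  if (ncol(m) == 0L) {    # empty feature list: header-only file
    header <- c("feature_id", "mz", "rt", rownames(m))
    writeLines(paste(header, collapse = table_sep(path)), path)
    return(invisible(path))
  }
  validate_feature_matrix(m)
  if (!identical(features$feature_id, colnames(m))) {
    stop("`features$feature_id` must match colnames of the matrix in order", call. = FALSE)
  }
  sep <- table_sep(path)
  if (any(grepl(sep, c(rownames(m), colnames(m)), fixed = TRUE))) {
    stop("sample/feature ids must not contain the field separator", call. = FALSE)
  }
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(feature_id = features$feature_id,
                    mz = num(features$mz), rt = num(features$rt),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(features$drift_time)) out$drift_time <- num(features$drift_time)
  for (s in rownames(m)) out[[s]] <- num(m[s, ])
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a CSV/TSV with columns `sample_id`, `sample_type`, `batch`,
#' `injection_order` and optionally `class`. Sample types are parsed
#' case-insensitively through a configurable vocabulary: by default `qc` and
#' `pool` map to QC, `blank` to BLANK, and anything else is a STUDY sample.
#'
#' @param path metadata file.
#' @param type_vocabulary named character vector mapping lower-cased type
#'   strings to `"QC"` or `"BLANK"`.
#' @return data frame with columns `sample_id`, `sample_type` (one of
#'   `"STUDY"`, `"QC"`, `"BLANK"`), `batch`, `injection_order`, `class_label`.
#' @export
read_sample_metadata <- function(path,
                                 type_vocabulary = c(qc = "QC", pool = "QC",
                                                     pooled = "QC", blank = "BLANK")) {
  sep <- table_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  required <- c("sample_id", "sample_type", "batch", "injection_order")
  absent <- setdiff(required, names(df))
  if (length(absent)) {
    stop("sample metadata missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  sid <- as.character(df$sample_id)
  if (anyDuplicated(sid)) {
    stop("duplicate sample_id: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- as.integer(df$injection_order)
  if (any(is.na(ord)) || any(ord < 1L)) {
    stop("injection_order must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(ord)) {
    stop("duplicate injection_order: ", paste(unique(ord[duplicated(ord)]), collapse = ", "),
         call. = FALSE)
  }
  key <- tolower(as.character(df$sample_type))
  stype <- ifelse(key %in% names(type_vocabulary),
                  unname(type_vocabulary[key]), "STUDY")
  data.frame(sample_id = sid,
             sample_type = stype,
             batch = as.character(df$batch),
             injection_order = ord,
             class_label = if ("class" %in% names(df)) as.character(df$class) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write sample metadata
#'
#' Inverse of [read_sample_metadata()] for the columns it defines.
#'
#' @param samples sample metadata data frame.
#' @param path output CSV/TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(samples, path) {
  out <- data.frame(sample_id = samples$sample_id,
                    sample_type = samples$sample_type,
                    batch = samples$batch,
                    injection_order = samples$injection_order,
                    class = samples$class_label,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = table_sep(path), quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
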