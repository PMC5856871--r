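VALID_STAGES <- c("qc_filter", "blank_filter", "impute", "normalize",
                  "batch_correct", "annotate")

#' Validate and default a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent list) describing input paths, the
#' column mapping, an ordered stage list with per-stage parameters, a global
#' seed and an output directory, checks it against the known stage set and
#' parameter ranges, and injects the documented defaults (QC filter 50/20,
#' KNN k = 10, LOESS span 0.75, 5 ppm annotation tolerance, ...).
#'
#' @param config path to a YAML file, or a list with the same structure:
#'   `io: {feature_table, sample_metadata, mapping: {...}, zeros_as_missing}`,
#'   `output_dir`, `seed`, `stages: [{name: ..., <params>}, ...]`.
#' @return the validated, defaulted config list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list", call. = FALSE)

  io <- config$io
  if (is.null(io$feature_table)) stop("io.feature_table is required", call. = FALSE)
  if (is.null(io$sample_metadata)) stop("io.sample_metadata is required", call. = FALSE)
  map <- io$mapping
  mapping <- column_mapping(
    mz = map$mz %||% "mz", rt = map$rt %||% "rt",
    drift = map$drift, id = map$id,
    intensity_columns = unlist(map$intensity_columns),
    zeros_as_missing = io$zeros_as_missing %||% TRUE
  )

  stages <- config$stages
  if (is.null(stages) || !length(stages)) {
    stop("stages: the stage list must be non-empty", call. = FALSE)
  }
  stages <- lapply(seq_along(stages), function(i) {
    st <- stages[[i]]
    where <- sprintf("stages[%d]", i)
    if (is.null(st$name)) stop(where, ".name is required", call. = FALSE)
    if (!st$name %in% VALID_STAGES) {
      stop(where, ": unknown stage \"", st$name, "\"; valid stages: ",
           paste(VALID_STAGES, collapse = ", "), call. = FALSE)
    }
    chk <- function(field, value, lo = -Inf, hi = Inf) {
      if (!is.numeric(value) || value < lo || value > hi) {
        stop(sprintf("%s.%s: value out of range [%s, %s]", where, field, lo, hi),
             call. = FALSE)
      }
      value
    }
    switch(st$name,
      qc_filter = {
        st$max_missing_pct <- chk("max_missing_pct", st$max_missing_pct %||% 50, 0, 100)
        st$max_rsd_pct <- chk("max_rsd_pct", st$max_rsd_pct %||% 20, 1e-12, Inf)
        st$rule <- st$rule %||% "or"
      },
      blank_filter = {
        st$fold_factor <- chk("fold_factor", st$fold_factor %||% 3, 1e-12, Inf)
        st$max_sample_missing_pct <-
          chk("max_sample_missing_pct", st$max_sample_missing_pct %||% 50, 0, 100)
      },
      impute = {
        st$method <- st$method %||% "knn"
        if (!st$method %in% c("sv", "knn", "rf")) {
          stop(where, ".method must be one of sv, knn, rf", call. = FALSE)
        }
        st$k <- as.integer(chk("k", st$k %||% 10, 1, Inf))
        st$ntree <- as.integer(chk("ntree", st$ntree %||% 100, 1, Inf))
        st$max_iter <- as.integer(chk("max_iter", st$max_iter %||% 10, 1, Inf))
      },
      normalize = {
        st$method <- st$method %||% "pqn"
        if (!st$method %in% c("pqn", "sum")) {
          stop(where, ".method must be pqn or sum", call. = FALSE)
        }
        st$reference <- st$reference %||% "auto"
      },
      batch_correct = {
        st$anchor <- st$anchor %||% "qc"
        st$span <- chk("span", st$span %||% 0.75, 1e-12, 1)
        st$degree <- as.integer(chk("degree", st$degree %||% 2, 1, 2))
        st$robust_iterations <-
          as.integer(chk("robust_iterations", st$robust_iterations %||% 4, 0, Inf))
        st$per_batch <- st$per_batch %||% TRUE
      },
      annotate = {
        st$ppm_tol <- chk("ppm_tol", st$ppm_tol %||% 5, 1e-12, Inf)
        st$adducts <- st$adducts %||% "positive"
      }
    )
    st
  })

  structure(list(io = list(feature_table = io$feature_table,
                           sample_metadata = io$sample_metadata,
                           mapping = mapping),
                 output_dir = config$output_dir %||% "metaproc_out",
                 seed = as.integer(config$seed %||% 1L),
                 stages = stages),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the processing pipeline
#'
#' Executes the configured stages in order, each consuming the previous
#' stage's matrix. The conventional order is QC filter, blank filter,
#' imputation, normalization, batch correction, annotation, but the stage
#' list is fully reorderable. One global seed fans out deterministically to
#' per-stage seeds (`seed + stage index`) so a single stage rerun reproduces
#' the full run's behaviour. Writes `processed_matrix.csv`,
#' `annotations.tsv`, `reports.jsonl` and `run.log` to the output directory.
#'
#' @param config a [validate_config()] result, a config list, or a YAML path.
#' @return (invisibly) a list with the final `matrix`, surviving `features`,
#'   `annotations` (data frame or `NULL`), and the list of `reports`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  inp <- read_feature_table(config$io$feature_table, config$io$mapping)
  samples <- read_sample_metadata(config$io$sample_metadata)
  m <- inp$matrix
  features <- inp$features

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("metaproc %s", as.character(packageVersion("metaproc"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("input: %s (%d samples x %d features)",
                         config$io$feature_table, nrow(m), ncol(m)))

  reports <- list()
  annotations <- NULL
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    stage_seed <- config$seed + i
    res <- tryCatch(
      switch(st$name,
        qc_filter = filter_by_qc(m, samples,
                                 qc_filter_params(st$max_missing_pct,
                                                  st$max_rsd_pct, st$rule)),
        blank_filter = filter_by_blank(m, samples,
                                       blank_filter_params(st$fold_factor,
                                                           st$max_sample_missing_pct)),
        impute = switch(st$method,
                        sv = impute_small_value(m),
                        knn = impute_knn(m, k = min(st$k, ncol(m) - 1L)),
                        rf = impute_random_forest(m, ntree = st$ntree,
                                                  max_iter = st$max_iter,
                                                  seed = stage_seed)),
        normalize = if (st$method == "sum") normalize_sum(m) else {
          src <- st$reference
          ref <- compute_reference_spectrum(m, samples, source = src)
          normalize_pqn(m, ref)
        },
        batch_correct = correct_rlsc(m, samples,
                                     rlsc_params(st$anchor, st$span, st$degree,
                                                 st$robust_iterations, st$per_batch)),
        annotate = {
          db <- if (is.null(st$db)) {
            read_compound_table(system.file("extdata", "compounds_synthetic.tsv",
                                            package = "metaproc"))
          } else read_compound_table(st$db)
          adducts <- if (st$adducts %in% c("positive", "negative", "both")) {
            default_adducts(st$adducts)
          } else read_adduct_table(st$adducts)
          feats <- features[match(colnames(m), features$feature_id), , drop = FALSE]
          hits <- search_accurate_mass(feats, db, adducts, st$ppm_tol)
          rep <- identity_report("annotate", m, m,
                                 parameters = list(ppm_tol = st$ppm_tol,
                                                   n_compounds = nrow(db),
                                                   n_adducts = nrow(adducts)),
                                 extra = list(n_hits = nrow(hits),
                                              n_unannotated = length(attr(hits, "unannotated")),
                                              unannotated = attr(hits, "unannotated")))
          list(matrix = m, report = rep, annotations = hits)
        }
      ),
      error = function(e) {
        stop(sprintf("pipeline aborted at stage %d (%s): %s", i, st$name,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    if (!is.null(res$annotations)) annotations <- res$annotations
    m <- res$matrix
    reports[[i]] <- res$report
    log_lines <- c(log_lines,
                   sprintf("stage %d %s: features %d -> %d, samples %d -> %d",
                           i, st$name, res$report$n_features_in,
                           res$report$n_features_out, res$report$n_samples_in,
                           res$report$n_samples_out))
  }

  features_out <- features[match(colnames(m), features$feature_id), , drop = FALSE]
  write_feature_table(m, features_out, file.path(config$output_dir, "processed_matrix.csv"))
  if (!is.null(annotations)) {
    write_annotation_table(annotations, features_out,
                           file.path(config$output_dir, "annotations.tsv"))
  }
  write_reports_jsonl(reports, file.path(config$output_dir, "reports.jsonl"))
  writeLines(log_lines, file.path(config$output_dir, "run.log"))

  invisible(list(matrix = m, features = features_out,
                 annotations = annotations, reports = reports))
}
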