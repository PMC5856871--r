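#' Create a stage report
#'
#' Every processing stage returns, alongside its output matrix, a report
#' recording what it did: the parameters used, feature/sample counts before and
#' after, the ids of removed features, and optional per-feature metrics (e.g.
#' QC RSD%, missing fraction). Reports are serializable as JSON lines and give
#' the pipeline a reproducible provenance trail.
#'
#' @param stage_name short stage identifier, e.g. `"qc_filter"`.
#' @param parameters named list of the parameters the stage ran with.
#' @param n_features_in,n_features_out,n_samples_in,n_samples_out counts.
#' @param removed_feature_ids character vector of deleted feature ids.
#' @param per_feature_metrics optional data frame of per-feature diagnostics.
#' @param extra named list of additional stage-specific entries.
#' @return an object of class `stage_report`.
#' @export
stage_report <- function(stage_name, parameters = list(),
                         n_features_in, n_features_out,
                         n_samples_in, n_samples_out,
                         removed_feature_ids = character(),
                         per_feature_metrics = NULL,
                         extra = list()) {
  if (n_features_out != n_features_in - length(removed_feature_ids)) {
    stop("stage report inconsistency: n_features_out != n_features_in - removed",
         call. = FALSE)
  }
  structure(
    c(list(
      stage_name = stage_name,
      parameters = parameters,
      n_features_in = as.integer(n_features_in),
      n_features_out = as.integer(n_features_out),
      n_samples_in = as.integer(n_samples_in),
      n_samples_out = as.integer(n_samples_out),
      removed_feature_ids = removed_feature_ids,
      per_feature_metrics = per_feature_metrics,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ), extra),
    class = "stage_report"
  )
}

# convenience for stages that neither add nor remove rows/columns
identity_report <- function(stage_name, m_in, m_out, parameters = list(), ...) {
  stage_report(stage_name, parameters,
               n_features_in = ncol(m_in), n_features_out = ncol(m_out),
               n_samples_in = nrow(m_in), n_samples_out = nrow(m_out),
               ...)
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report: %s>\n", x$stage_name))
  cat(sprintf("  features %d -> %d, samples %d -> %d\n",
              x$n_features_in, x$n_features_out, x$n_samples_in, x$n_samples_out))
  if (length(x$removed_feature_ids)) {
    cat(sprintf("  removed %d feature(s)\n", length(x$removed_feature_ids)))
  }
  invisible(x)
}

#' Write stage reports as JSON lines
#'
#' One JSON object per line, one line per stage, in pipeline order.
#'
#' @param reports a list of [stage_report()] objects (a single report is
#'   wrapped automatically).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(reports, path) {
  if (inherits(reports, "stage_report")) reports <- list(reports)
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
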