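#' Small-value replacement imputation
#'
#' Replaces each missing cell of a feature by half of the minimum non-missing
#' value of that feature across all samples — the conventional surrogate for
#' intensities censored below the limit of detection. A per-sample variant
#' (half of the sample's minimum across features) is available for the
#' alternative reading of the rule.
#'
#' @param m samples x features matrix.
#' @param per_sample use the per-sample minimum instead of the per-feature
#'   minimum (default `FALSE`).
#' @return list with the imputed `matrix` and a [stage_report()].
#' @export
impute_small_value <- function(m, per_sample = FALSE) {
  validate_feature_matrix(m)
  check_no_empty_features(m)
  out <- m
  n_imp <- sum(is.na(m))
  if (n_imp > 0) {
    if (per_sample) {
      fill <- apply(m, 1L, min, na.rm = TRUE) / 2
      idx <- which(is.na(out), arr.ind = TRUE)
      out[idx] <- fill[idx[, 1L]]
    } else {
      fill <- apply(m, 2L, min, na.rm = TRUE) / 2
      idx <- which(is.na(out), arr.ind = TRUE)
      out[idx] <- fill[idx[, 2L]]
    }
  }
  report <- identity_report("impute_sv", m, out,
                            parameters = list(method = "sv", per_sample = per_sample),
                            extra = list(n_imputed = n_imp))
  list(matrix = out, report = report)
}

check_no_empty_features <- function(m) {
  empty <- colnames(m)[colSums(!is.na(m)) == 0L]
  if (length(empty)) {
    stop("feature(s) with no observed values cannot be imputed: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
}

# Euclidean distance between two feature columns over co-observed samples,
# with the squared distance rescaled by (total samples / co-observed samples)
# so sparsely co-observed pairs are penalized; Inf when nothing co-observed.
knn_feature_distances <- function(m, j) {
  n <- nrow(m)
  x <- m[, j]
  vapply(seq_len(ncol(m)), function(g) {
    if (g == j) return(Inf)
    y <- m[, g]
    co <- !is.na(x) & !is.na(y)
    nc <- sum(co)
    if (nc == 0L) return(Inf)
    sqrt(sum((x[co] - y[co])^2) * n / nc)
  }, numeric(1))
}

#' K-nearest-neighbour imputation
#'
#' Feature-wise KNN in the style used for expression-type matrices: for each
#' feature with missing entries, the `k` nearest features by Euclidean
#' distance (computed over samples where both features are observed and
#' rescaled by the co-observation count) donate values. The imputed cell is
#' the unweighted mean of the neighbours' observed values in that sample;
#' neighbours missing there are skipped, and when all `k` are missing the
#' feature's own mean over observed samples is used. Distance ties are broken
#' by feature index, so the result is deterministic.
#'
#' @param m samples x features matrix.
#' @param k number of neighbour features (default 10); must be smaller than
#'   the number of features.
#' @return list with the imputed `matrix` and a [stage_report()].
#' @export
impute_knn <- function(m, k = 10) {
  validate_feature_matrix(m)
  check_no_empty_features(m)
  k <- as.integer(k)
  if (k < 1L || k >= ncol(m)) {
    stop("`k` must be a positive integer smaller than the number of features", call. = FALSE)
  }
  out <- m
  feat_mean <- colMeans(m, na.rm = TRUE)
  n_fallback <- 0L
  for (j in which(colSums(is.na(m)) > 0L)) {
    d <- knn_feature_distances(m, j)
    ord <- order(d, seq_along(d))   # tie-break by feature index
    nbrs <- ord[is.finite(d[ord])]
    nbrs <- head(nbrs, k)
    for (s in which(is.na(m[, j]))) {
      donor <- nbrs[!is.na(m[s, nbrs])]
      if (length(donor)) {
        out[s, j] <- mean(m[s, donor])
      } else {
        out[s, j] <- feat_mean[j]
        n_fallback <- n_fallback + 1L
      }
    }
  }
  report <- identity_report("impute_knn", m, out,
                            parameters = list(method = "knn", k = k),
                            extra = list(n_imputed = sum(is.na(m)),
                                         n_mean_fallback = n_fallback))
  list(matrix = out, report = report)
}

#' Iterative random-forest imputation
#'
#' missForest-style scheme: missing cells are initialized with feature means;
#' features are visited in order of ascending missingness, each regressed on
#' all other features over the samples where it was originally observed, and
#' its originally-missing cells replaced by the forest's predictions. Sweeps
#' repeat until the convergence statistic — the sum of squared differences
#' between successive imputed matrices, normalized by the sum of squares of
#' the current matrix — increases, at which point the previous sweep's
#' imputation is returned; `max_iter` caps the number of sweeps.
#'
#' @param m samples x features matrix (at least two features).
#' @param ntree trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param seed integer seed; forests are stochastic, a fixed seed gives
#'   bit-identical output.
#' @return list with the imputed `matrix` and a [stage_report()] whose
#'   `iterations` and `convergence_trace` entries record the stopping
#'   behaviour.
#' @export
impute_random_forest <- function(m, ntree = 100, max_iter = 10, seed = NULL) {
  validate_feature_matrix(m)
  if (ncol(m) < 2L) stop("random-forest imputation needs at least 2 features", call. = FALSE)
  check_no_empty_features(m)
  stopifnot(max_iter >= 1)
  if (!is.null(seed)) set.seed(seed)

  mask <- is.na(m)
  trace <- numeric(0)
  if (!any(mask)) {
    report <- identity_report("impute_rf", m, m,
                              parameters = list(method = "rf", ntree = ntree,
                                                max_iter = max_iter, seed = seed),
                              extra = list(n_imputed = 0L, iterations = 0L,
                                           convergence_trace = trace))
    return(list(matrix = m, report = report))
  }

  # internal syntactic column names keep randomForest's formula-free interface happy
  X <- m
  colnames(X) <- paste0("F", seq_len(ncol(m)))
  feat_mean <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[mask[, j], j] <- feat_mean[j]

  visit <- order(colSums(mask), seq_len(ncol(m)))
  visit <- visit[colSums(mask)[visit] > 0L]

  iters <- 0L
  repeat {
    X_old <- X
    for (j in visit) {
      obs <- !mask[, j]
      rf <- randomForest::randomForest(x = X[obs, -j, drop = FALSE],
                                       y = X[obs, j], ntree = ntree)
      X[mask[, j], j] <- predict(rf, X[mask[, j], -j, drop = FALSE])
    }
    iters <- iters + 1L
    delta <- sum((X - X_old)^2) / sum(X^2)
    trace <- c(trace, delta)
    if (iters > 1L && delta > trace[iters - 1L]) {
      X <- X_old            # return the imputation from before the increase
      iters <- iters - 1L
      break
    }
    if (delta == 0 || iters >= max_iter) break
  }

  out <- m
  out[mask] <- X[mask]
  report <- identity_report("impute_rf", m, out,
                            parameters = list(method = "rf", ntree = ntree,
                                              max_iter = max_iter, seed = seed),
                            extra = list(n_imputed = sum(mask), iterations = iters,
                                         convergence_trace = trace))
  list(matrix = out, report = report)
}
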