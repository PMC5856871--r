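#' RLSC (robust LOESS signal correction) parameters
#'
#' Intensity drift along the injection sequence is smooth and multiplicative;
#' RLSC fits a robust local regression of each feature's intensity on
#' injection order, anchored on the pooled QCs (or on all samples), and
#' divides it out. Defaults are the conventional robust-LOESS configuration:
#' span 0.75, local quadratic, 4 bisquare reweighting passes, fitted per
#' batch.
#'
#' @param anchor `"qc"` (default) or `"all"`: which samples anchor the fit.
#' @param span fraction of anchor points in each local window, in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @param robust_iterations bisquare robustness reweighting passes (>= 0).
#' @param per_batch fit per analytical batch (default) or once across the run.
#' @return an `rlsc_params` list.
#' @export
rlsc_params <- function(anchor = c("qc", "all"), span = 0.75, degree = 2,
                        robust_iterations = 4, per_batch = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(span > 0, span <= 1, degree %in% c(1, 2), robust_iterations >= 0)
  structure(list(anchor = anchor, span = span, degree = as.integer(degree),
                 robust_iterations = as.integer(robust_iterations),
                 per_batch = isTRUE(per_batch)),
            class = "rlsc_params")
}

# Robust local polynomial regression at the anchor points themselves.
# For each anchor x_i: tricube weights over the span-nearest anchors, weighted
# least-squares polynomial of the requested degree centred at x_i, fitted
# value = intercept. Robustness passes downweight large residuals with the
# bisquare function scaled by 6 * median absolute residual.
loess_fit_points <- function(x, y, span, degree, robust_iterations) {
  n <- length(x)
  q <- min(n, max(degree + 1L, ceiling(span * n)))
  rw <- rep(1, n)
  fitted <- numeric(n)
  for (iter in 0:robust_iterations) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      h <- sort(d, partial = q)[q]
      w <- if (h <= 0) as.numeric(d <= 0) else {
        u <- pmin(d / h, 1)
        (1 - u^3)^3
      }
      w <- w * rw
      use <- w > 0
      if (!any(use)) {             # all weight removed by robustness: fall back
        w <- if (h <= 0) as.numeric(d <= 0) else (1 - pmin(d / h, 1)^3)^3
        use <- w > 0
      }
      deg <- min(degree, sum(use) - 1L)
      xc <- x[use] - x[i]
      X <- outer(xc, 0:max(deg, 0L), `^`)
      fit <- lm.wfit(X, y[use], w[use])
      fitted[i] <- fit$coefficients[1L]
    }
    if (iter == robust_iterations) break
    r <- y - fitted
    s <- median(abs(r))
    if (s <= 0) break
    u <- r / (6 * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  fitted
}

#' Fit a drift curve to anchor samples
#'
#' Robust tricube-weighted local polynomial fit of intensity on injection
#' order over the anchor samples, returning a `drift_fit` whose curve is
#' defined for every injection order: linear interpolation between fitted
#' anchor values, constant extrapolation beyond the first/last anchor (clamped
#' rather than extrapolated, to avoid wild polynomial tails for early or late
#' study injections).
#'
#' @param values anchor intensities (non-missing).
#' @param orders anchor injection orders, same length as `values`.
#' @param params an [rlsc_params()].
#' @return a `drift_fit` with `anchor_orders`, `anchor_fitted` and a
#'   `predict(fit, orders)` method.
#' @export
fit_loess_drift <- function(values, orders, params = rlsc_params()) {
  stopifnot(length(values) == length(orders), !anyNA(values), !anyNA(orders))
  if (length(values) < params$degree + 2L) {
    stop("need at least degree + 2 anchor points for a drift fit", call. = FALSE)
  }
  ord <- order(orders)
  x <- as.numeric(orders[ord])
  y <- as.numeric(values[ord])
  f <- loess_fit_points(x, y, params$span, params$degree, params$robust_iterations)
  structure(list(anchor_orders = x, anchor_values = y, anchor_fitted = f,
                 params = params),
            class = "drift_fit")
}

#' @export
predict.drift_fit <- function(object, orders, ...) {
  approx(object$anchor_orders, object$anchor_fitted, xout = as.numeric(orders),
         method = "linear", rule = 2)$y
}

#' QC-anchored LOESS drift and batch correction
#'
#' Per feature and per batch, a robust LOESS curve is fitted to the anchor
#' samples' intensities against injection order ([fit_loess_drift()]), and
#' every sample's intensity is divided by the curve's value at its injection
#' order, then rescaled by the feature's median over the anchor samples of the
#' whole run. The rescaling restores a common, interpretable intensity scale
#' across batches, which is what merges analytical blocks. Batches with fewer
#' than `degree + 2` usable anchors fall back to median scaling (division by
#' the batch anchor median), recorded in the report. Cells whose fitted curve
#' value is not positive are set to missing and counted.
#'
#' @param m samples x features matrix.
#' @param samples sample metadata with injection orders and batches.
#' @param params an [rlsc_params()].
#' @return list with the corrected `matrix` and a [stage_report()] carrying
#'   per-feature QC RSD before/after, the number of invalidated cells, and the
#'   batches that fell back to median scaling.
#' @export
correct_rlsc <- function(m, samples, params = rlsc_params()) {
  validate_feature_matrix(m)
  meta <- align_samples(m, samples)
  if (anyNA(meta$injection_order)) stop("injection orders are required for RLSC", call. = FALSE)

  anchor_ids <- if (params$anchor == "qc") {
    samples_of_type(meta, "QC")
  } else {
    meta$sample_id
  }
  if (!length(anchor_ids)) stop("no anchor samples for RLSC (anchor = \"qc\" needs QCs)", call. = FALSE)

  batches <- if (params$per_batch) split(seq_len(nrow(m)), meta$batch) else list(all = seq_len(nrow(m)))
  is_anchor <- meta$sample_id %in% anchor_ids
  orders <- meta$injection_order

  # run-wide anchor median per feature restores the common scale
  m_f <- apply(m[is_anchor, , drop = FALSE], 2L, median, na.rm = TRUE)

  out <- m
  n_invalid <- 0L
  fallbacks <- character()
  min_anchors <- params$degree + 2L

  for (b in names(batches)) {
    rows <- batches[[b]]
    a_rows <- rows[is_anchor[rows]]
    for (j in seq_len(ncol(m))) {
      av <- m[a_rows, j]
      ok <- !is.na(av)
      if (sum(ok) >= min_anchors) {
        fit <- fit_loess_drift(av[ok], orders[a_rows][ok], params)
        pred <- predict(fit, orders[rows])
      } else {
        med <- if (any(ok)) median(av[ok]) else NA_real_
        pred <- rep(med, length(rows))
        fallbacks <- c(fallbacks, paste0(b, ":", colnames(m)[j]))
      }
      bad <- is.na(pred) | pred <= 0
      corrected <- m[rows, j] / pred * m_f[j]
      corrected[bad] <- NA_real_
      n_invalid <- n_invalid + sum(bad & !is.na(m[rows, j]))
      out[rows, j] <- corrected
    }
  }

  qc_ids <- intersect(rownames(m), samples_of_type(meta, "QC"))
  rsd_before <- if (length(qc_ids) >= 2) feature_rsd(m, qc_ids) else rep(NA_real_, ncol(m))
  rsd_after <- if (length(qc_ids) >= 2) feature_rsd(out, qc_ids) else rep(NA_real_, ncol(m))

  report <- identity_report(
    "batch_correct", m, out,
    parameters = list(anchor = params$anchor, span = params$span,
                      degree = params$degree,
                      robust_iterations = params$robust_iterations,
                      per_batch = params$per_batch, n_batches = length(batches)),
    per_feature_metrics = data.frame(feature_id = colnames(m),
                                     qc_rsd_before = unname(rsd_before),
                                     qc_rsd_after = unname(rsd_after),
                                     stringsAsFactors = FALSE),
    extra = list(n_cells_invalidated = n_invalid,
                 median_scaling_fallbacks = fallbacks)
  )
  list(matrix = out, report = report)
}
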