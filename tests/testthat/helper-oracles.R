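# Independent brute-force oracles used to cross-check the package
# implementations on random small instances. Written as plain per-feature /
# per-point loops, deliberately sharing no code with the package internals.

# random samples x features matrix with a random missing mask
random_feature_matrix <- function(n, p, miss_rate = 0.1) {
  m <- matrix(runif(n * p, 1, 1000), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  if (miss_rate > 0) {
    mask <- matrix(runif(n * p) < miss_rate, n, p)
    # keep at least one observation per feature
    for (j in 1:p) if (all(mask[, j])) mask[sample(n, 1), j] <- FALSE
    m[mask] <- NA_real_
  }
  m
}

kept_ids <- function(m) if (is.null(colnames(m))) character(0) else colnames(m)

make_samples <- function(ids, types, batch = "b1", orders = seq_along(ids)) {
  data.frame(sample_id = ids, sample_type = types, batch = batch,
             injection_order = orders, class_label = NA_character_,
             stringsAsFactors = FALSE)
}

# literal per-feature re-implementation of the QC filter rules
oracle_qc_keep <- function(m, qc_ids, max_miss, max_rsd, rule = "or") {
  keep <- character()
  for (f in colnames(m)) {
    v <- m[qc_ids, f]
    miss_pct <- 100 * sum(is.na(v)) / length(v)
    obs <- v[!is.na(v)]
    rsd <- if (length(obs) >= 2 && mean(obs) != 0) 100 * sd(obs) / mean(obs) else NA_real_
    fail_miss <- miss_pct > max_miss
    fail_rsd <- is.na(rsd) || rsd > max_rsd
    dropped <- if (rule == "or") fail_miss || fail_rsd else fail_miss && fail_rsd
    if (!dropped) keep <- c(keep, f)
  }
  keep
}

oracle_blank_keep <- function(m, study_ids, blank_ids, fold, max_miss) {
  keep <- character()
  for (f in colnames(m)) {
    sv <- m[study_ids, f]; bv <- m[blank_ids, f]
    smean <- if (any(!is.na(sv))) mean(sv, na.rm = TRUE) else 0
    bmean <- if (any(!is.na(bv))) mean(bv, na.rm = TRUE) else 0
    miss_pct <- 100 * sum(is.na(sv)) / length(sv)
    if (smean > fold * bmean && miss_pct <= max_miss) keep <- c(keep, f)
  }
  keep
}

# naive feature-wise KNN imputation following the documented rule
oracle_knn_impute <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  for (j in 1:p) {
    mis <- which(is.na(m[, j]))
    if (!length(mis)) next
    d <- rep(Inf, p)
    for (g in 1:p) {
      if (g == j) next
      co <- which(!is.na(m[, j]) & !is.na(m[, g]))
      if (length(co) > 0) d[g] <- sqrt(sum((m[co, j] - m[co, g])^2) * n / length(co))
    }
    nb <- order(d, 1:p)
    nb <- nb[is.finite(d[nb])][seq_len(min(k, sum(is.finite(d))))]
    for (s in mis) {
      donors <- nb[!is.na(m[s, nb])]
      out[s, j] <- if (length(donors)) mean(m[s, donors]) else mean(m[, j], na.rm = TRUE)
    }
  }
  out
}

# explicit per-point tricube weighted least squares with bisquare reweighting,
# fitted through lm()
oracle_loess_points <- function(x, y, span, degree, robust_iterations) {
  n <- length(x)
  q <- min(n, max(degree + 1, ceiling(span * n)))
  rw <- rep(1, n)
  fitted <- numeric(n)
  for (iter in 0:robust_iterations) {
    for (i in 1:n) {
      d <- abs(x - x[i])
      h <- sort(d)[q]
      w <- if (h <= 0) as.numeric(d <= 0) else (1 - pmin(d / h, 1)^3)^3
      w <- w * rw
      if (all(w == 0)) w <- if (h <= 0) as.numeric(d <= 0) else (1 - pmin(d / h, 1)^3)^3
      df <- data.frame(xc = x - x[i], y = y)
      deg <- min(degree, sum(w > 0) - 1)
      fml <- if (deg == 0) y ~ 1 else if (deg == 1) y ~ xc else y ~ xc + I(xc^2)
      fit <- lm(fml, data = df, weights = w)
      fitted[i] <- unname(coef(fit)[1])
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

# triple loop over (feature, adduct, compound)
oracle_mass_search <- function(features, db, adducts, ppm_tol) {
  rows <- list()
  for (i in seq_len(nrow(features))) {
    for (a in seq_len(nrow(adducts))) {
      obs <- (features$mz[i] * abs(adducts$charge[a]) - adducts$mass_shift[a]) /
        adducts$multimer[a]
      for (c in seq_len(nrow(db))) {
        ppm <- (obs - db$monoisotopic_mass[c]) / db$monoisotopic_mass[c] * 1e6
        if (abs(ppm) <= ppm_tol) {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = features$feature_id[i], compound_id = db$compound_id[c],
            adduct_name = adducts$name[a], ppm_error = ppm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(data.frame(feature_id = character(),
                                       compound_id = character(),
                                       adduct_name = character(),
                                       ppm_error = numeric()))
  do.call(rbind, rows)
}

# canonical string key for comparing hit sets regardless of ordering
hit_key <- function(hits) {
  sort(paste(hits$feature_id, hits$compound_id, hits$adduct_name, sep = "|"))
}
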