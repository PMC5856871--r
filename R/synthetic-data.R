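#' Parameters for the synthetic LC-MS dataset generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' lognormal base abundances with factor-model correlation between features,
#' per-sample dilution, pooled-QC replicates inserted at fixed injection
#' intervals, blanks carrying only contaminant features, smooth multiplicative
#' injection-order drift, multiplicative batch offsets, lognormal measurement
#' noise, limit-of-detection censoring, and additional missingness completely
#' at random. Every corrupting component is stored cell-by-cell in the ground
#' truth, so each stage of the pipeline can be validated against known truth.
#'
#' @param n_study,n_qc,n_blank,n_features design counts. QCs are placed at
#'   every `qc_every`-th injection of the analytical run; blanks precede the
#'   run.
#' @param n_batches contiguous analytical blocks the run is split into.
#' @param qc_every QC injection interval; `n_qc * qc_every` must not exceed
#'   the run length `n_study + n_qc`.
#' @param base_log_mean,base_log_sd lognormal parameters of the per-feature
#'   base abundances.
#' @param feature_correlation common-factor correlation rho of log abundances
#'   between features, in \[0, 1).
#' @param biological_log_sd per-sample biological variation on the log scale.
#' @param dilution_log_sd lognormal sd of the per-sample dilution factors
#'   (study samples only; QCs and blanks are undiluted).
#' @param drift_amplitude relative intensity gain over one batch (e.g. 0.5
#'   means the drift multiplier rises linearly from 1 to 1.5 across a batch).
#' @param batch_offsets multiplicative factor per batch; default all 1.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (mean 1).
#' @param lod_quantile censoring quantile: cells whose noise-free value falls
#'   below this quantile of the positive noise-free values become missing
#'   (mechanism LOD). Zero-valued cells (features absent from blanks) are
#'   always LOD-censored.
#' @param mcar_rate additional completely-at-random missingness among the
#'   remaining observed cells.
#' @param contaminant_fraction fraction of features present in blanks at
#'   sample-comparable intensity.
#' @param seed mandatory integer seed; the whole dataset is deterministic
#'   given the seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_study = 60, n_qc = 12, n_blank = 4, n_features = 100,
                         n_batches = 1, qc_every = 5,
                         base_log_mean = log(1e5), base_log_sd = 1,
                         feature_correlation = 0.5, biological_log_sd = 0.4,
                         dilution_log_sd = 0.2,
                         drift_amplitude = 0, batch_offsets = NULL,
                         noise_cv = 0.05, lod_quantile = 0, mcar_rate = 0,
                         contaminant_fraction = 0.05, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_study >= 1, n_qc >= 0, n_blank >= 0, n_features >= 1, n_batches >= 1,
            feature_correlation >= 0, feature_correlation < 1,
            mcar_rate >= 0, mcar_rate < 1, lod_quantile >= 0, lod_quantile < 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            noise_cv >= 0, drift_amplitude >= 0)
  if (is.null(batch_offsets)) batch_offsets <- rep(1, n_batches)
  if (length(batch_offsets) != n_batches) {
    stop("`batch_offsets` must have one factor per batch", call. = FALSE)
  }
  run_len <- n_study + n_qc
  if (n_qc > 0 && n_qc * qc_every > run_len) {
    stop("qc_every * n_qc exceeds the run length; QCs cannot be placed", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_params")
}

#' Named presets of generator conditions
#'
#' * `clean` — no drift, noise, censoring or blanks; observed equals truth
#'   times dilution.
#' * `drifty` — 160 study + 40 QC injections, 50 features, linear
#'   multiplicative drift of amplitude 0.5 across the run, QC every 5th
#'   injection, 5% noise CV; the drift-correction benchmark.
#' * `two-batch` — as `drifty` but split into two batches with offsets 1 and 2.
#' * `sparse` — correlated features (rho 0.7), 10% MCAR and 5% LOD
#'   missingness; the imputation benchmark.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a [synth_params()] object.
#' @export
synth_preset <- function(name = c("clean", "drifty", "two-batch", "sparse"), seed) {
  name <- match.arg(name)
  switch(name,
    clean = synth_params(n_study = 60, n_qc = 12, n_blank = 0, n_features = 80,
                         noise_cv = 0, drift_amplitude = 0, lod_quantile = 0,
                         mcar_rate = 0, seed = seed),
    drifty = synth_params(n_study = 160, n_qc = 40, n_blank = 0, n_features = 50,
                          qc_every = 5, drift_amplitude = 0.5, noise_cv = 0.05,
                          lod_quantile = 0, mcar_rate = 0, seed = seed),
    `two-batch` = synth_params(n_study = 160, n_qc = 40, n_blank = 0,
                               n_features = 50, qc_every = 5, n_batches = 2,
                               batch_offsets = c(1, 2), drift_amplitude = 0.5,
                               noise_cv = 0.05, seed = seed),
    sparse = synth_params(n_study = 100, n_qc = 20, n_blank = 6, n_features = 100,
                          feature_correlation = 0.7, mcar_rate = 0.1,
                          lod_quantile = 0.05, noise_cv = 0.1,
                          contaminant_fraction = 0.1, seed = seed)
  )
}

#' Generate a synthetic dataset with cell-level ground truth
#'
#' See [synth_params()] for the generative model. The observed value of every
#' non-censored cell factorizes exactly as
#' `true * dilution * drift * batch_offset * noise`, with each component
#' stored in the returned `ground_truth`.
#'
#' @param params a [synth_params()] object.
#' @return list with `matrix` (samples x features, `NA` = missing), `samples`
#'   (metadata, see [read_sample_metadata()]), `features` (descriptors with
#'   m/z and RT), and `ground_truth` (list: `true_intensities`, `dilution`,
#'   `drift`, `batch_offset`, `noise`, `mechanism` — one of OBSERVED/LOD/MCAR
#'   per cell — `contaminant_feature_ids`, `lod_threshold`).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  p <- params
  run_len <- p$n_study + p$n_qc
  n_total <- run_len + p$n_blank

  # injection layout: blanks first, then the run with a QC every qc_every-th slot
  run_pos <- seq_len(run_len)
  qc_pos <- if (p$n_qc > 0) seq(p$qc_every, by = p$qc_every, length.out = p$n_qc) else integer()
  type_run <- rep("STUDY", run_len)
  type_run[qc_pos] <- "QC"
  sample_type <- c(rep("BLANK", p$n_blank), type_run)
  injection_order <- seq_len(n_total)

  ids <- character(n_total)
  ids[sample_type == "BLANK"] <- sprintf("B%02d", seq_len(sum(sample_type == "BLANK")))
  ids[sample_type == "QC"] <- sprintf("QC%03d", seq_len(sum(sample_type == "QC")))
  ids[sample_type == "STUDY"] <- sprintf("S%03d", seq_len(sum(sample_type == "STUDY")))

  # contiguous batches over the whole injection sequence
  batch_idx <- if (p$n_batches == 1L) rep(1L, n_total) else {
    as.integer(cut(injection_order, breaks = p$n_batches, labels = FALSE))
  }
  batch <- sprintf("batch%d", batch_idx)

  fid <- sprintf("F%04d", seq_len(p$n_features))
  features <- data.frame(feature_id = fid,
                         mz = sort(runif(p$n_features, 80, 1000)),
                         rt = runif(p$n_features, 10, 900),
                         stringsAsFactors = FALSE)

  mu <- rlnorm(p$n_features, p$base_log_mean, p$base_log_sd)
  rho <- p$feature_correlation

  true <- matrix(0, n_total, p$n_features, dimnames = list(ids, fid))
  study_rows <- which(sample_type == "STUDY")
  u <- rnorm(length(study_rows))
  e <- matrix(rnorm(length(study_rows) * p$n_features), length(study_rows))
  z <- p$biological_log_sd * (sqrt(rho) * u + sqrt(1 - rho) * e)
  true[study_rows, ] <- exp(sweep(z, 2L, log(mu), `+`))

  # QCs are replicates of the pooled study mean
  pool <- colMeans(true[study_rows, , drop = FALSE])
  qc_rows <- which(sample_type == "QC")
  if (length(qc_rows)) true[qc_rows, ] <- matrix(pool, length(qc_rows), p$n_features, byrow = TRUE)

  # blanks carry only contaminant features, at base-abundance level
  n_cont <- round(p$contaminant_fraction * p$n_features)
  cont_idx <- if (n_cont > 0) sort(sample.int(p$n_features, n_cont)) else integer()
  blank_rows <- which(sample_type == "BLANK")
  if (length(blank_rows) && length(cont_idx)) {
    true[blank_rows, cont_idx] <- matrix(mu[cont_idx], length(blank_rows),
                                         length(cont_idx), byrow = TRUE)
  }

  dilution <- rep(1, n_total)
  dilution[study_rows] <- rlnorm(length(study_rows), 0, p$dilution_log_sd)

  # linear multiplicative drift within each batch: 1 at the first injection of
  # the batch, 1 + amplitude at its last
  drift <- rep(1, n_total)
  if (p$drift_amplitude > 0) {
    for (b in seq_len(p$n_batches)) {
      rows <- which(batch_idx == b)
      span <- max(length(rows) - 1L, 1L)
      drift[rows] <- 1 + p$drift_amplitude * (seq_along(rows) - 1L) / span
    }
  }
  batch_offset <- p$batch_offsets[batch_idx]

  noise <- matrix(1, n_total, p$n_features)
  if (p$noise_cv > 0) {
    sdlog <- sqrt(log(1 + p$noise_cv^2))
    noise <- matrix(rlnorm(n_total * p$n_features, -sdlog^2 / 2, sdlog),
                    n_total, p$n_features)
  }

  noisefree <- true * dilution * drift * batch_offset
  observed <- noisefree * noise

  mechanism <- matrix("OBSERVED", n_total, p$n_features, dimnames = list(ids, fid))
  lod_threshold <- if (any(noisefree > 0)) {
    quantile(noisefree[noisefree > 0], p$lod_quantile, names = FALSE)
  } else 0
  lod <- noisefree < lod_threshold | noisefree == 0
  mechanism[lod] <- "LOD"
  mcar <- !lod & matrix(runif(n_total * p$n_features) < p$mcar_rate, n_total)
  mechanism[mcar] <- "MCAR"
  observed[mechanism != "OBSERVED"] <- NA_real_

  samples <- data.frame(sample_id = ids, sample_type = sample_type,
                        batch = batch, injection_order = injection_order,
                        class_label = NA_character_, stringsAsFactors = FALSE)

  list(matrix = feature_matrix(observed),
       samples = samples,
       features = features,
       ground_truth = list(true_intensities = true,
                           dilution = setNames(dilution, ids),
                           drift = setNames(drift, ids),
                           batch_offset = setNames(batch_offset, ids),
                           noise = noise,
                           mechanism = mechanism,
                           contaminant_feature_ids = fid[cont_idx],
                           lod_threshold = lod_threshold))
}

# curated small-molecule table: real metabolite formulas covering amino acids,
# organic acids, nucleobases, sugars and lipids; all pairwise-distinct
# monoisotopic masses so |ppm|-ranked hits are unambiguous
curated_compounds <- function() {
  tab <- c(
    "water",              "H2O",
    "glucose",            "C6H12O6",
    "alanine",            "C3H7NO2",
    "palmitic acid",      "C16H32O2",
    "cholesterol",        "C27H46O",
    "glycine",            "C2H5NO2",
    "serine",             "C3H7NO3",
    "leucine",            "C6H13NO2",
    "valine",             "C5H11NO2",
    "proline",            "C5H9NO2",
    "phenylalanine",      "C9H11NO2",
    "tyrosine",           "C9H11NO3",
    "tryptophan",         "C11H12N2O2",
    "methionine",         "C5H11NO2S",
    "cysteine",           "C3H7NO2S",
    "lysine",             "C6H14N2O2",
    "arginine",           "C6H14N4O2",
    "histidine",          "C6H9N3O2",
    "glutamine",          "C5H10N2O3",
    "glutamic acid",      "C5H9NO4",
    "aspartic acid",      "C4H7NO4",
    "asparagine",         "C4H8N2O3",
    "threonine",          "C4H9NO3",
    "lactic acid",        "C3H6O3",
    "pyruvic acid",       "C3H4O3",
    "citric acid",        "C6H8O7",
    "succinic acid",      "C4H6O4",
    "fumaric acid",       "C4H4O4",
    "malic acid",         "C4H6O5",
    "2-oxoglutaric acid", "C5H6O5",
    "creatinine",         "C4H7N3O",
    "creatine",           "C4H9N3O2",
    "urea",               "CH4N2O",
    "uric acid",          "C5H4N4O3",
    "hypoxanthine",       "C5H4N4O",
    "xanthine",           "C5H4N4O2",
    "adenine",            "C5H5N5",
    "guanine",            "C5H5N5O",
    "adenosine",          "C10H13N5O4",
    "inosine",            "C10H12N4O5",
    "caffeine",           "C8H10N4O2",
    "cholic acid",        "C24H40O5",
    "stearic acid",       "C18H36O2",
    "oleic acid",         "C18H34O2",
    "linoleic acid",      "C18H32O2",
    "arachidonic acid",   "C20H32O2",
    "myristic acid",      "C14H28O2",
    "glycerol",           "C3H8O3",
    "carnitine",          "C7H15NO3",
    "taurine",            "C2H7NO3S",
    "glucose 6-phosphate","C6H13O9P",
    "AMP",                "C10H14N5O7P",
    "glutathione",        "C10H17N3O6S",
    "sphingosine",        "C18H37NO2",
    "LPC 16:0",           "C24H50NO7P"
  )
  name <- tab[seq(1, length(tab), 2)]
  formula <- tab[seq(2, length(tab), 2)]
  data.frame(compound_id = sprintf("CPD%04d", seq_along(name)),
             name = name, formula = formula,
             monoisotopic_mass = formula_monoisotopic_mass(formula),
             source = "CUSTOM", stringsAsFactors = FALSE)
}

#' Build a compound-table fixture
#'
#' Returns `n` compounds with valid CHNOPS formulas and masses computed via
#' [formula_monoisotopic_mass()]. The first entries come from a fixed curated
#' core of real metabolites (water, glucose, alanine, palmitic acid,
#' cholesterol, ...) with hand-verifiable masses; when `n` exceeds the curated
#' table, random plausible CHNOPS formulas are appended (ids `SYNxxxx`).
#'
#' @param n number of compounds (>= 1).
#' @param seed integer seed for the generated tail.
#' @return compound data frame (see [read_compound_table()] for the columns).
#' @export
make_compound_fixture <- function(n = 50, seed = 1) {
  stopifnot(n >= 1)
  core <- curated_compounds()
  if (n <= nrow(core)) return(core[seq_len(n), , drop = FALSE])
  set.seed(seed)
  extra_n <- n - nrow(core)
  formula <- vapply(seq_len(extra_n), function(i) {
    c_n <- sample(4:40, 1)
    h_n <- sample(seq(max(2, c_n - 4), 2 * c_n + 2), 1)
    parts <- c(sprintf("C%d", c_n), sprintf("H%d", h_n))
    if (runif(1) < 0.6) parts <- c(parts, sprintf("N%d", sample(1:4, 1)))
    if (runif(1) < 0.9) parts <- c(parts, sprintf("O%d", sample(1:10, 1)))
    if (runif(1) < 0.15) parts <- c(parts, sprintf("P%d", sample(1:2, 1)))
    if (runif(1) < 0.15) parts <- c(parts, sprintf("S%d", sample(1:2, 1)))
    paste(parts, collapse = "")
  }, character(1))
  extra <- data.frame(compound_id = sprintf("SYN%04d", seq_len(extra_n)),
                      name = sprintf("synthetic compound %d", seq_len(extra_n)),
                      formula = formula,
                      monoisotopic_mass = formula_monoisotopic_mass(formula),
                      source = "CUSTOM", stringsAsFactors = FALSE)
  rbind(core, extra)
}

#' Write a generated dataset to disk
#'
#' Writes the standard feature table and sample metadata CSVs that the readers
#' and the pipeline consume.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(dataset$matrix, dataset$features,
                      file.path(dir, "feature_table.csv"))
  write_sample_metadata(dataset$samples, file.path(dir, "sample_metadata.csv"))
  invisible(dir)
}
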