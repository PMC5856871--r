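# Monoisotopic masses of the most abundant isotope (IUPAC/CODATA), Da.
ELEMENT_MASSES <- c(
  H = 1.0078250319, D = 2.0141017780, C = 12.0, N = 14.0030740052,
  O = 15.9949146221, P = 30.97376151, S = 31.97207069, F = 18.99840322,
  Cl = 34.96885268, Br = 78.9183376, I = 126.904468, Si = 27.9769265327,
  Na = 22.98976928, K = 38.9637064864, Ca = 39.9625912, Mg = 23.9850419,
  Fe = 55.9349421, Zn = 63.9291466, Cu = 62.9296011, Mn = 54.9380496,
  Co = 58.9332002, Ni = 57.9353479, Se = 79.9165218, B = 11.0093055,
  Li = 7.016004, Al = 26.98153844, As = 74.9215964, Mo = 97.9054078,
  Cr = 51.9405119, Sn = 119.9021966, Hg = 201.970626, Pb = 207.976636
)

ELECTRON_MASS <- 0.00054857990946
PROTON_MASS <- 1.00727646688   # H minus one electron

#' Monoisotopic mass of an elemental formula
#'
#' Parses formulas like `"C6H12O6"` (element symbols with optional integer
#' counts, no parentheses) and sums the masses of the most abundant isotopes
#' (C = 12 exactly, H = 1.0078250319, O = 15.9949146221, ...).
#'
#' @param formula character vector of elemental formulas.
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' formula_monoisotopic_mass("H2O")       # 18.0105647
#' formula_monoisotopic_mass("C6H12O6")   # 180.0633881
#' @export
formula_monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    f <- gsub("[[:space:]]", "", f)
    if (!nzchar(f)) stop("empty formula", call. = FALSE)
    mm <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(mm))[[1]]
    if (paste(tokens, collapse = "") != f) {
      stop("cannot parse formula: \"", f, "\"", call. = FALSE)
    }
    total <- 0
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(ELEMENT_MASSES)) {
        stop("unknown element symbol \"", el, "\" in formula \"", f, "\"", call. = FALSE)
      }
      total <- total + ELEMENT_MASSES[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = !is.null(names(formula)) || length(formula) > 1)
}

#' Default electrospray adduct tables
#'
#' Adducts define the algebra between an observed m/z and the neutral
#' monoisotopic mass M: `mz = (multimer * M + mass_shift) / |charge|`.
#' `mass_shift` is the signed total mass added to the multimer, electrons
#' included (e.g. `[M+H]+` adds a proton, 1.00727647 Da; `[M+Cl]-` adds Cl
#' plus an electron).
#'
#' @param polarity `"positive"`, `"negative"` or `"both"`.
#' @return data frame with columns `name`, `charge`, `multimer`, `mass_shift`.
#' @export
default_adducts <- function(polarity = c("positive", "negative", "both")) {
  polarity <- match.arg(polarity)
  pos <- data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[2M+H]+"),
    charge = c(1L, 1L, 1L, 1L, 1L),
    multimer = c(1L, 1L, 1L, 1L, 2L),
    mass_shift = c(
      PROTON_MASS,
      ELEMENT_MASSES[["Na"]] - ELECTRON_MASS,
      ELEMENT_MASSES[["K"]] - ELECTRON_MASS,
      ELEMENT_MASSES[["N"]] + 4 * ELEMENT_MASSES[["H"]] - ELECTRON_MASS,
      PROTON_MASS
    ),
    stringsAsFactors = FALSE
  )
  neg <- data.frame(
    name = c("[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[2M-H]-"),
    charge = c(-1L, -1L, -1L, -1L),
    multimer = c(1L, 1L, 1L, 2L),
    mass_shift = c(
      -PROTON_MASS,
      ELEMENT_MASSES[["Cl"]] + ELECTRON_MASS,
      ELEMENT_MASSES[["C"]] + ELEMENT_MASSES[["H"]] + 2 * ELEMENT_MASSES[["O"]] + ELECTRON_MASS,
      -PROTON_MASS
    ),
    stringsAsFactors = FALSE
  )
  switch(polarity, positive = pos, negative = neg, both = rbind(pos, neg))
}

validate_adducts <- function(adducts) {
  req <- c("name", "charge", "multimer", "mass_shift")
  absent <- setdiff(req, names(adducts))
  if (length(absent)) stop("adduct table missing column(s): ", paste(absent, collapse = ", "),
                           call. = FALSE)
  if (any(adducts$charge == 0) || any(adducts$multimer < 1)) {
    stop("adducts need |charge| >= 1 and multimer >= 1", call. = FALSE)
  }
  adducts
}

#' Neutral monoisotopic mass of a feature under an adduct hypothesis
#'
#' Inverts the adduct algebra: `M = (mz * |charge| - mass_shift) / multimer`.
#'
#' @param mz observed mass-to-charge ratio (> 0), vectorized.
#' @param adduct one row of an adduct table (or a list with `charge`,
#'   `multimer`, `mass_shift`).
#' @return neutral mass in Da.
#' @export
feature_neutral_mass <- function(mz, adduct) {
  stopifnot(all(mz > 0))
  (mz * abs(adduct$charge) - adduct$mass_shift) / adduct$multimer
}

#' Theoretical m/z of a neutral mass under an adduct
#'
#' Forward direction of the adduct algebra, the exact inverse of
#' [feature_neutral_mass()].
#'
#' @param mass neutral monoisotopic mass in Da, vectorized.
#' @param adduct one row of an adduct table.
#' @return m/z in Da per charge.
#' @export
theoretical_mz <- function(mass, adduct) {
  (mass * adduct$multimer + adduct$mass_shift) / abs(adduct$charge)
}

#' Read a compound database table
#'
#' TSV/CSV with columns `compound_id`, `name`, `formula`,
#' `monoisotopic_mass`, `source` (the layout of HMDB / LIPID MAPS export
#' dumps reduced to the accurate-mass essentials). Either `formula` or
#' `monoisotopic_mass` may be empty per row; a missing mass is computed from
#' the formula, and when both are present they must agree within 0.001 Da.
#'
#' @param path compound table file.
#' @return validated compound data frame.
#' @export
read_compound_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = table_sep(path), check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"", comment.char = "",
                   na.strings = c("", "NA"))
  req <- c("compound_id", "name")
  absent <- setdiff(req, names(df))
  if (length(absent)) stop("compound table missing column(s): ", paste(absent, collapse = ", "),
                           call. = FALSE)
  if (is.null(df$monoisotopic_mass)) df$monoisotopic_mass <- NA_real_
  if (is.null(df$formula)) df$formula <- NA_character_
  if (is.null(df$source)) df$source <- "CUSTOM"
  has_f <- !is.na(df$formula)
  fmass <- rep(NA_real_, nrow(df))
  fmass[has_f] <- formula_monoisotopic_mass(df$formula[has_f])
  fill <- is.na(df$monoisotopic_mass) & has_f
  df$monoisotopic_mass[fill] <- fmass[fill]
  if (any(is.na(df$monoisotopic_mass))) {
    stop("compound(s) with neither formula nor mass: ",
         paste(df$compound_id[is.na(df$monoisotopic_mass)], collapse = ", "), call. = FALSE)
  }
  both <- has_f & !is.na(df$monoisotopic_mass)
  off <- both & abs(fmass - df$monoisotopic_mass) > 0.001
  if (any(off)) {
    stop("formula/mass disagreement > 0.001 Da for: ",
         paste(df$compound_id[off], collapse = ", "), call. = FALSE)
  }
  if (any(df$monoisotopic_mass <= 0)) stop("monoisotopic masses must be > 0", call. = FALSE)
  df
}

#' Read an adduct table
#'
#' TSV/CSV with columns `name`, `charge`, `multimer`, `mass_shift` (Da,
#' signed, electrons included).
#'
#' @param path adduct table file.
#' @return validated adduct data frame.
#' @export
read_adduct_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = table_sep(path), check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  validate_adducts(df)
}

#' Accurate-mass annotation of features
#'
#' For every feature x adduct hypothesis the observed neutral mass is computed
#' and matched against the compound table: a hit is emitted for every compound
#' whose monoisotopic mass `m` satisfies `|observed - m| / m * 1e6 <= ppm_tol`.
#' One feature can therefore collect hits under several adducts; no scoring
#' beyond the ppm error is applied. Hits are sorted per feature by absolute
#' ppm error, ties broken by `compound_id`.
#'
#' @param features data frame with `feature_id` and `mz` (plus anything else,
#'   e.g. `rt`, carried through unused).
#' @param db compound data frame (see [read_compound_table()]).
#' @param adducts adduct data frame (see [default_adducts()]).
#' @param ppm_tol symmetric mass tolerance in parts per million (default 5,
#'   typical Q-TOF accuracy).
#' @return data frame of hits (`feature_id`, `compound_id`, `compound_name`,
#'   `adduct_name`, `observed_neutral_mass`, `ppm_error`) with the unannotated
#'   feature ids in `attr(, "unannotated")`.
#' @export
search_accurate_mass <- function(features, db, adducts = default_adducts("positive"),
                                 ppm_tol = 5) {
  if (!nrow(db)) stop("compound database is empty", call. = FALSE)
  stopifnot(ppm_tol > 0)
  validate_adducts(adducts)
  ord <- order(db$monoisotopic_mass)
  mass <- db$monoisotopic_mass[ord]
  tol <- ppm_tol * 1e-6

  hits <- vector("list", nrow(adducts))
  for (a in seq_len(nrow(adducts))) {
    add <- adducts[a, ]
    obs <- feature_neutral_mass(features$mz, add)
    # |obs - m| <= tol * m  <=>  m in [obs / (1 + tol), obs / (1 - tol)]
    lo <- findInterval(obs / (1 + tol), mass, left.open = TRUE) + 1L
    hi <- findInterval(obs / (1 - tol), mass)
    rows <- which(hi >= lo)
    if (!length(rows)) next
    hits[[a]] <- do.call(rbind, lapply(rows, function(i) {
      idx <- ord[lo[i]:hi[i]]
      data.frame(feature_id = features$feature_id[i],
                 compound_id = db$compound_id[idx],
                 compound_name = db$name[idx],
                 adduct_name = add$name,
                 observed_neutral_mass = obs[i],
                 ppm_error = (obs[i] - db$monoisotopic_mass[idx]) /
                   db$monoisotopic_mass[idx] * 1e6,
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(feature_id = character(), compound_id = character(),
                      compound_name = character(), adduct_name = character(),
                      observed_neutral_mass = numeric(), ppm_error = numeric(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(match(res$feature_id, features$feature_id),
                   abs(res$ppm_error), res$compound_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unannotated") <- setdiff(features$feature_id, res$feature_id)
  res
}

#' Write an annotation table
#'
#' Hits joined to the feature descriptors (m/z, RT), TSV.
#'
#' @param hits result of [search_accurate_mass()].
#' @param features feature descriptor data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(hits, features, path) {
  idx <- match(hits$feature_id, features$feature_id)
  out <- cbind(hits[, "feature_id", drop = FALSE],
               mz = features$mz[idx], rt = features$rt[idx],
               hits[, setdiff(names(hits), "feature_id"), drop = FALSE])
  num <- c("mz", "rt", "observed_neutral_mass", "ppm_error")
  for (cn in num) out[[cn]] <- sprintf("%.6f", out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
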