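---
title: "Methods and design of metaproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of metaproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metaproc` processes a deconvoluted feature-intensity matrix — the table that
XCMS-style or vendor software produces from raw LC–MS/GC–MS data — into an
analysis-ready matrix. This vignette explains the statistical model behind
each stage, the tunable parameters and why their defaults are what they are,
the design decisions that were genuinely open, and what the synthetic-data
generator does and does not prove about real data.

## Data model

The working object is an ordinary numeric matrix oriented **samples ×
features**, with `NA` marking a missing (unrecorded) value. A measured zero is
kept as 0 and is distinct from `NA`. On disk the package reads and writes the
common deconvolution-export layout (features as rows, one intensity column per
sample, empty cells for missing values); whether stored zeros should be read
as missing is a reader flag, `zeros_as_missing`, defaulting to `TRUE` because
most deconvolution tools write 0 for "not detected". Deconvolution tools
disagree on this convention and input files rarely document it, so it is a
flag rather than a guess.

Sample metadata carries the run structure: a type (`STUDY`, `QC`, `BLANK`), a
batch identifier, and a unique injection order. Pooled QCs are aliquots of a
mixture of the study samples injected at regular intervals; blanks contain no
biological material. Every stage returns, besides its output matrix, a
`stage_report` (parameters, feature/sample counts in and out, removed ids,
per-feature metrics, timestamp) serialized as JSON lines by the pipeline — the
provenance trail for a documented, reproducible analysis.

No stage mutates its input; all transforms return new matrices, so stages
compose and reorder freely.

## Feature filtering

Because pooled QCs should contain every signal present in the study samples,
a stable instrument detects each genuine feature in (nearly) every QC with
modest variation; features that fail this are unstable metabolites or
contaminants. The QC filter deletes a feature when

* its missing fraction among QCs exceeds `max_missing_pct` (default **50%**), or
* its RSD% across QCs (100 · sd/mean over non-missing QC values, sample
  standard deviation) exceeds `max_rsd_pct` (default **20%**).

Both comparisons are strict ("more than", "higher than"), so a feature sitting
exactly on a boundary is retained. A feature with fewer than two QC
observations, or QC mean zero, has undefined RSD and fails the RSD criterion —
by construction it is inconsistently detected. The two criteria are applied as
independent deletion rules (`rule = "or"`) by default; this matches the
stated rationale (either instability *or* contamination flags a feature) and
universal QC-filtering practice, but a conjunctive `rule = "and"` is available
since the prose description of the method can be read either way.

The blank filter serves QC-free designs: a feature is retained only when its
mean study intensity strictly exceeds `fold_factor` times its mean blank
intensity, and its missing fraction among study samples is at most
`max_sample_missing_pct`. `fold_factor` has no universal default and is a
required argument (3 is a common choice). A feature entirely missing in blanks
gets blank mean 0 and always passes the fold test; "samples" means study
samples by default (`sample_scope = "study_qc"` widens it). Missing
percentages are always computed against the count of samples of the relevant
type, never the whole run.

Note an interplay with stage order: the QC filter acts on raw intensities, so
severe uncorrected drift or large batch offsets inflate every feature's QC RSD
and can legitimately remove most of the matrix. With multi-batch data either
raise `max_rsd_pct`, or reorder the stages so batch correction runs first —
the pipeline permits any order.

## Missing-value imputation

Missingness in feature matrices arises from class-dependent absence,
censoring below the detection limit, and deconvolution failures. Three
imputers are provided:

* **Small-value replacement (SV)**: each missing cell of a feature becomes
  half the feature's minimum observed value — the conventional surrogate for
  left-censored values. The phrase "minimum value found for a given feature in
  given sample" is grammatically ambiguous between a per-feature and a
  per-sample minimum; the per-feature reading (the standard one for
  feature-wise detection limits) is the default and a `per_sample` flag gives
  the other.
* **K-nearest neighbours (KNN)**, feature-wise, following the convention of
  KNN imputers for expression-style matrices: distances between feature
  columns are Euclidean over co-observed samples, with the squared distance
  rescaled by (total samples / co-observed samples) so sparsely co-observed
  pairs are penalized. The `k` (default 10) nearest features donate the
  unweighted mean of their observed values in the target sample; when all
  neighbours are missing there, the feature's own mean is used. Ties in
  distance break by feature index, making the method fully deterministic.
* **Random forest (RF)**, the missForest-style iterative scheme: initialize
  missing cells with feature means, visit features in ascending missingness,
  regress each on all others over its originally-observed rows (100 trees by
  default) and predict its missing cells; sweep until the convergence
  statistic Δ = Σ(X_new − X_old)² / ΣX_new² increases, then return the
  previous sweep (cap `max_iter = 10`). A fixed seed gives bit-identical
  output.

No imputer ever alters an observed cell, and all are no-ops on complete
matrices. Log-transformation before KNN/RF is deliberately not applied by
default — raw intensity space is where the SV semantics live — and imputation
is expected to run after filtering, so features with no observations at all
(an error for every imputer) have normally been removed. On the synthetic
generator's correlated data (ρ = 0.7, 10% MCAR), KNN and RF reach a
normalized RMSE against ground truth well below SV's (about 0.8 and 0.3
versus 1.1 averaged over ten seeds in the acceptance run), which is the
expected ordering: SV is only appropriate for censoring-type missingness.

## Normalization

**PQN.** Sample-to-sample dilution (urine concentration, extraction yield) is
a per-sample multiplicative factor. PQN estimates it robustly: (i) build a
reference spectrum as the per-feature median over the QCs when present
(`source = "auto"`), else over all samples; (ii) divide each observed
intensity by its reference value, giving the sample's quotient list; (iii)
divide the sample by the median quotient. Even-count medians are the mean of
the two middle order statistics throughout. Features with reference value 0
carry no dilution information and are excluded from the quotient list but are
still divided by the dilution factor, keeping the sample on a single scale.
Quotients are computed over observed cells only, so PQN tolerates missing
values and the stages can be reordered around imputation. Algebraically, a
sample proportional to the reference maps exactly onto the reference, the
post-normalization median quotient is 1, and pre-multiplying any sample by
c > 0 changes nothing — these identities are asserted to 1e-9 in the tests.

**Sum normalization** divides each sample by its total observed intensity and
multiplies by 100, so every sample's observed total becomes exactly 100.

## Drift and batch correction (RLSC)

LC–MS intensity drifts smoothly along the injection sequence (source fouling,
column ageing), and separately measured blocks sit at different overall
levels. Because these effects are multiplicative on intensity, the correction
is ratio-based: per feature and per batch, a robust LOESS curve `f(order)` is
fitted to the anchor samples (QCs by default, `anchor = "all"` otherwise) and
each intensity becomes `x / f(order) × m_f`, where `m_f` is the feature's
median over the anchor samples of the whole run. Dividing by the batch-local
curve removes drift; rescaling by the run-wide `m_f` puts all batches back on
one interpretable scale, which is what merges blocks.

The smoother is the conventional robust local regression: at each anchor
point, a tricube-weighted least-squares polynomial over the `span` fraction of
nearest anchors (default 0.75), local degree 2, followed by 4 bisquare
reweighting passes on the residuals (scale 6 × median |residual|). Between
anchors the curve is linearly interpolated; beyond the first/last anchor it is
clamped constant, avoiding wild polynomial tails for early and late study
injections. These defaults are the standard robust-LOESS configuration; the
original description of QC-based LOESS correction leaves them to the
implementation, so all are exposed. A batch with fewer than `degree + 2`
usable anchors for a feature falls back to median scaling for that feature and
batch, recorded in the report. Fitted values ≤ 0 would produce negative
intensities, so those cells are set missing and counted instead.

Correction is applied per batch by default (`per_batch = TRUE`); a single
global fit is available when batches are contiguous segments of one drift
regime. The stage computes each feature's QC RSD before and after as its
effectiveness metric: on the `drifty` preset (amplitude 0.5 drift, QC every
5th injection) correction reduces QC RSD for >95% of features, and on the
`two-batch` preset (offsets 1 and 2) the per-feature QC means of the two
batches agree within 5% afterwards.

## Accurate-mass annotation

An observed ion relates to a neutral molecule M through an adduct: m/z =
(n·M + shift)/|z|, where n is the multimer count and the signed shift includes
electrons (proton 1.00727646 Da). For each feature × adduct hypothesis the
neutral mass is inverted and every compound whose monoisotopic mass lies
within `ppm_tol` (default 5 ppm, typical Q-TOF accuracy) is emitted as a hit,
sorted by |ppm error| with ties broken by compound id. All adduct hypotheses
are reported — there is deliberately no scoring beyond the mass error, because
accurate mass alone cannot adjudicate between exactly isobaric hypotheses:
e.g. a protonated hexose and a proton-bound dimer of a triose-acid have
identical elemental composition. Such coincidences are real and several exist
even in the bundled 55-compound table; users are expected to resolve them with
retention time or MS/MS evidence downstream.

Formula masses are computed from a table of most-abundant-isotope masses
(C = 12 exactly, H = 1.0078250319, O = 15.9949146221, ...) by a small parser
over `SymbolCount` tokens; the compound reader accepts HMDB/LIPID MAPS-style
tables with either a formula or a mass per row and cross-validates the two to
0.001 Da when both are present. Default adduct sets are [M+H]+, [M+Na]+,
[M+K]+, [M+NH4]+, [2M+H]+ and [M−H]−, [M+Cl]−, [M+HCOO]−, [2M−H]−, fully
replaceable via a TSV. The search is interval-indexed over the mass-sorted
compound table and is tested to return exactly the hit set of a brute-force
triple loop.

The bundled `compounds_synthetic.tsv` is a stand-in for a real database dump:
55 real small-molecule formulas (amino acids, organic acids, nucleobases,
sugars, lipids) with ids `CPDxxxx` and masses computed by the package's own
formula function. It exists so annotation is testable offline; it is not a
curated reference resource.

## The synthetic-data generator

`generate_dataset()` draws per-feature base abundances from a lognormal
(meanlog log(1e5), sdlog 1 — spanning the 3–4 decades typical of untargeted
data), gives study samples a factor-model log-scale correlation ρ (one shared
factor per sample, default ρ = 0.5; the imputation benchmark uses 0.7), a
per-sample lognormal dilution factor (sd 0.2), and multiplies in a linear
per-batch drift curve, per-batch offsets, and mean-1 lognormal measurement
noise (CV 5% by default). QCs are replicates of the pooled study mean placed
every `qc_every`-th injection; blanks precede the run and contain only a
contaminant subset of features at sample-comparable intensity. Censoring
below a detection-limit quantile operates on the *noise-free* value, so the
threshold is a knowable ground-truth property; additional MCAR missingness is
applied on top. Every multiplicative component and the per-cell missingness
mechanism are stored, so the observed matrix factorizes exactly and each
stage can be scored against truth. Drift is multiplicative and smooth by
construction because that is the regime RLSC's ratio correction assumes.

The presets freeze the benchmark conditions: `clean` (no corruption beyond
dilution, and no blanks — blanks necessarily carry missing cells, which would
contradict the preset's no-missing contract), `drifty` (160 study + 40 QC
injections, 50 features, amplitude 0.5, CV 5%), `two-batch` (adding offsets 1
and 2), and `sparse` (ρ 0.7, 10% MCAR, 5% LOD). These sizes keep the full
validation suite at a few minutes on one core while leaving the effects far
larger than their estimation error.

What passing these tests does **not** show about real data: the generator's
drift is smooth and strictly multiplicative (real drift can jump after
maintenance), QCs are ideal pool replicates (real QCs evaporate and degrade),
missingness is exactly LOD-plus-MCAR (real data has class-dependent absence),
and annotation features carry exact theoretical m/z (real mass error is the
reason the ppm window exists). The suite validates the algorithms, not the
biology.

## Numerical choices and edge cases

* Tables are written with 17 significant digits, so a write→read round trip
  reproduces every double exactly; missing cells are empty fields.
* Feature ids synthesized as `M<mz>T<rt>` get `_2`, `_3`, ... suffixes on
  collision (co-eluting isomers).
* The pipeline's single seed fans out as `seed + stage index`, so rerunning
  one stage in isolation reproduces its in-pipeline behaviour; with a fixed
  config and seed the output tables are byte-identical across runs (stage
  reports carry wall-clock timestamps and are excluded from that guarantee).
* RSD, blank means and reference medians are computed over non-missing values
  only; an all-missing blank profile counts as blank mean 0, not undefined.
* In the planted-compound recovery experiment, a feature synthesized from an
  exactly isobaric (compound, adduct) pair still ranks its generating
  hypothesis first because its inversion arithmetic is exact to rounding while
  the rival hypothesis accumulates a few ulps of element-mass summation error;
  with real (noisy) masses both would tie and the ambiguity stands.

## Known limitations

* No isotope-pattern or MS/MS scoring, no retention-time prediction; the
  annotation stage is accurate-mass only.
* No ComBat-style location/scale batch correction; batches with no usable
  anchors for a feature lose that feature's cells in that batch.
* KNN imputation is O(p² n) — fine for the thousands of features typical of
  deconvolution exports, but not for raw centroid data.
* Missingness-mechanism diagnostics (MCAR vs MNAR) are out of scope; the user
  chooses the imputer.
* Peak picking/deconvolution is upstream of this package: it begins at the
  exported feature table.
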