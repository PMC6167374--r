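---
title: "Models and methods behind marrowquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind marrowquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowquant)
```

marrowquant implements the quantification and statistics layer of an
isobaric-label (TMT 6-plex) proteomics study of sorted bone marrow cell
populations across an adult ageing cohort, together with the matched
single-cell RNA analyses of lineage priming. This vignette explains the
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the procedures left genuine freedom.

## Study design the package assumes

Six cell populations (HPC, LYM, MON, GRA, ERP, MSC) are sorted per donor.
Within a population, peptides from five donors plus a pooled internal
standard are labelled with the six TMT channels (126 = internal standard,
127–131 = donors) and measured together as one batch. A cohort of 59
donors aged 20–60 therefore yields around twelve batches per population.
Because every batch carries the same internal standard, donor/standard
ratios are comparable across batches.

## TMT quantification chain

The chain starts from PSM (peptide-spectrum match) tables:

1. **Quality gates** (`filter_psms()`): search rank 1 for identification;
   for quantification additionally isolation interference < 30 %, summed
   donor-channel intensity (127–131) > 30,000, and no missed cleavages.
   The intensity sum is taken over observed values; imputation follows the
   filter, not the other way round, so a spectrum cannot be rescued by its
   own imputed values.
2. **Imputation** (`impute_missing_reporters()`): a missing donor-channel
   value becomes the minimum reporter intensity observed in channels
   127–131 of the same batch. Channel 126 is never imputed.
3. **Median-ratio normalization** (`normalize_psm_ratios()`): per PSM and
   channel c the ratio $I_c/I_{126}$ is multiplied by the batch median of
   the *raw* $I_{126}/I_c$ ratios. Imputed cells are excluded from the
   medians (they are flagged by the imputation step for exactly this
   purpose). For positive values and an odd PSM count the per-channel
   median ratio after normalization is exactly 1, because the median
   commutes with the reciprocal; with even counts the two-middle-value
   convention applies. Floating point leaves this identity intact to about
   one ulp, which is what the tests assert.
4. **Peptide rollup** (`rollup_peptides()`): one PSM passes through; with
   two or more, the median of the (at most three) PSMs with highest
   precursor area is used, the same PSM selection for all channels. Area
   ties are broken by spectrum id so the result is deterministic.
5. **Protein rollup** (`rollup_proteins()`): the median over peptides
   unique to the protein group; at least two unique peptides are required.
   Protein grouping is taken from the input's gene-symbol column as-is.
6. **Studentization** (`studentize_matrix()`): per protein, all samples of
   one population are transformed to mean 0 / sd 1. Zero-variance rows are
   dropped rather than zeroed — they carry no age signal and a 0/0 is
   undefined. Mean normalization (`mean_normalize_matrix()`, row/rowmean)
   is kept separate: it preserves scale so that regression slopes read as
   relative change per year, which studentization would destroy by
   inflating slopes of barely-varying proteins.

## Label-free abundance scores

TMT ratios compare the same protein across donors but say nothing about
relative abundance between proteins or populations. The hybrid label-free
(LF) score fills that gap: each peptide's precursor (MS1) area is split
across the six channels proportionally to its reporter intensities
(conserving the total exactly), donor channels are rescaled by the same
batch median ratios as the TMT chain, and the protein score is the summed
area of its unique peptides divided by the number of *observable* tryptic
peptides — fragments of length 8–25 with no missed cleavage, cleaving
after K/R but not before P (Keil rule). Division by the observable count
makes scores comparable between proteins of different tryptic geometry,
the same idea that drives iBAQ-style metrics. Whether the division happens
before or after the per-run aggregation is algebraically irrelevant for
sum-based rollups; the package aggregates first, then divides, then sums.
Scores are log2-transformed, the per-batch median subtracted, and LF sums
per population divide by the maximum number of donors available so that
populations with incomplete donor coverage are not inflated.

Missing LF values stay missing: minimum-value imputation is a TMT-ratio
device and would bias MS1 areas.

## Sample QC and outlier rejection

PCA runs on log2 values of proteins quantified in all samples of a
population, rows centred and not scaled; restricting to complete rows
avoids letting imputation shape the components. On (PC1, PC2) a Gaussian
product-kernel density with Scott's bandwidth ($h_j = s_j\,n^{-1/6}$) is
evaluated at the samples themselves, and highest-density regions follow
the density-quantile construction: the L % region is bounded by the
(1−L/100) quantile of the sample densities. A sample outside the 97 %
region is discarded. Note the estimator's intrinsic behaviour: on a clean
Gaussian cloud it flags roughly the lowest-density 3 % of samples — the
null flag rate the tests check sits in the 1–6 % band by construction, not
by luck. Degenerate densities (zero variance) flag nothing and warn.

## Age-association statistics

Per protein and population, Spearman's rank correlation between ratios
and donor ages, with a two-sided p from the t approximation (adequate and
deterministic at n ≈ 40–59; average ranks for ties), computed only when
donor coverage exceeds 15 % strictly. Slopes come from ordinary least
squares on mean-normalized ratios, so a slope of 0.001 per year means 4 %
over the 40-year span from 20 to 60 (`slope_to_percent()`). No
multiple-testing correction is applied to the per-protein age p values;
downstream pathway selection consumes the nominal p < 0.05 flags, and the
documentation says so rather than pretending otherwise. The male-only
sensitivity check (`sex_sensitivity()`) recomputes the rho vector after
dropping female samples and correlates it with the all-sample vector.

## Pathway analytics

**Stoichiometry** (`pathway_stoichiometry()`): for pathways of 5–100
quantified members, member abundances are divided by the per-sample median
of the pathway's members, removing pathway-level shifts so that only
composition changes remain. Members covered in at least two populations
(> 15 % of donors each) are cross-compared between population pairs by
two-sided Wilcoxon rank-sum tests; the mean of the pairwise p values per
member is adjusted by Benjamini–Hochberg across all pathways. The mean of
pairwise p values is not a calibrated p value — it is used deliberately,
as specified, and one consequence is worth knowing: a shift confined to
one population among k dilutes into (k−1) informative and
$\binom{k-1}{2}$ null comparisons, so with six populations a single-
population shift cannot push the mean below 0.05. The recovery tests
therefore use two populations, where the construction is sensitive.

**Ageing pathways** (`select_age_pathways()`): admission needs 5–150
members, > 30 % quantified, and > 20 % plus at least three significantly
age-altered members. Redundancy removal then drops any pathway whose
significant set is contained in another candidate's, unless it holds a
significant protein unique among all candidates ("unique" is evaluated
globally; the pairwise alternative reading is noted in the code).
Identical significant sets collapse to the largest pathway, then the more
general hierarchy level, then the lexicographically first id — making the
output provably independent of input order. The average slope of the
significant members is banded at ±0.001/year: inside the band no tendency;
outside, three or more members moving with the average make a strong
call, one or two a weak one.

**Co-abundance** (`coabundance_distributions()`): Pearson correlations of
within-complex pairs, within-pathway pairs (excluding pairs already
co-complexed), and unannotated background pairs.

## Ligand–receptor correlation across populations

For annotated ligand–receptor pairs, both orientations (MSC ligand vs
partner receptor in another population, and the converse) are correlated
by Spearman over shared donors, gated on each protein being age-altered
(p < 0.1) in its own population and on at least 85 % donor overlap. The
overlap denominator is the smaller of the two donor sets — the reading
that makes the fraction well-defined. MSC proteins without any partner
correlation at p < 0.1 are removed; retained non-significant cells are
marked, not deleted. For the two-axis complete-linkage Euclidean
clustering, missing cells are imputed as 0 (uncorrelated) for the distance
computation only and reported.

## Single-cell lineage priming

Cells pass QC with at least 1,000 genes at ≥ 10 reads and ≥ 150,000 total
reads; genes need ≥ 10 reads in ≥ 5 cells. Expression is normalized by
library-size factors, log2-transformed with a pseudocount, and adjusted to
zero mean per cell. Markers failing to correlate positively (Pearson
p < 0.01, pooled across cells) with any same-lineage marker are removed.
A cell is lymphoid-primed when at least half (ceiling) of the refined
lymphoid markers are expressed (adjusted value > 0), neither CD19 nor CD71
is expressed, and the myeloid criterion is not met simultaneously —
conflicts are conservatively undefined. Because the adjusted value
subtracts the per-cell mean, "expressed" effectively means "above the
cell's average gene" — a detail that matters for the generator (below).
Fraction enrichment uses two-sided Fisher exact tests per sample;
degenerate tables report p = 1 and are flagged. Enzyme–marker correlation
disparities are summarized by Cohen's d with pooled sd and a two-sample
t test; the lineage effect on expression ratios uses a rank-sum test and
the age effect a one-way analysis-of-variance F test on slopes grouped by
age-regulation status (the procedure named for that test without further
model detail; the one-way reading is the simplest consistent one).

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions every
recovery test runs under.

* **Cohort**: 59 donors, ages uniform on 20–60, 45/59 male, six
  populations, batches of five donors plus internal standard, donors
  assigned to batches in age-shuffled order so age and batch are not
  confounded (the normalization tests need that separation to be
  meaningful).
* **PSMs**: per-protein absolute abundance is log-normal (sdlog 1);
  reporter intensities are the peptide baseline × planted ratio ×
  multiplicative log-normal noise. The default reporter CV is 0.042,
  chosen to emulate the replicate behaviour the assay is documented to
  have (replicate correlations near 0.94, median protein CV near 4 %);
  the fully-labelled flag fires at rate 0.985 for the same reason.
  Missingness is missing-at-random in donor channels (default 5 %).
  Precursor area is the exact sum of the six channel intensities, which
  the conservation tests rely on. Planted age slopes enter as
  $1 + b\,(\text{age} - \overline{\text{age}})$ so that mean-normalized
  regression recovers $b$ exactly on noise-free data. Planted effects are
  always a minority of the proteome: planting a majority would bias the
  per-channel median normalization itself (a real phenomenon, worth
  remembering with real data too).
* **Single cells**: negative-binomial counts with dispersion 0.3
  (gene-level default). Marker genes follow a bursting model: an
  own-lineage marker is "on" with probability 1 − dropout (default
  dropout 0.1) at NB mean 480 (base 60 × fold change 8); an off-lineage
  marker is "on" with probability 0.1 at NB mean 60. The "on" level is
  set high deliberately: lineage markers of primed progenitors rank among
  a cell's top-expressed genes, and the classifier's "expressed" means
  above the per-cell average. A mean-fold-only NB model at these settings
  cannot separate the lineages under the count > 0 reading — the
  zero-inflated structure is the realistic and the workable model.
  Primed cells carry zero CD19/CD71; undefined cells may express them.
  Age-regulated enzymes are elevated threefold in myeloid cells and can
  carry planted per-year slopes.

What the generator does **not** emulate: peptide-level ionization
efficiency differences, batch drift over acquisition time, co-isolation
structure behind the interference percentages, real marker co-expression
topology, or doublets and ambient RNA in the single-cell data. Passing
recovery tests therefore demonstrates correctness of the algorithms under
the stated statistical structure, not robustness to every artefact of
real instruments.

## Numerical choices and degenerate inputs

* Medians of even counts are the mean of the two middle values everywhere.
* Top-3 PSM selection breaks area ties by spectrum id; dendrogram leaf
  order is canonicalized by the lexicographically smallest label per
  subtree; the redundancy rule evaluates coverage simultaneously against
  all candidates. All three make results independent of input order.
* Zero internal-standard intensities exclude the PSM with a warning;
  all-zero reporter records are excluded from area splitting; constant
  columns are excluded from correlation clustering; zero-variance genes
  are excluded from correlation tests; a zero pooled sd flags Cohen's d
  as undefined instead of returning an infinity.
* Boundary conventions: coverage "above 15 %" and quantified/significant
  fractions are strict inequalities; the tendency band includes its
  endpoints (|avg| ≤ 0.001 → none); "at least half" of an odd marker
  count uses the ceiling.

## Problem sizes used in tests

The suites run on deliberately small instances chosen to exercise every
code path while keeping the whole test run in a couple of minutes: cohorts
of 5–45 donors, 20–400 proteins, up to ~80,000 PSMs in the deepest
recovery test, 1,000-sample null calibrations for the HDR flag rate, 500
cells for classification accuracy, and exhaustive Fisher-table enumeration
up to total 16 plus seeded random tables to margin 30. The acceptance
script reruns the same computations from scratch at the same scales.

## Known limitations

* Spearman p values use the t approximation; exact permutation p values
  at n < 10 would differ (the package is built for cohort-scale n).
* The per-protein age tests are reported at nominal p < 0.05, as the
  downstream selection rules expect; genome-wide error control is out of
  scope by design.
* The LF score shares the quality gates with the TMT chain and therefore
  inherits their biases (e.g., against low-intensity peptides).
* `run_pipeline()` orchestrates synthetic end-to-end runs; applying the
  package to real exports only requires the PSM/metadata readers and the
  same module functions, but no vendor-format parsing is included.
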