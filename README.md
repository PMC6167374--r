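# marrowquant

Hybrid TMT / label-free proteomic quantification and ageing statistics for
sorted bone marrow cell populations, plus marker-based lineage-priming
classification of single CD34+ cells.

## What problem it solves

Isobaric (TMT 6-plex) proteomics of an ageing cohort measures five donors
and a pooled internal standard (channel 126) per LC-MS batch. Turning the
resulting peptide-spectrum-match (PSM) tables into defensible biology takes
a long chain of small, easy-to-get-wrong steps: quality gates, missing-value
imputation, internal-standard ratio normalization, spectral rollup,
between-batch studentization, label-free abundance scoring scaled by
in-silico tryptic digestion, sample outlier rejection, per-protein
age-association statistics, pathway-level selection rules, cross-population
ligand–receptor correlation, and single-cell lymphoid/myeloid priming
calls. marrowquant implements that chain as tested, reusable functions, and
ships a synthetic-data generator with planted ground truth so every stage
can be verified without access to any deposited raw data.

It is aimed at proteomics bioinformaticians re-analysing cohort-style TMT
studies and at method developers who need a reference implementation of the
procedures with explicit conventions at every ambiguous point.

## The core quantities

* **TMT ratio**: for PSM intensities $I_c$, the normalized donor ratio is
  $(I_c/I_{126}) \cdot \operatorname{median}(I_{126}/I_c)$ per batch, the
  median taken over raw intensities — so each channel's median ratio is 1.
  Peptides take the median of the ≤3 most intense PSMs; proteins the median
  over ≥2 unique peptides; rows are studentized per population, or divided
  by their mean when slopes must stay in per-year units.
* **LF score**: precursor area split across channels by reporter
  intensities, summed over unique peptides, divided by the number of
  observable tryptic peptides (8–25 aa, no missed cleavage, K/R cleavage
  except before P).
* **Age association**: Spearman rho and two-sided p (t approximation)
  against donor age for proteins with >15 % donor coverage; OLS slopes on
  mean-normalized ratios, with slope 0.001/year ≡ 4 % over the 40-year
  span (`slope_to_percent(0.001, 40)`).
* **Outlier rejection**: PCA on complete log2 rows, Gaussian kernel density
  with Scott bandwidth on (PC1, PC2); samples outside the 97 % highest-
  density region are discarded.
* **Lineage priming**: a cell is lymphoid/myeloid-primed when at least half
  of the refined lineage markers are expressed, neither CD19 nor CD71 is,
  and the opposite criterion is not met simultaneously.

## Worked example

```r
library(marrowquant)

cc <- cohort_config(n_donors = 15, populations = "HPC", seed = 42,
                    planted_slopes = data.frame(protein = "P0002",
                                                population = "HPC",
                                                slope = 0.005))
cohort   <- simulate_cohort(cc)
proteins <- simulate_protein_db(40, seed = 43)
psms     <- simulate_psm_table(cohort, proteins, seed = 44)

mats   <- tmt_protein_matrices(psms, cohort$samples)
assoc  <- age_correlation(studentize_matrix(mats$HPC), cohort$samples)
slopes <- age_slopes(mean_normalize_matrix(mats$HPC), cohort$samples)
res    <- merge(assoc, slopes, by = "protein")
res$percent_40y <- slope_to_percent(res$slope)
head(res[order(res$p), c("protein", "rho", "p", "slope", "percent_40y")], 3)
#>    protein    rho        p    slope percent_40y
#> 2    P0002  0.929 5.51e-07  0.00545        21.8
#> 22   P0023 -0.519 4.73e-02 -0.00122        -4.9
#> 16   P0017 -0.516 4.91e-02 -0.00613       -24.5

labelling_efficiency(psms)$median_pct
#> [1] 98.4
```

The planted protein (P0002, +0.5 %/year) is recovered as the top hit with
rho 0.93 and an estimated slope of 0.0055 per year — a 22 % rise over the
20–60-year span; the next two proteins are nulls sitting at the nominal
significance boundary. The labelling-efficiency metric reflects the
generator's 98.5 % complete-labelling rate.

An end-to-end synthetic run (simulate → quantify → QC → statistics →
pathways → ligand–receptor → single cell) is one call:

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

or from a shell, `Rscript inst/scripts/run-pipeline.R --config cfg.yaml`.

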