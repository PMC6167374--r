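#' Synthetic cohort, PSM, sequence, and single-cell generators
#'
#' Everything downstream of the spectral search is testable without external
#' data: these generators emulate the study design (6-plex batches of five
#' donors plus a pooled internal standard in channel 126, a 59-donor cohort
#' aged 20--60 years, six sorted cell populations) and plant known effects
#' (age slopes, stoichiometry shifts, outlier samples, correlated
#' ligand--receptor pairs, single-cell lineage labels) that recovery tests
#' check against.
#'
#' @name synthetic_data
NULL

BM_POPULATIONS <- c("HPC", "LYM", "MON", "GRA", "ERP", "MSC")

#' Cohort configuration
#'
#' @param n_donors number of donors (study design: 59).
#' @param age_range inclusive age range in years (study design: 20--60).
#' @param sex_ratio fraction of male donors (study design: 45/59).
#' @param populations cell population labels.
#' @param batch_size donors per TMT 6-plex batch (5; channel 126 is the
#'   internal standard).
#' @param seed integer seed; all randomness is explicit, no global state.
#' @param planted_slopes optional data.frame (`protein`, `population`,
#'   `slope`): relative abundance change per year planted into PSM tables.
#' @param planted_stoichiometry optional data.frame (`protein`, `population`,
#'   `multiplier`): relative abundance multipliers.
#' @param planted_outliers character vector of sample ids to corrupt into
#'   PCA outliers (validated against the generated samples).
#' @param planted_lr_pairs optional data.frame (`ligand`, `receptor`,
#'   `population`, `slope`): ligand/receptor proteins given a common age
#'   trend in MSC and the named population.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = 59L, age_range = c(20, 60),
                          sex_ratio = 45 / 59, populations = BM_POPULATIONS,
                          batch_size = 5L, seed = 1L,
                          planted_slopes = NULL, planted_stoichiometry = NULL,
                          planted_outliers = character(),
                          planted_lr_pairs = NULL) {
  if (n_donors < 1L) stopf("n_donors must be >= 1")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stopf("age_range must be (min, max) with min < max")
  assert_in_unit(sex_ratio, "sex_ratio")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (!length(populations)) stopf("at least one population required")
  structure(list(n_donors = as.integer(n_donors), age_range = age_range,
                 sex_ratio = sex_ratio, populations = populations,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 planted_slopes = planted_slopes,
                 planted_stoichiometry = planted_stoichiometry,
                 planted_outliers = planted_outliers,
                 planted_lr_pairs = planted_lr_pairs),
            class = "cohort_config")
}

#' Reporter-level noise model
#'
#' @param reporter_cv coefficient of variation of the multiplicative
#'   log-normal reporter noise (default 0.042, emulating the replicate
#'   behaviour of the assay this pipeline targets).
#' @param missing_rate fraction of donor-channel reporter values set missing.
#' @param psm_per_peptide Poisson rate for extra PSMs per peptide and batch
#'   (every peptide gets at least one PSM).
#' @param peptide_per_protein maximum observable peptides sampled per protein.
#' @param frac_rank2 fraction of PSMs assigned search rank 2.
#' @param frac_missed fraction of PSMs assigned one missed cleavage.
#' @param frac_high_interference fraction of PSMs with isolation interference
#'   drawn above the 30 percent gate; the rest fall below it.
#' @param fully_labelled_rate probability a PSM is completely TMT-labelled
#'   (default 0.985).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(reporter_cv = 0.042, missing_rate = 0.05,
                        psm_per_peptide = 1, peptide_per_protein = 6L,
                        frac_rank2 = 0.02, frac_missed = 0.02,
                        frac_high_interference = 0.05,
                        fully_labelled_rate = 0.985) {
  if (reporter_cv < 0) stopf("reporter_cv must be >= 0")
  assert_in_unit(missing_rate, "missing_rate")
  assert_in_unit(frac_rank2, "frac_rank2")
  assert_in_unit(frac_missed, "frac_missed")
  assert_in_unit(frac_high_interference, "frac_high_interference")
  assert_in_unit(fully_labelled_rate, "fully_labelled_rate")
  if (psm_per_peptide < 0) stopf("psm_per_peptide must be >= 0")
  if (peptide_per_protein < 1L) stopf("peptide_per_protein must be >= 1")
  structure(list(reporter_cv = reporter_cv, missing_rate = missing_rate,
                 psm_per_peptide = psm_per_peptide,
                 peptide_per_protein = as.integer(peptide_per_protein),
                 frac_rank2 = frac_rank2, frac_missed = frac_missed,
                 frac_high_interference = frac_high_interference,
                 fully_labelled_rate = fully_labelled_rate),
            class = "noise_model")
}

#' Simulate the donor cohort and sample layout
#'
#' Draws donor ages and sexes, lays out one sample per donor and population,
#' and partitions donors into TMT batches of `batch_size` per population.
#' Donors are batch-assigned in age-shuffled order so age is not confounded
#' with batch. Each batch implicitly carries the internal standard in
#' channel 126; donor samples occupy channels 127 upward.
#'
#' @param config a [cohort_config()].
#' @return object of class `bm_cohort`: list with `samples` (one row per
#'   donor sample: `sample_id`, `donor_id`, `age`, `sex`, `population`,
#'   `batch_id`, `channel`), `donors`, and `truth` (a `ground_truth` list of
#'   the planted effects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_donors
  donors <- data.frame(
    donor_id = sprintf("D%03d", seq_len(n)),
    age = sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "M", "F"),
    stringsAsFactors = FALSE)
  rows <- list()
  for (pop in config$populations) {
    ord <- sample.int(n)                       # age-shuffled batch fill
    batch_no <- ceiling(seq_len(n) / config$batch_size)
    within <- (seq_len(n) - 1L) %% config$batch_size
    rows[[pop]] <- data.frame(
      sample_id = paste0(pop, "_", donors$donor_id[ord]),
      donor_id = donors$donor_id[ord],
      age = donors$age[ord],
      sex = donors$sex[ord],
      population = pop,
      batch_id = sprintf("%s_b%02d", pop, batch_no),
      channel = 127L + within,
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  bad_out <- setdiff(config$planted_outliers, samples$sample_id)
  if (length(bad_out))
    stopf("planted outlier sample(s) not in cohort: %s", paste(bad_out, collapse = ", "))
  truth <- structure(list(
    age_slopes = config$planted_slopes,
    stoichiometry = config$planted_stoichiometry,
    outlier_samples = config$planted_outliers,
    lr_pairs = config$planted_lr_pairs,
    cell_labels = NULL), class = "ground_truth")
  structure(list(samples = samples, donors = donors, truth = truth,
                 config = config), class = "bm_cohort")
}

#' @exportS3Method base::print
print.bm_cohort <- function(x, ...) {
  cat(sprintf("bm_cohort: %d donors (ages %d-%d), %d populations, %d samples\n",
              nrow(x$donors), min(x$donors$age), max(x$donors$age),
              length(unique(x$samples$population)), nrow(x$samples)))
  invisible(x)
}

#' Simulate a random protein sequence database
#'
#' Sequences over the 20-letter amino-acid alphabet with a configurable
#' frequency of the tryptic cleavage residues K and R.
#'
#' @param n_proteins number of proteins.
#' @param length_range sequence length range in residues.
#' @param kr_frequency combined frequency of K and R (split evenly).
#' @param seed integer seed.
#' @return named [Biostrings::AAStringSet] (names `P0001`, ...).
#' @export
simulate_protein_db <- function(n_proteins, length_range = c(150L, 400L),
                                kr_frequency = 0.08, seed = 1L) {
  if (n_proteins < 1L) stopf("n_proteins must be >= 1")
  assert_in_unit(kr_frequency, "kr_frequency")
  if (length_range[1] < 1L || length_range[1] > length_range[2])
    stopf("invalid length_range")
  set.seed(seed)
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # the 18 non-K/R residues
  probs <- c(rep((1 - kr_frequency) / length(aa), length(aa)),
             kr_frequency / 2, kr_frequency / 2)
  alphabet <- c(aa, "K", "R")
  lens <- sample(seq(length_range[1], length_range[2]), n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(alphabet, L, replace = TRUE, prob = probs), collapse = ""),
    character(1))
  names(seqs) <- sprintf("P%04d", seq_len(n_proteins))
  Biostrings::AAStringSet(seqs)
}

# Planted donor/internal-standard ratio for one protein in one population:
# stoichiometry multiplier times a linear age trend centred on the
# population's mean age, so mean-normalized regression recovers the slope
# exactly on noise-free data.
planted_ratio <- function(protein, samples, truth) {
  r <- rep(1, nrow(samples))
  if (!is.null(truth$stoichiometry)) {
    st <- truth$stoichiometry
    hit <- st$protein == protein
    if (any(hit)) {
      for (i in which(hit)) {
        sel <- samples$population == st$population[i]
        r[sel] <- r[sel] * st$multiplier[i]
      }
    }
  }
  if (!is.null(truth$age_slopes)) {
    sl <- truth$age_slopes
    hit <- sl$protein == protein
    for (i in which(hit)) {
      sel <- samples$population == sl$population[i]
      if (any(sel)) {
        abar <- mean(samples$age[sel])
        r[sel] <- r[sel] * pmax(1 + sl$slope[i] * (samples$age[sel] - abar), 1e-6)
      }
    }
  }
  if (!is.null(truth$lr_pairs)) {
    lp <- truth$lr_pairs
    for (i in seq_len(NROW(lp))) {
      tgt <- list(c("MSC", lp$ligand[i]), c(lp$population[i], lp$receptor[i]))
      for (t in tgt) {
        if (protein == t[2]) {
          sel <- samples$population == t[1]
          if (any(sel)) {
            abar <- mean(samples$age[sel])
            r[sel] <- r[sel] * pmax(1 + lp$slope[i] * (samples$age[sel] - abar), 1e-6)
          }
        }
      }
    }
  }
  r
}

#' Simulate a PSM-level quantification table
#'
#' Generates PSMs per observable tryptic peptide, batch by batch. Reporter
#' intensities are a log-normal peptide baseline (channel 126, the internal
#' standard) times the planted donor ratio times multiplicative log-normal
#' noise; the precursor area is the exact sum of the six channel
#' contributions. Missingness, isolation interference, missed cleavages,
#' search ranks, and labelling flags are drawn from the [noise_model()].
#' Planted outlier samples receive a per-protein random fold so they leave
#' the population's PCA cloud.
#'
#' @param cohort a `bm_cohort` from [simulate_cohort()].
#' @param sequences named `AAStringSet` (or named character vector) covering
#'   every protein referenced by the planted truth.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return data.frame of PSM records with columns `spectrum_id`, `batch_id`,
#'   `run_id`, `peptide_sequence`, `protein_group`, `is_unique`,
#'   `search_rank`, `missed_cleavages`, `isolation_interference`,
#'   `precursor_area`, `reporter_126` .. `reporter_131`, `fully_labelled`.
#' @export
simulate_psm_table <- function(cohort, sequences, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(cohort, "bm_cohort"))
  seqs <- as.character(sequences)
  truth <- cohort$truth
  referenced <- unique(c(truth$age_slopes$protein, truth$stoichiometry$protein,
                         truth$lr_pairs$ligand, truth$lr_pairs$receptor))
  unknown <- setdiff(referenced, names(seqs))
  if (length(unknown))
    stopf("ground truth references unknown protein(s): %s",
          paste(unknown, collapse = ", "))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise$reporter_cv^2))
  # per-protein absolute abundance (internal-standard baseline level)
  abundance <- stats::setNames(
    stats::rlnorm(length(seqs), meanlog = log(2e4), sdlog = 1), names(seqs))
  samples <- cohort$samples
  batches <- unique(samples[, c("batch_id", "population")])
  # peptide catalogue: observable tryptic peptides per protein
  pep_list <- lapply(names(seqs), function(p) {
    peps <- digest_observable_peptides(seqs[[p]])$peptides
    if (length(peps) > noise$peptide_per_protein)
      peps <- sample(peps, noise$peptide_per_protein)
    peps
  })
  names(pep_list) <- names(seqs)
  pep_df <- data.frame(
    protein_group = rep(names(pep_list), lengths(pep_list)),
    peptide_sequence = unlist(pep_list, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(pep_df)) stopf("no observable peptides in the sequence database")
  dup <- pep_df$peptide_sequence[duplicated(pep_df$peptide_sequence)]
  pep_df$is_unique <- !(pep_df$peptide_sequence %in% dup)
  # per (protein, sample) outlier fold, drawn once
  out_fold <- list()
  for (s in truth$outlier_samples) {
    out_fold[[s]] <- stats::setNames(
      exp(stats::rnorm(length(seqs), sd = 1.0)), names(seqs))
  }
  # planted ratios per protein across all samples (proteins x samples)
  ratio_mat <- do.call(rbind, lapply(names(seqs), function(p)
    planted_ratio(p, samples, truth)))
  rownames(ratio_mat) <- names(seqs)
  psm_counter <- 0L
  out <- vector("list", nrow(batches))
  for (bi in seq_len(nrow(batches))) {
    b <- batches$batch_id[bi]
    smp <- samples[samples$batch_id == b, , drop = FALSE]
    smp <- smp[order(smp$channel), , drop = FALSE]
    n_psm <- 1L + stats::rpois(nrow(pep_df), noise$psm_per_peptide)
    total <- sum(n_psm)
    idx <- rep(seq_len(nrow(pep_df)), n_psm)
    baseline <- abundance[pep_df$protein_group[idx]] *
      stats::rlnorm(total, meanlog = 0, sdlog = 0.5)
    rep_mat <- matrix(NA_real_, nrow = total, ncol = 6L,
                      dimnames = list(NULL, REPORTER_COLS))
    noise_fac <- function(n) if (noise$reporter_cv > 0)
      exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog)) else rep(1, n)
    rep_mat[, 1L] <- baseline * noise_fac(total)
    for (j in seq_len(nrow(smp))) {
      srow <- smp[j, ]
      global_idx <- match(srow$sample_id, samples$sample_id)
      r <- ratio_mat[pep_df$protein_group[idx], global_idx]
      if (srow$sample_id %in% names(out_fold))
        r <- r * out_fold[[srow$sample_id]][pep_df$protein_group[idx]]
      rep_mat[, srow$channel - 125L] <- baseline * r * noise_fac(total)
    }
    area <- rowSums(rep_mat, na.rm = TRUE)   # conservation: area = sum of channels
    # missingness in donor channels only
    if (noise$missing_rate > 0) {
      for (ch in 2L:6L) {
        miss <- stats::runif(total) < noise$missing_rate
        rep_mat[miss, ch] <- NA_real_
      }
    }
    interference <- ifelse(stats::runif(total) < noise$frac_high_interference,
                           stats::runif(total, 30, 90), stats::runif(total, 0, 29.9))
    df <- data.frame(
      spectrum_id = sprintf("%s_s%06d", b, psm_counter + seq_len(total)),
      batch_id = b,
      run_id = paste0(b, "_r01"),
      peptide_sequence = pep_df$peptide_sequence[idx],
      protein_group = pep_df$protein_group[idx],
      is_unique = pep_df$is_unique[idx],
      search_rank = ifelse(stats::runif(total) < noise$frac_rank2, 2L, 1L),
      missed_cleavages = ifelse(stats::runif(total) < noise$frac_missed, 1L, 0L),
      isolation_interference = interference,
      precursor_area = area,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(rep_mat))
    df$fully_labelled <- stats::runif(total) < noise$fully_labelled_rate
    psm_counter <- psm_counter + total
    out[[bi]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "protein_abundance") <- abundance
  res
}

#' Default lineage marker and enzyme gene sets
#'
#' Marker sets sized like the refined sets used for CD34+ cell
#' classification (12 lymphoid, 8 myeloid genes), the CD19/CD71 exclusion
#' genes, and glycolysis/TCA enzyme sets split into age-regulated and
#' age-stable groups.
#'
#' @return named list of character vectors.
#' @export
default_marker_sets <- function() {
  list(
    lymphoid = c("CD79A", "CD79B", "VPREB1", "VPREB3", "IGLL1", "DNTT",
                 "RAG1", "RAG2", "EBF1", "PAX5", "LCK", "BLNK"),
    myeloid = c("MPO", "ELANE", "PRTN3", "CTSG", "AZU1", "CEBPA",
                "CSF1R", "FCGR1A"),
    exclusion = c("CD19", "CD71"),
    enzymes_age = c("HK1", "PFKM", "ALDOC", "TPI1", "PGM1", "TALDO1",
                    "GPD2", "PYGB"),
    enzymes_stable = c("GAPDH", "ENO1", "PKM", "CS", "IDH2", "SDHA",
                       "FH", "MDH2"))
}

#' Simulate single-cell count matrices with planted lineage labels
#'
#' Negative-binomial counts with a marker-block bursting model: a marker of
#' a cell's own lineage is "on" with probability `1 - dropout` at NB mean
#' `base_marker * fold_change`; an off-lineage marker is "on" with
#' probability `off_rate` at NB mean `base_marker`. Primed cells carry zero
#' counts for the exclusion genes (CD19/CD71); undefined cells may express
#' them. Age-regulated enzymes are elevated in myeloid-primed cells and, if
#' `age_effect` is set, rise with donor age in the affected lineage.
#'
#' @param n_cells total number of cells.
#' @param markers list with `lymphoid` and `myeloid` character vectors
#'   (disjoint from the exclusion genes).
#' @param lineage_fractions named fractions for `lymphoid` and `myeloid`
#'   (remainder is undefined); must sum to at most 1.
#' @param donor_ages ages of the donors cells are split across (study
#'   design: two young, two old subjects).
#' @param fold_change NB mean fold of an "on" own-lineage marker over an
#'   "on" off-lineage marker.
#' @param dropout probability an own-lineage marker stays silent.
#' @param off_rate probability an off-lineage marker fires.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param n_background number of unstructured background genes.
#' @param exclusion_genes genes barred from primed cells (default CD19/CD71).
#' @param enzymes_age,enzymes_stable enzyme gene sets; the age set is
#'   myeloid-elevated by `enzyme_lineage_fold`.
#' @param enzyme_lineage_fold fold of age-regulated enzymes in myeloid cells.
#' @param age_effect optional data.frame (`gene`, `lineage`, `slope`):
#'   per-year relative expression slope planted within that lineage.
#' @param seed integer seed.
#' @return list with `counts` (gene x cell integer matrix), `cells`
#'   (data.frame: `cell_id`, `sample_id`, `donor_age`, `true_label`), and
#'   `truth` (planted labels and parameters).
#' @export
simulate_singlecell_counts <- function(n_cells,
                                       markers = default_marker_sets()[c("lymphoid", "myeloid")],
                                       lineage_fractions = c(lymphoid = 0.4, myeloid = 0.4),
                                       donor_ages = c(25, 27, 53, 55),
                                       fold_change = 8, dropout = 0.1,
                                       off_rate = 0.1, dispersion = 0.3,
                                       n_background = 1500L,
                                       exclusion_genes = c("CD19", "CD71"),
                                       enzymes_age = default_marker_sets()$enzymes_age,
                                       enzymes_stable = default_marker_sets()$enzymes_stable,
                                       enzyme_lineage_fold = 3,
                                       age_effect = NULL, seed = 1L) {
  if (length(intersect(markers$lymphoid, markers$myeloid)))
    stopf("lymphoid and myeloid marker sets overlap")
  if (length(intersect(unlist(markers), exclusion_genes)))
    stopf("marker sets must be disjoint from the exclusion genes")
  if (sum(lineage_fractions) > 1 + 1e-12) stopf("lineage fractions sum above 1")
  genes <- c(markers$lymphoid, markers$myeloid, exclusion_genes,
             enzymes_age, enzymes_stable,
             sprintf("BG%04d", seq_len(n_background)))
  if (n_cells == 0L) {
    counts <- matrix(0L, nrow = length(genes), ncol = 0L,
                     dimnames = list(genes, character()))
    return(list(counts = counts,
                cells = data.frame(cell_id = character(), sample_id = character(),
                                   donor_age = numeric(), true_label = character(),
                                   stringsAsFactors = FALSE),
                truth = list(labels = character())))
  }
  set.seed(seed)
  labels <- sample(c(rep("lymphoid", round(n_cells * lineage_fractions[["lymphoid"]])),
                     rep("myeloid", round(n_cells * lineage_fractions[["myeloid"]]))))
  labels <- c(labels, rep("undefined", n_cells - length(labels)))[seq_len(n_cells)]
  donor <- rep_len(seq_along(donor_ages), n_cells)
  cells <- data.frame(
    cell_id = sprintf("C%04d", seq_len(n_cells)),
    sample_id = sprintf("S%d", donor),
    donor_age = donor_ages[donor],
    true_label = labels, stringsAsFactors = FALSE)
  size <- 1 / dispersion
  # lineage markers of primed progenitors rank among the cell's top-expressed
  # genes when on; the "on" level must clear the per-cell mean that the
  # adjusted >0 rule implies
  base_marker <- 60
  mu <- matrix(0, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, cells$cell_id))
  rnb <- function(mu_vec) stats::rnbinom(length(mu_vec), mu = mu_vec, size = size)
  # marker blocks: bursting on/off times NB mean
  for (set_name in c("lymphoid", "myeloid")) {
    mk <- markers[[set_name]]
    for (g in mk) {
      own <- labels == set_name
      other <- labels == setdiff(c("lymphoid", "myeloid"), set_name)
      undef <- labels == "undefined"
      on <- logical(n_cells)
      on[own] <- stats::runif(sum(own)) > dropout
      on[other] <- stats::runif(sum(other)) < off_rate
      on[undef] <- stats::runif(sum(undef)) < 0.3
      mu[g, ] <- ifelse(on, ifelse(own, base_marker * fold_change, base_marker), 0)
    }
  }
  for (g in exclusion_genes) {
    on <- labels == "undefined" & stats::runif(n_cells) < 0.7
    mu[g, ] <- ifelse(on, base_marker * fold_change, 0)
  }
  age_centre <- mean(donor_ages)
  for (g in c(enzymes_age, enzymes_stable)) {
    base <- 150
    m <- rep(base, n_cells)
    if (g %in% enzymes_age) m[labels == "myeloid"] <- base * enzyme_lineage_fold
    mu[g, ] <- m
  }
  if (!is.null(age_effect)) {
    for (i in seq_len(nrow(age_effect))) {
      g <- age_effect$gene[i]
      if (!g %in% genes) stopf("age_effect references unknown gene '%s'", g)
      sel <- labels == age_effect$lineage[i]
      mu[g, sel] <- mu[g, sel] *
        pmax(1 + age_effect$slope[i] * (cells$donor_age[sel] - age_centre), 1e-6)
    }
  }
  bg <- genes[startsWith(genes, "BG")]
  bg_mean <- stats::rlnorm(length(bg), meanlog = log(120), sdlog = 0.8)
  mu[bg, ] <- matrix(rep(bg_mean, n_cells), nrow = length(bg))
  counts <- matrix(rnb(as.vector(mu)), nrow = length(genes),
                   dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  list(counts = counts, cells = cells,
       truth = list(labels = stats::setNames(labels, cells$cell_id),
                    markers = markers, fold_change = fold_change,
                    dropout = dropout, off_rate = off_rate))
}
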