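test_that("tryptic digestion applies the Keil rule and the length window", {
  # no cleavage site, length 8 -> the whole chain is observable
  expect_equal(digest_observable_peptides("AAAAAAAA"),
               list(peptides = "AAAAAAAA", count = 1L))
  # internal K splits into two 4-mers, both below the window
  expect_equal(digest_observable_peptides("AAAKAAAA")$count, 0L)
  # K followed by P is not cleaved: one 16-mer survives
  expect_equal(digest_observable_peptides("AAAAAAAKPAAAAAAA"),
               list(peptides = "AAAAAAAKPAAAAAAA", count = 1L))
  # empty sequence and invalid residues
  expect_equal(digest_observable_peptides("")$count, 0L)
  expect_error(digest_observable_peptides("AAAAAAAB"), "invalid residue")
  # duplicated fragments count once
  expect_equal(digest_observable_peptides("AAAAAAAKAAAAAAAK")$count, 1L)
})

test_that("digestion matches the brute-force cleaver on random sequences", {
  set.seed(5)
  for (i in 1:300) {
    s <- random_sequence(sample(20:200, 1), kr_frequency = runif(1, 0, 0.3))
    # splice in KP/RP motifs regularly to stress the proline exception
    if (i %% 3 == 0) s <- paste0(substr(s, 1, 10), "KPRP", substr(s, 11, nchar(s)))
    expect_setequal(digest_observable_peptides(s)$peptides, brute_force_digest(s))
  }
})

test_that("precursor area splitting is proportional and conservative", {
  rec <- make_psm(reporters = c(1, 1, 2, 2, 2, 2) * 1e4, area = 1000)
  out <- split_precursor_areas(rec)
  expect_equal(unlist(out[paste0("area_", 126:131)], use.names = FALSE),
               c(100, 100, 200, 200, 200, 200))
  # equal reporters split uniformly
  eq <- split_precursor_areas(make_psm(reporters = rep(1e4, 6), area = 600))
  expect_equal(unlist(eq[paste0("area_", 126:131)], use.names = FALSE), rep(100, 6))
  # conservation on random records
  set.seed(9)
  tab <- do.call(rbind, lapply(1:200, function(i)
    make_psm(spectrum_id = paste0("s", i), reporters = rlnorm(6, 8, 1),
             area = runif(1, 10, 1e6))))
  split <- split_precursor_areas(tab)
  sums <- rowSums(as.matrix(split[, paste0("area_", 126:131)]))
  expect_equal(sums, tab$precursor_area, tolerance = 1e-12)
  # all-zero reporters are excluded with a warning
  expect_warning(out0 <- split_precursor_areas(
    make_psm(reporters = rep(0, 6), area = 10)), "all-zero")
  expect_equal(nrow(out0), 0L)
})

make_area_records <- function(proteins, peptides, areas, unique_flags = TRUE,
                              batch = "b01") {
  n <- length(peptides)
  df <- data.frame(protein_group = proteins, peptide_sequence = peptides,
                   is_unique = rep_len(unique_flags, n), batch_id = batch,
                   stringsAsFactors = FALSE)
  for (ch in 126:131) df[[paste0("area_", ch)]] <- areas
  df
}

test_that("LF scores divide summed unique-peptide areas by observable count", {
  rec <- make_area_records(c("G1", "G1"), c("AAAAAAAK", "CCCCCCCK"), c(50, 30))
  counts <- c(G1 = 10L)
  samples <- make_samples(batch_id = "b01")
  lf <- compute_lf_scores(rec, counts, samples)
  expect_equal(unname(lf$values["G1", "b01_IS"]), (50 + 30) / 10)
  # single unique peptide -> excluded
  one <- make_area_records("G2", "DDDDDDDK", 40)
  lf1 <- compute_lf_scores(rbind(rec, one), c(counts, G2 = 5L), samples)
  expect_false("G2" %in% rownames(lf1$values))
  # observable count zero -> excluded with a warning
  zero <- make_area_records(c("G3", "G3"), c("EEEEEEEK", "FFFFFFFK"), 10)
  expect_warning(lf2 <- compute_lf_scores(rbind(rec, zero),
                                          c(counts, G3 = 0L), samples),
                 "zero observable")
  expect_false("G3" %in% rownames(lf2$values))
  # linearity: doubling one channel's areas doubles that channel's score only
  rec2 <- rec
  rec2$area_128 <- rec2$area_128 * 2
  lf3 <- compute_lf_scores(rec2, counts, samples)
  expect_equal(unname(lf3$values["G1", "HPC_D02"]),
               2 * unname(lf$values["G1", "HPC_D02"]))
  expect_equal(unname(lf3$values["G1", "HPC_D03"]),
               unname(lf$values["G1", "HPC_D03"]))
})

test_that("LF score is invariant to how signal splits among unique peptides", {
  samples <- make_samples()
  counts <- c(G1 = 7L)
  a <- compute_lf_scores(make_area_records(c("G1", "G1"),
                                           c("AAAAAAAK", "CCCCCCCK"),
                                           c(60, 20)), counts, samples)
  b <- compute_lf_scores(make_area_records(c("G1", "G1"),
                                           c("AAAAAAAK", "CCCCCCCK"),
                                           c(10, 70)), counts, samples)
  expect_equal(a$values["G1", ], b$values["G1", ])
})

test_that("LF normalization zeroes batch medians and forms LF sums", {
  samples <- rbind(make_samples(batch_id = "b01", n = 5),
                   transform(make_samples(batch_id = "b02", n = 5),
                             sample_id = sprintf("HPC_D%02d", 6:10),
                             donor_id = sprintf("D%02d", 6:10)))
  v <- matrix(rlnorm(2 * 12, 3, 1), nrow = 2,
              dimnames = list(c("G1", "G2"),
                              c("b01_IS", samples$sample_id[1:5],
                                "b02_IS", samples$sample_id[6:10])))
  lfm <- lf_matrix(v, batch = setNames(rep(c("b01", "b02"), each = 6), colnames(v)))
  out <- normalize_lf_matrix(lfm, samples)
  for (b in c("b01", "b02")) {
    cols <- names(lfm$batch)[lfm$batch == b]
    expect_lt(abs(median(out$matrix$values[, cols], na.rm = TRUE)), 1e-9)
  }
  # all-equal matrix -> all zeros
  ve <- matrix(4, nrow = 2, ncol = 12, dimnames = dimnames(v))
  oute <- normalize_lf_matrix(lf_matrix(ve, batch = lfm$batch), samples)
  expect_true(all(oute$matrix$values == 0))
  # LF sum: normalized unlogged values divided by the population's max donors
  # (two quantified donors out of five with values {2, 3} -> 1.0)
  samples5 <- make_samples(n = 5)
  v5 <- matrix(NA_real_, nrow = 1, ncol = 6,
               dimnames = list("G1", c("b01_IS", samples5$sample_id)))
  v5["G1", c("HPC_D01", "HPC_D02")] <- c(2, 3)
  lf5 <- lf_matrix(v5, batch = setNames(rep("b01", 6), colnames(v5)))
  out5 <- normalize_lf_matrix(lf5, samples5)
  # batch median of log2 values is subtracted; undo it to check the stated sum
  med <- median(log2(c(2, 3)))
  expect_equal(out5$lf_sums$lf_sum[out5$lf_sums$protein == "G1"],
               (2 / 2^med + 3 / 2^med) / 5)
})

test_that("complete-linkage clustering matches a brute-force oracle", {
  brute_complete <- function(d) {
    # O(n^3) agglomeration on a distance matrix, returning sorted merge heights
    active <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(NA, NA); best_h <- Inf
      for (i in seq_along(active)) for (j in seq_len(i - 1)) {
        h <- max(d[active[[i]], active[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
      heights <- c(heights, best_h)
      active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
      active[[best[2]]] <- NULL
    }
    heights
  }
  set.seed(21)
  for (rep_i in 1:20) {
    x <- matrix(rnorm(8 * 5), nrow = 8)
    colnames(x) <- paste0("S", 1:5)
    res <- hierarchical_cluster_samples(x)
    d <- as.matrix(1 - cor(x))
    expect_equal(sort(res$hclust$height), sort(brute_complete(d)),
                 tolerance = 1e-12)
  }
  # identical samples merge first at distance ~0
  x <- matrix(rnorm(10 * 4), nrow = 10)
  x <- cbind(x, x[, 1])
  colnames(x) <- paste0("S", 1:5)
  res <- hierarchical_cluster_samples(x)
  expect_lt(res$hclust$height[1], 1e-12)
  pair <- res$hclust$merge[1, ]
  expect_setequal(res$hclust$labels[-pair], c("S1", "S5"))
  # single sample -> single leaf
  single <- hierarchical_cluster_samples(x[, 1, drop = FALSE])
  expect_null(single$hclust)
  expect_equal(single$order, 1L)
  # leaf order is stable under input column order
  perm <- sample(ncol(x))
  res_p <- hierarchical_cluster_samples(x[, perm])
  expect_equal(res_p$labels[res_p$order], res$labels[res$order])
})

test_that("LF scores recover planted abundance ranks on clean data", {
  cc <- cohort_config(n_donors = 5, populations = "HPC", seed = 3)
  co <- simulate_cohort(cc)
  db <- simulate_protein_db(30, seed = 4)
  psms <- simulate_psm_table(co, db, seed = 5,
                             noise = noise_model(reporter_cv = 0.05,
                                                 missing_rate = 0,
                                                 peptide_per_protein = 100L,
                                                 frac_rank2 = 0,
                                                 frac_missed = 0,
                                                 frac_high_interference = 0))
  lf <- lf_quantify(psms, db, co$samples)
  truth_abund <- attr(psms, "protein_abundance")
  got <- rowMeans(lf$lf_raw$values, na.rm = TRUE)
  shared <- intersect(names(truth_abund), names(got))
  expect_gt(length(shared), 15)
  expect_gt(cor(rank(truth_abund[shared]), rank(got[shared])), 0.9)
})
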