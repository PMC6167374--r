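test_that("quality gates admit exactly the PSMs satisfying every criterion", {
  psms <- make_gate_fixture()
  sets <- filter_psms(psms)
  # rank-2 spectra are discarded from identification and quantification
  expect_false("rank2" %in% sets$identification$spectrum_id)
  expect_identical(sets$quantification$spectrum_id, "ok")
  # each remaining violator fails exactly its own gate
  expect_setdiff <- setdiff(sets$identification$spectrum_id,
                            sets$quantification$spectrum_id)
  expect_setequal(expect_setdiff, c("interf", "lowsum", "missed"))
  # idempotence: filtering the quantification set again changes nothing
  again <- filter_psms(sets$quantification)
  expect_identical(again$quantification, sets$quantification)
})

test_that("malformed records are rejected with their spectrum id", {
  psms <- make_psm(spectrum_id = "neg", reporters = c(1e4, -5, rep(1e4, 4)))
  expect_error(filter_psms(psms), "neg")
})

test_that("imputation fills donor channels with the batch minimum, never 126", {
  psms <- make_psm_table(
    make_psm(spectrum_id = "a", reporters = c(9e3, 500, 800, NA, 700, 900)),
    make_psm(spectrum_id = "b", reporters = c(9e3, 600, NA, 1000, 700, 900)))
  out <- impute_missing_reporters(psms)
  expect_equal(out$reporter_129[1], 500)  # batch min over channels 127-131
  expect_equal(out$reporter_128[2], 500)
  expect_true(out$imp_129[1] && out$imp_128[2])
  expect_equal(out$reporter_126, c(9e3, 9e3))
  # no-op when nothing is missing
  clean <- make_psm(spectrum_id = "c", reporters = rep(1e3, 6))
  expect_equal(impute_missing_reporters(clean)$reporter_127, 1e3)
  # a wholly missing channel gets the minimum of the remaining channels
  psms2 <- make_psm_table(
    make_psm(spectrum_id = "d", reporters = c(9e3, 700, 800, 900, 1000, NA)),
    make_psm(spectrum_id = "e", reporters = c(9e3, 750, 850, 950, 1050, NA)))
  out2 <- impute_missing_reporters(psms2)
  expect_equal(out2$reporter_131, c(700, 700))
})

test_that("median-ratio normalization fixes each channel's median at 1", {
  # identity: all channels equal to the internal standard
  psms <- make_psm_table(
    make_psm(spectrum_id = "a", reporters = rep(2e4, 6)),
    make_psm(spectrum_id = "b", reporters = rep(3e4, 6)),
    make_psm(spectrum_id = "c", reporters = rep(4e4, 6)))
  ratios <- normalize_psm_ratios(psms)
  for (ch in 127:131) expect_equal(ratios[[paste0("ratio_", ch)]], rep(1, 3))

  # a channel loaded at 2x across all PSMs returns to median 1
  set.seed(42)
  reps <- lapply(1:7, function(i) {
    r <- rlnorm(6, log(2e4), 0.3); r[3] <- r[1] * 2  # channel 128 = 2 x IS
    make_psm(spectrum_id = sprintf("s%02d", i), reporters = r)
  })
  ratios2 <- normalize_psm_ratios(do.call(rbind, reps))
  expect_equal(median(ratios2$ratio_128), 1, tolerance = 1e-12)

  # odd PSM counts: every channel's median is 1 to machine precision
  set.seed(7)
  for (rep_i in 1:10) {
    n <- sample(c(5, 9, 13), 1)
    tab <- do.call(rbind, lapply(seq_len(n), function(i)
      make_psm(spectrum_id = sprintf("t%03d", i),
               reporters = rlnorm(6, log(2e4), 0.5))))
    r <- normalize_psm_ratios(tab)
    for (ch in 127:131)
      expect_equal(median(r[[paste0("ratio_", ch)]]), 1, tolerance = 1e-12)
  }
})

test_that("normalization medians come from raw, not imputed, intensities", {
  psms <- make_psm_table(
    make_psm(spectrum_id = "a", reporters = c(1e4, 1e4, 1e4, 1e4, 1e4, 2e4)),
    make_psm(spectrum_id = "b", reporters = c(1e4, 1e4, 1e4, 1e4, 1e4, NA)),
    make_psm(spectrum_id = "c", reporters = c(1e4, 1e4, 1e4, 1e4, 1e4, 2e4)))
  imputed <- impute_missing_reporters(psms)
  med <- channel_median_ratios(imputed)
  # channel 131's median uses only the two observed 2e4 values, not the
  # imputed batch minimum
  expect_equal(med$median_ratio[med$channel == 131], 0.5)
})

test_that("peptide rollup takes the median of the top-3 most intense PSMs", {
  base <- function(id, ratio, area) {
    df <- make_psm(spectrum_id = id, area = area)
    for (ch in 127:131) df[[paste0("ratio_", ch)]] <- ratio
    df[, c("spectrum_id", "batch_id", "run_id", "peptide_sequence",
           "protein_group", "is_unique", "precursor_area",
           paste0("ratio_", 127:131))]
  }
  # singleton passes through
  single <- rollup_peptides(base("a", 1.3, 100))
  expect_equal(single$ratio_127, 1.3)
  # two PSMs: median of both
  two <- rollup_peptides(rbind(base("a", 1.0, 100), base("b", 2.0, 200)))
  expect_equal(two$ratio_127, 1.5)
  # five PSMs with areas ranking the last three highest
  five <- rollup_peptides(rbind(
    base("a", 0.8, 10), base("b", 1.0, 20), base("c", 1.2, 100),
    base("d", 2.0, 200), base("e", 3.0, 300)))
  expect_equal(five$ratio_127, 2.0)
})

test_that("rollup matches the exhaustive oracle on random small fixtures", {
  set.seed(11)
  for (case in 1:200) {
    n_pep <- sample(1:6, 1)
    rows <- list()
    for (p in seq_len(n_pep)) {
      n_psm <- sample(1:6, 1)
      for (s in seq_len(n_psm)) {
        df <- make_psm(spectrum_id = sprintf("p%ds%d", p, s),
                       peptide = sprintf("PEPTIDE%dK", p),
                       area = sample(1:50, 1))
        for (ch in 127:131) df[[paste0("ratio_", ch)]] <- round(rlnorm(1), 3)
        rows[[length(rows) + 1]] <- df[, c("spectrum_id", "batch_id", "run_id",
                                           "peptide_sequence", "protein_group",
                                           "is_unique", "precursor_area",
                                           paste0("ratio_", 127:131))]
      }
    }
    tab <- do.call(rbind, rows)
    got <- rollup_peptides(tab)
    want <- brute_force_rollup(tab)
    key <- order(got$peptide_sequence)
    wkey <- order(want$peptide_sequence)
    for (ch in 127:131)
      expect_equal(got[[paste0("ratio_", ch)]][key],
                   want[[paste0("ratio_", ch)]][wkey])
  }
})

test_that("protein rollup uses unique peptides only and needs at least two", {
  pep <- data.frame(
    batch_id = "b01",
    peptide_sequence = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK", "EEEEEEEK"),
    protein_group = c("G1", "G1", "G1", "G2"),
    is_unique = c(TRUE, TRUE, FALSE, TRUE),
    n_psms = 1L, stringsAsFactors = FALSE)
  for (ch in 127:131) pep[[paste0("ratio_", ch)]] <- c(0.9, 1.4, 100, 1.0)
  samples <- make_samples()
  rm_ <- rollup_proteins(pep, samples)
  # shared peptide (ratio 100) ignored: median of the two unique ratios
  expect_equal(unname(rm_$values["G1", "HPC_D01"]), (0.9 + 1.4) / 2)
  # G2 has a single unique peptide -> excluded
  expect_false("G2" %in% rownames(rm_$values))
  # three unique peptides -> their median
  pep3 <- pep[1:3, ]; pep3$is_unique <- TRUE
  for (ch in 127:131) pep3[[paste0("ratio_", ch)]] <- c(0.9, 1.0, 1.4)
  expect_equal(unname(rollup_proteins(pep3, samples)$values["G1", "HPC_D01"]), 1.0)
})

test_that("studentization yields rows with mean 0, sd 1; constants drop", {
  v <- matrix(c(1, 2, 3,
                2, 2, 2,
                5, 1, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("S", 1:3)))
  rm_ <- ratio_matrix(v, state = "raw")
  expect_warning(st <- studentize_matrix(rm_), "zero variance")
  expect_equal(unname(st$values["A", ]), c(-1, 0, 1))
  expect_false("B" %in% rownames(st$values))
  expect_true(all(abs(rowMeans(st$values, na.rm = TRUE)) < 1e-9))
  expect_true(all(abs(apply(st$values, 1, sd, na.rm = TRUE) - 1) < 1e-9))
  expect_identical(attr(st, "dropped"), "B")
})

test_that("mean normalization divides rows by their mean", {
  v <- matrix(c(1, 2, 3, 1, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("S", 1:3)))
  mn <- mean_normalize_matrix(ratio_matrix(v))
  expect_equal(unname(mn$values["A", ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(mn$values["B", ]), c(1, 1, 1))
  expect_true(all(abs(rowMeans(mn$values) - 1) < 1e-12))
  expect_equal(mn$state, "mean_normalized")
})
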