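# Shared fixture builders. Everything is generated in code; no stored data.

# One PSM row with explicit reporter intensities (126..131).
make_psm <- function(spectrum_id = "s001", batch_id = "b01", run_id = "r01",
                     peptide = "PEPTIDEK", protein = "GENE1", is_unique = TRUE,
                     rank = 1L, missed = 0L, interference = 5,
                     area = NULL, reporters = rep(1e4, 6),
                     fully_labelled = TRUE) {
  stopifnot(length(reporters) == 6L)
  df <- data.frame(spectrum_id = spectrum_id, batch_id = batch_id,
                   run_id = run_id, peptide_sequence = peptide,
                   protein_group = protein, is_unique = is_unique,
                   search_rank = rank, missed_cleavages = missed,
                   isolation_interference = interference,
                   precursor_area = if (is.null(area)) sum(reporters, na.rm = TRUE) else area,
                   stringsAsFactors = FALSE)
  for (i in 1:6) df[[paste0("reporter_", 125L + i)]] <- reporters[i]
  df$fully_labelled <- fully_labelled
  df
}

make_psm_table <- function(...) do.call(rbind, list(...))

# Minimal sample metadata for one batch of up to five donors.
make_samples <- function(batch_id = "b01", population = "HPC",
                         n = 5L, ages = seq(25, 25 + 5 * (n - 1), by = 5)) {
  data.frame(sample_id = sprintf("%s_D%02d", population, seq_len(n)),
             donor_id = sprintf("D%02d", seq_len(n)),
             age = ages[seq_len(n)], sex = rep(c("M", "F"), length.out = n),
             population = population, batch_id = batch_id,
             channel = 126L + seq_len(n), stringsAsFactors = FALSE)
}

# Brute-force reference digestion: walk the chain residue by residue.
brute_force_digest <- function(sequence, min_length = 8L, max_length = 25L) {
  chars <- strsplit(sequence, "")[[1]]
  frags <- character(0)
  current <- character(0)
  for (i in seq_along(chars)) {
    current <- c(current, chars[i])
    nxt <- if (i < length(chars)) chars[i + 1L] else ""
    if (chars[i] %in% c("K", "R") && nxt != "P" && i < length(chars)) {
      frags <- c(frags, paste(current, collapse = ""))
      current <- character(0)
    }
  }
  if (length(current)) frags <- c(frags, paste(current, collapse = ""))
  keep <- nchar(frags) >= min_length & nchar(frags) <= max_length
  unique(frags[keep])
}

# Random amino-acid sequence with adjustable K/R content and explicit KP/RP
# runs to stress the Keil rule.
random_sequence <- function(len, kr_frequency = 0.08) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  probs <- c(rep((1 - kr_frequency) / 18, 18), kr_frequency / 2, kr_frequency / 2)
  paste(sample(c(aa, "K", "R"), len, replace = TRUE, prob = probs), collapse = "")
}

# Exhaustive reference for the peptide/protein rollup on a small ratio table.
brute_force_rollup <- function(ratios) {
  out <- list()
  for (b in unique(ratios$batch_id)) {
    sub_b <- ratios[ratios$batch_id == b, ]
    for (pep in unique(sub_b$peptide_sequence)) {
      sub <- sub_b[sub_b$peptide_sequence == pep, ]
      ord <- order(-sub$precursor_area, sub$spectrum_id)
      top <- sub[ord[seq_len(min(3, nrow(sub)))], ]
      row <- data.frame(batch_id = b, peptide_sequence = pep,
                        protein_group = sub$protein_group[1],
                        is_unique = sub$is_unique[1], stringsAsFactors = FALSE)
      for (ch in 127:131)
        row[[paste0("ratio_", ch)]] <- median(top[[paste0("ratio_", ch)]])
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

# Two-sided Fisher p by explicit enumeration of 2x2 tables with the observed
# margins: sum of hypergeometric probabilities not exceeding the observed
# table's probability (with the same tolerance fisher.test uses).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Quantification-gate PSM fixture: five PSMs, each violating exactly one
# criterion, plus one clean PSM.
make_gate_fixture <- function() {
  make_psm_table(
    make_psm(spectrum_id = "ok",     reporters = rep(2e4, 6)),
    make_psm(spectrum_id = "rank2",  rank = 2L, reporters = rep(2e4, 6)),
    make_psm(spectrum_id = "interf", interference = 45, reporters = rep(2e4, 6)),
    make_psm(spectrum_id = "lowsum", reporters = c(2e4, rep(1000, 5))),
    make_psm(spectrum_id = "missed", missed = 1L, reporters = rep(2e4, 6)))
}

# Constructed pathway fixtures with hand-computed expected outcomes.
# Quantified universe: Q01..Q20; significant: S01..S08 (also quantified).
fixture_pathways <- function() {
  quantified <- c(sprintf("Q%02d", 1:20), sprintf("S%02d", 1:8))
  significant <- sprintf("S%02d", 1:8)
  mk <- function(id, members, level = 1L) {
    data.frame(id = id, name = id, top_hierarchy = "H", level = level,
               stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, list(
    mk("too_small"),      # 4 members -> fails the size filter
    mk("low_quant"),      # 2/10 quantified -> fails >30%
    mk("two_sig"),        # only 2 significant -> fails count >= 3
    mk("covered"),        # sig set subset of 'big', no unique protein
    mk("unique_kept"),    # subset of 'big' but holds unique S07
    mk("big"),            # superset pathway
    mk("twin_small", level = 2L),  # same sig set as twin_large
    mk("twin_large", level = 3L)))
  p$members <- list(
    c("S01", "S02", "S03", "Q01"),                                   # too_small
    c("S01", "S02", "S03", "X01", "X02", "X03", "X04", "X05", "X06", "X07"),
    c("S01", "S02", "Q01", "Q02", "Q03"),                            # two_sig
    c("S01", "S02", "S03", "Q01", "Q02"),                            # covered
    c("S01", "S02", "S07", "Q03", "Q04"),                            # unique_kept
    c("S01", "S02", "S03", "S04", "Q05", "Q06", "Q07"),              # big
    c("S05", "S06", "S08", "Q08", "Q09"),                            # twin_small
    c("S05", "S06", "S08", "Q10", "Q11", "Q12", "Q13", "Q14"))       # twin_large
  p$n_members <- lengths(p$members)
  assoc <- data.frame(protein = quantified, population = "HPC",
                      n = 40L, coverage = 1, rho = 0.1, p = 0.5,
                      significant = quantified %in% significant,
                      stringsAsFactors = FALSE)
  assoc$p[assoc$significant] <- 0.01
  list(pathways = p, assoc = assoc)
}

# A deterministic count fixture crossing every QC threshold exactly.
make_qc_fixture <- function() {
  n_genes <- 1600
  genes <- sprintf("G%04d", seq_len(n_genes))
  # good cells: 1000 genes at exactly 10 reads, remainder padding to 150k
  good <- c(rep(10L, 1000), rep(0L, 500), rep(0L, 100))
  good[1001:1100] <- as.integer((150000 - sum(good)) / 100)
  cells <- list(
    good1 = good, good2 = good, good3 = good, good4 = good, good5 = good,
    few_genes = {x <- good; x[1000] <- 9L; x},                  # 999 genes at >=10
    low_total = {x <- rep(0L, n_genes); x[1:1200] <- 10L; x})   # 12,000 reads
  m <- do.call(cbind, cells)
  rownames(m) <- genes
  m
}
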