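#' Hybrid label-free abundance scores
#'
#' The label-free (LF) score estimates protein abundance across cell
#' populations: each peptide's precursor (MS1) area is split across the six
#' TMT channels by its reporter-ion ratios, channel-normalized like the TMT
#' ratios, and protein scores are the summed unique-peptide areas divided by
#' the number of theoretically observable tryptic peptides of the protein
#' (length 8--25 residues, no missed cleavage).
#'
#' @name lf_quant
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' In-silico tryptic digestion: observable peptides
#'
#' Cleaves C-terminal to K or R except when the next residue is P (Keil
#' rule), with no missed cleavages, and returns the distinct fragments whose
#' length lies within `[min_length, max_length]`. I and L are treated as
#' distinct residues; duplicate fragments within a protein count once.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @param min_length,max_length observable length window (default 8--25).
#' @return list with `peptides` (character vector, order of first
#'   occurrence) and `count`.
#' @examples
#' digest_observable_peptides("AAAAAAAA")$count        # 1
#' digest_observable_peptides("AAAKAAAA")$count        # 0: both fragments short
#' digest_observable_peptides(strrep("A", 7))$count    # 0
#' @export
digest_observable_peptides <- function(sequence, min_length = 8L, max_length = 25L) {
  if (min_length > max_length || min_length < 1L) stopf("invalid length window")
  sequence <- as.character(sequence)
  if (!nchar(sequence)) return(list(peptides = character(), count = 0L))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stopf("invalid residue(s) in sequence: %s", paste(bad, collapse = ", "))
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  frags <- substring(sequence, starts, ends)
  lens <- ends - starts + 1L
  keep <- unique(frags[lens >= min_length & lens <= max_length])
  list(peptides = keep, count = length(keep))
}

#' Observable-peptide counts for a sequence set
#'
#' @param sequences named `AAStringSet` or character vector.
#' @inheritParams digest_observable_peptides
#' @return named integer vector of observable-peptide counts.
#' @export
observable_peptide_counts <- function(sequences, min_length = 8L, max_length = 25L) {
  seqs <- as.character(sequences)
  vapply(seqs, function(s)
    digest_observable_peptides(s, min_length, max_length)$count, integer(1))
}

#' Split precursor areas across TMT channels
#'
#' Each record's precursor area is allocated proportionally to its observed
#' reporter intensities over channels 126--131; the split conserves the
#' total area exactly. When `median_ratios` (from [channel_median_ratios()])
#' is supplied, donor-channel areas are additionally multiplied by the batch
#' median internal-standard/channel ratio, mirroring the TMT normalization.
#' Records whose observed reporters are all zero are excluded with a
#' warning. Missing channels stay missing; no LF imputation is done.
#'
#' @param records data.frame with `reporter_126` .. `reporter_131`,
#'   `precursor_area`, and `batch_id` (the latter only needed for
#'   normalization).
#' @param median_ratios optional per-batch median-ratio table.
#' @return `records` with added columns `area_126` .. `area_131`.
#' @export
split_precursor_areas <- function(records, median_ratios = NULL) {
  rep_mat <- as.matrix(records[, REPORTER_COLS])
  tot <- rowSums(rep_mat, na.rm = TRUE)
  bad <- !is.finite(tot) | tot <= 0
  if (any(bad)) {
    warnf("excluding %d record(s) with all-zero reporter intensities", sum(bad))
    records <- records[!bad, , drop = FALSE]
    rep_mat <- rep_mat[!bad, , drop = FALSE]
    tot <- tot[!bad]
  }
  areas <- rep_mat / tot * records$precursor_area
  colnames(areas) <- paste0("area_", TMT_CHANNELS)
  if (!is.null(median_ratios)) {
    key <- paste(median_ratios$batch_id, median_ratios$channel)
    med <- stats::setNames(median_ratios$median_ratio, key)
    for (ch in DONOR_CHANNELS) {
      m <- as.numeric(med[paste(records$batch_id, ch)])
      areas[, paste0("area_", ch)] <- areas[, paste0("area_", ch)] * m
    }
  }
  cbind(records, as.data.frame(areas))
}

#' Label-free matrix container
#'
#' @param values numeric protein-by-sample matrix of LF scores.
#' @param state `"raw"` or `"log_median_normalized"`.
#' @param batch named vector (by column) of batch ids.
#' @return object of class `lf_matrix`.
#' @export
lf_matrix <- function(values, state = "raw", batch = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  state <- match.arg(state, c("raw", "log_median_normalized"))
  if (state == "raw" && any(values < 0, na.rm = TRUE))
    stopf("raw LF scores must be non-negative")
  structure(list(values = values, state = state, batch = batch),
            class = "lf_matrix")
}

#' @exportS3Method base::print
print.lf_matrix <- function(x, ...) {
  cat(sprintf("lf_matrix: %d proteins x %d samples [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.lf_matrix <- function(x, ...) x$values

#' Compute protein label-free scores
#'
#' Peptide-level channel areas are summed per protein over its unique
#' peptides and divided by the protein's observable tryptic peptide count.
#' Proteins with fewer than two unique quantified peptides, or with an
#' observable count of zero, are excluded (the latter logged via warning).
#'
#' @param areas data.frame of peptide-level records carrying
#'   `protein_group`, `peptide_sequence`, `is_unique`, `batch_id`, and
#'   `area_126` .. `area_131` (see [split_precursor_areas()]).
#' @param observable_counts named integer vector from
#'   [observable_peptide_counts()].
#' @param samples sample metadata mapping batch/channel to sample ids; the
#'   internal standard column of each batch is labelled `<batch>_IS`.
#' @param min_unique_peptides minimum distinct unique peptides per protein.
#' @return an [lf_matrix] in state `"raw"` (donor sample columns plus one
#'   internal-standard column per batch).
#' @export
compute_lf_scores <- function(areas, observable_counts, samples,
                              min_unique_peptides = 2L) {
  ua <- areas[areas$is_unique, , drop = FALSE]
  known <- ua$protein_group %in% names(observable_counts)
  if (!all(known))
    stopf("missing observable-peptide count for: %s",
          paste(unique(ua$protein_group[!known]), collapse = ", "))
  zero_obs <- unique(ua$protein_group[observable_counts[ua$protein_group] == 0L])
  if (length(zero_obs)) {
    warnf("excluding %d protein(s) with zero observable peptides: %s",
          length(zero_obs), paste(zero_obs, collapse = ", "))
    ua <- ua[!ua$protein_group %in% zero_obs, , drop = FALSE]
  }
  # distinct unique peptides per (protein, batch)
  pep_key <- unique(ua[, c("protein_group", "batch_id", "peptide_sequence")])
  n_unique <- stats::aggregate(peptide_sequence ~ protein_group + batch_id,
                               data = pep_key, FUN = length)
  keep_key <- paste(n_unique$protein_group, n_unique$batch_id)[
    n_unique$peptide_sequence >= min_unique_peptides]
  ua <- ua[paste(ua$protein_group, ua$batch_id) %in% keep_key, , drop = FALSE]
  batches <- unique(samples$batch_id)
  col_ids <- character(0); col_batch <- character(0)
  for (b in batches) {
    smp <- samples[samples$batch_id == b, , drop = FALSE]
    smp <- smp[order(smp$channel), , drop = FALSE]
    col_ids <- c(col_ids, paste0(b, "_IS"), smp$sample_id)
    col_batch <- c(col_batch, rep(b, nrow(smp) + 1L))
  }
  prots <- sort(unique(ua$protein_group))
  values <- matrix(NA_real_, nrow = length(prots), ncol = length(col_ids),
                   dimnames = list(prots, col_ids))
  sample_key <- paste(samples$batch_id, samples$channel)
  for (b in batches) {
    sub <- ua[ua$batch_id == b, , drop = FALSE]
    if (!nrow(sub)) next
    for (ch in TMT_CHANNELS) {
      col <- if (ch == 126L) paste0(b, "_IS") else
        samples$sample_id[match(paste(b, ch), sample_key)]
      if (is.na(col)) next
      a <- sub[[paste0("area_", ch)]]
      sums <- tapply(a, sub$protein_group, sum, na.rm = TRUE)
      p <- names(sums)
      values[p, col] <- as.numeric(sums) / as.numeric(observable_counts[p])
    }
  }
  lf_matrix(values, state = "raw",
            batch = stats::setNames(col_batch, col_ids))
}

#' Normalize a label-free matrix and compute LF sums
#'
#' Scores are log2-transformed (non-positive scores treated as missing) and
#' the per-batch median over all protein scores of that TMT experiment is
#' subtracted. The LF sum per protein and cell population is the sum of the
#' normalized, unlogged donor-sample values divided by the maximum number of
#' donors available in that population.
#'
#' @param x a raw [lf_matrix].
#' @param samples sample metadata (defines populations and donor counts).
#' @return list with `matrix` (an [lf_matrix], state
#'   `"log_median_normalized"`) and `lf_sums` (data.frame: `protein`,
#'   `population`, `lf_sum`).
#' @export
normalize_lf_matrix <- function(x, samples) {
  stopifnot(inherits(x, "lf_matrix"))
  if (x$state != "raw") stopf("normalize_lf_matrix() expects a raw matrix")
  v <- x$values
  v[!is.na(v) & v <= 0] <- NA_real_
  lg <- log2(v)
  for (b in unique(x$batch)) {
    cols <- names(x$batch)[x$batch == b]
    med <- stats::median(lg[, cols], na.rm = TRUE)
    lg[, cols] <- lg[, cols] - med
  }
  norm <- lf_matrix(lg, state = "log_median_normalized", batch = x$batch)
  unlogged <- 2^lg
  pops <- unique(samples$population)
  sums <- list()
  for (pop in pops) {
    smp <- samples[samples$population == pop, , drop = FALSE]
    max_donors <- length(unique(smp$donor_id))
    cols <- intersect(smp$sample_id, colnames(unlogged))
    if (!length(cols)) next
    s <- rowSums(unlogged[, cols, drop = FALSE], na.rm = TRUE)
    s[rowSums(is.finite(unlogged[, cols, drop = FALSE])) == 0L] <- NA_real_
    sums[[pop]] <- data.frame(protein = rownames(unlogged), population = pop,
                              lf_sum = s / max_donors, stringsAsFactors = FALSE,
                              row.names = NULL)
  }
  list(matrix = norm, lf_sums = do.call(rbind, c(sums, list(make.row.names = FALSE))))
}

#' Hierarchical clustering of samples or proteins
#'
#' Deterministic complete-linkage clustering of the columns of a matrix,
#' with distance `1 - Pearson correlation` (default) or Euclidean distance.
#' Constant columns (undefined correlation) are excluded with a warning.
#' Leaf order is canonicalized so that it does not depend on input column
#' order.
#'
#' @param x an [lf_matrix], [ratio_matrix], or plain numeric matrix; columns
#'   are clustered.
#' @param dist_method `"correlation"` or `"euclidean"`.
#' @return list with `hclust` (NULL for a single column), `order`, and
#'   `labels`.
#' @export
hierarchical_cluster_samples <- function(x, dist_method = c("correlation", "euclidean")) {
  if (inherits(x, "lf_matrix") || inherits(x, "ratio_matrix")) x <- x$values
  complete_linkage(x, match.arg(dist_method))
}

#' Label-free pipeline from PSMs to normalized LF matrix
#'
#' Runs the LF chain: reuse the TMT quality filters, split precursor areas
#' by reporter ratios with batch median-ratio normalization, aggregate to
#' peptide-level areas (median of the top-3 most intense PSMs scaled to the
#' peptide's summed area per run), score proteins, and normalize.
#'
#' @param psms PSM data.frame.
#' @param sequences named sequence set covering the quantified proteins.
#' @param samples sample metadata.
#' @return list with `lf_raw`, `matrix`, `lf_sums` (see
#'   [normalize_lf_matrix()]).
#' @export
lf_quantify <- function(psms, sequences, samples) {
  sets <- filter_psms(psms)
  quant <- sets$quantification
  med <- channel_median_ratios(quant)
  # peptide-level area per run: sum of PSM areas; channel shares from the
  # median reporter profile of the top-3 most intense PSMs
  key <- paste(quant$batch_id, quant$run_id, quant$peptide_sequence, sep = "\r")
  groups <- split(seq_len(nrow(quant)), key)
  rows <- lapply(groups, function(idx) {
    sub <- quant[idx, , drop = FALSE]
    ord <- order(-sub$precursor_area, sub$spectrum_id)
    top <- sub[ord[seq_len(min(3L, nrow(sub)))], , drop = FALSE]
    prof <- vapply(REPORTER_COLS, function(col)
      stats::median(top[[col]], na.rm = TRUE), numeric(1))
    out <- sub[1L, c("batch_id", "run_id", "peptide_sequence",
                     "protein_group", "is_unique"), drop = FALSE]
    out$precursor_area <- sum(sub$precursor_area)
    for (col in REPORTER_COLS) out[[col]] <- prof[[col]]
    out
  })
  pep <- do.call(rbind, rows)
  rownames(pep) <- NULL
  areas <- split_precursor_areas(pep, median_ratios = med)
  counts <- observable_peptide_counts(sequences)
  lf_raw <- compute_lf_scores(areas, counts, samples)
  c(list(lf_raw = lf_raw), normalize_lf_matrix(lf_raw, samples))
}
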