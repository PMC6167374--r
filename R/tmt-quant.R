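#' TMT reporter-ion quantification from PSM tables
#'
#' Functions turning peptide-spectrum-match (PSM) records with TMT 6-plex
#' reporter intensities into normalized protein-by-sample ratio matrices.
#' Channel 126 carries the pooled internal standard by convention; channels
#' 127--131 carry the five donor samples of a batch.
#'
#' The processing chain is: [filter_psms()] (quality gates),
#' [impute_missing_reporters()] (batch minimum), [normalize_psm_ratios()]
#' (internal-standard ratios times per-channel median ratio),
#' [rollup_peptides()] (median of the up-to-three most intense PSMs),
#' [rollup_proteins()] (median over unique peptides, at least two required),
#' then [studentize_matrix()] or [mean_normalize_matrix()].
#'
#' @name tmt_quant
NULL

psm_required_cols <- function() {
  c("spectrum_id", "batch_id", "run_id", "peptide_sequence", "protein_group",
    "is_unique", "search_rank", "missed_cleavages", "isolation_interference",
    "precursor_area", REPORTER_COLS)
}

validate_psms <- function(psms) {
  missing_cols <- setdiff(psm_required_cols(), names(psms))
  if (length(missing_cols))
    stopf("PSM table lacks required column(s): %s", paste(missing_cols, collapse = ", "))
  rep_mat <- as.matrix(psms[, REPORTER_COLS])
  neg <- which(rowSums(rep_mat < 0, na.rm = TRUE) > 0)
  bad_if <- which(!is.finite(psms$isolation_interference) |
                    psms$isolation_interference < 0 | psms$isolation_interference > 100)
  bad <- union(neg, bad_if)
  if (length(bad))
    stopf("malformed PSM record(s): %s",
          paste(utils::head(psms$spectrum_id[bad], 10L), collapse = ", "))
  invisible(psms)
}

#' Filter PSMs into identification and quantification sets
#'
#' Identification keeps rank-1 search hits only. Quantification additionally
#' requires isolation interference below 30 percent, the summed reporter
#' intensity of the donor channels (127--131, the internal standard excluded)
#' above 30,000, and no missed cleavages. The sum is taken over observed
#' (non-missing) values; imputation happens afterwards.
#'
#' @param psms data.frame of PSM records (see [simulate_psm_table()] for the
#'   column contract).
#' @param max_interference,min_reporter_sum,max_missed_cleavages quality gates;
#'   defaults are the pipeline's standard thresholds.
#' @return list with elements `identification` and `quantification`, both
#'   subsets of `psms`.
#' @examples
#' psms <- simulate_psm_table(
#'   simulate_cohort(cohort_config(n_donors = 5, seed = 1)),
#'   simulate_protein_db(5, seed = 2), seed = 3)
#' sets <- filter_psms(psms)
#' nrow(sets$quantification) <= nrow(sets$identification)
#' @export
filter_psms <- function(psms, max_interference = 30, min_reporter_sum = 30000,
                        max_missed_cleavages = 0) {
  validate_psms(psms)
  ident <- psms[psms$search_rank == 1L, , drop = FALSE]
  donor_sum <- rowSums(as.matrix(ident[, DONOR_REPORTER_COLS]), na.rm = TRUE)
  keep <- ident$isolation_interference < max_interference &
    donor_sum > min_reporter_sum &
    ident$missed_cleavages <= max_missed_cleavages
  list(identification = ident, quantification = ident[keep, , drop = FALSE])
}

#' Impute missing donor-channel reporter intensities
#'
#' Absent values in channels 127--131 are replaced by the minimum reporter
#' intensity observed in those channels within the same TMT batch. Channel
#' 126 (internal standard) is never imputed. Imputed cells are flagged in
#' logical columns `imp_127` .. `imp_131` so that downstream normalization
#' can compute its medians from raw observed intensities only.
#'
#' @param quant quantification-set PSM data.frame.
#' @return `quant` with missing donor reporters filled in and `imp_*` flags.
#' @export
impute_missing_reporters <- function(quant) {
  imp_cols <- paste0("imp_", DONOR_CHANNELS)
  for (col in imp_cols) quant[[col]] <- FALSE
  for (b in unique(quant$batch_id)) {
    idx <- which(quant$batch_id == b)
    mat <- as.matrix(quant[idx, DONOR_REPORTER_COLS])
    if (all(is.na(mat)))
      stopf("batch '%s' has no observed donor reporter values; cannot impute", b)
    bmin <- min(mat, na.rm = TRUE)
    miss <- is.na(mat)
    if (any(miss)) {
      mat[miss] <- bmin
      quant[idx, DONOR_REPORTER_COLS] <- mat
      quant[idx, imp_cols] <- miss
    }
  }
  quant
}

#' Per-batch median ratios between internal standard and donor channels
#'
#' For each batch and donor channel c, the median over quantification-set
#' PSMs of raw `I_126 / I_c`. Imputed values (flagged by
#' [impute_missing_reporters()]) are excluded: the medians are determined
#' from the raw intensities of each channel.
#'
#' @param quant quantification-set PSMs (imputation flags optional).
#' @return data.frame with columns `batch_id`, `channel`, `median_ratio`.
#' @export
channel_median_ratios <- function(quant) {
  out <- list()
  for (b in unique(quant$batch_id)) {
    sub <- quant[quant$batch_id == b, , drop = FALSE]
    for (ch in DONOR_CHANNELS) {
      ic <- sub[[paste0("reporter_", ch)]]
      imp_col <- paste0("imp_", ch)
      observed <- if (imp_col %in% names(sub)) !sub[[imp_col]] else rep(TRUE, nrow(sub))
      ok <- observed & is.finite(ic) & ic > 0 &
        is.finite(sub$reporter_126) & sub$reporter_126 > 0
      med <- if (any(ok)) stats::median(sub$reporter_126[ok] / ic[ok]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        batch_id = b, channel = ch, median_ratio = med,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Normalize PSM-level ratios to the internal standard
#'
#' For each PSM and donor channel c the ratio `I_c / I_126` is multiplied by
#' the per-batch median of the raw `I_126 / I_c` ratios (see
#' [channel_median_ratios()]). This fixes the per-channel median ratio at 1
#' within every batch, correcting mixing errors and loading differences.
#' PSMs with a zero or missing internal-standard intensity are excluded
#' with a warning.
#'
#' @param quant quantification-set PSMs, normally after
#'   [impute_missing_reporters()].
#' @param median_ratios optional precomputed output of
#'   [channel_median_ratios()]; computed from `quant` when `NULL`.
#' @return data.frame with the PSM annotation columns plus `ratio_127` ..
#'   `ratio_131`; the median-ratio table is attached as attribute
#'   `"median_ratios"`.
#' @export
normalize_psm_ratios <- function(quant, median_ratios = NULL) {
  if (is.null(median_ratios)) median_ratios <- channel_median_ratios(quant)
  bad <- !is.finite(quant$reporter_126) | quant$reporter_126 <= 0
  if (any(bad)) {
    warnf("excluding %d PSM(s) with zero or missing internal-standard intensity", sum(bad))
    quant <- quant[!bad, , drop = FALSE]
  }
  keep_cols <- c("spectrum_id", "batch_id", "run_id", "peptide_sequence",
                 "protein_group", "is_unique", "precursor_area")
  out <- quant[, intersect(keep_cols, names(quant)), drop = FALSE]
  key <- paste(median_ratios$batch_id, median_ratios$channel)
  med <- stats::setNames(median_ratios$median_ratio, key)
  for (ch in DONOR_CHANNELS) {
    m <- med[paste(quant$batch_id, ch)]
    out[[paste0("ratio_", ch)]] <-
      (quant[[paste0("reporter_", ch)]] / quant$reporter_126) * as.numeric(m)
  }
  attr(out, "median_ratios") <- median_ratios
  out
}

# Select up to the three PSMs with highest precursor area (ties broken by
# spectrum_id, lexicographic) and take per-channel medians.
top3_median <- function(sub) {
  ord <- order(-sub$precursor_area, sub$spectrum_id)
  top <- sub[ord[seq_len(min(3L, nrow(sub)))], , drop = FALSE]
  vapply(paste0("ratio_", DONOR_CHANNELS),
         function(col) stats::median(top[[col]], na.rm = TRUE), numeric(1))
}

#' Roll PSM ratios up to peptide ratios
#'
#' Per batch and peptide: a single PSM contributes its ratio directly; with
#' two or more, the median ratio of the (at most three) PSMs with highest
#' precursor intensity is used. The same PSM selection applies to all
#' channels.
#'
#' @param ratios output of [normalize_psm_ratios()].
#' @return data.frame keyed by `batch_id`, `peptide_sequence` with
#'   `protein_group`, `is_unique`, `n_psms`, and `ratio_127` .. `ratio_131`.
#' @export
rollup_peptides <- function(ratios) {
  key <- paste(ratios$batch_id, ratios$peptide_sequence, sep = "\r")
  groups <- split(seq_len(nrow(ratios)), key)
  rows <- lapply(groups, function(idx) {
    sub <- ratios[idx, , drop = FALSE]
    med <- top3_median(sub)
    cbind(
      data.frame(batch_id = sub$batch_id[1L],
                 peptide_sequence = sub$peptide_sequence[1L],
                 protein_group = sub$protein_group[1L],
                 is_unique = sub$is_unique[1L],
                 n_psms = nrow(sub),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(med)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll peptide ratios up to a protein ratio matrix
#'
#' The protein value per batch and channel is the median ratio over peptides
#' unique to that protein group; shared peptides are ignored. Proteins with
#' fewer than `min_unique_peptides` unique quantified peptides in a batch are
#' absent from that batch's columns.
#'
#' @param peptides output of [rollup_peptides()].
#' @param samples sample metadata (see [simulate_cohort()]); maps
#'   batch/channel to sample ids and defines column order.
#' @param min_unique_peptides minimum unique peptides per protein (default 2).
#' @return a [ratio_matrix] in state `"raw"`.
#' @export
rollup_proteins <- function(peptides, samples, min_unique_peptides = 2L) {
  upep <- peptides[peptides$is_unique, , drop = FALSE]
  sample_key <- paste(samples$batch_id, samples$channel)
  prot <- sort(unique(upep$protein_group))
  values <- matrix(NA_real_, nrow = length(prot), ncol = nrow(samples),
                   dimnames = list(prot, samples$sample_id))
  for (b in unique(upep$batch_id)) {
    sub <- upep[upep$batch_id == b, , drop = FALSE]
    counts <- table(sub$protein_group)
    ok_prot <- names(counts)[counts >= min_unique_peptides]
    if (!length(ok_prot)) next
    for (ch in DONOR_CHANNELS) {
      col <- which(sample_key == paste(b, ch))
      if (!length(col)) next
      vals <- tapply(sub[[paste0("ratio_", ch)]], sub$protein_group,
                     stats::median, na.rm = TRUE)
      values[ok_prot, col] <- as.numeric(vals[ok_prot])
    }
  }
  values <- values[rowSums(is.finite(values)) > 0L, , drop = FALSE]
  ratio_matrix(values, state = "raw",
               batch = stats::setNames(samples$batch_id, samples$sample_id),
               channel = stats::setNames(samples$channel, samples$sample_id))
}

#' Protein-by-sample ratio matrix container
#'
#' Lightweight S3 container for TMT ratio matrices: a numeric protein-by-
#' sample matrix plus its normalization state (`"raw"`,
#' `"channel_normalized"`, `"studentized"`, or `"mean_normalized"`) and the
#' batch/channel provenance of every column.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#' @param state normalization state label.
#' @param batch,channel named vectors (by sample id) recording provenance.
#' @return object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(values, state = "raw", batch = NULL, channel = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  state <- match.arg(state, c("raw", "channel_normalized", "studentized", "mean_normalized"))
  if (state %in% c("raw", "channel_normalized")) {
    if (any(values <= 0, na.rm = TRUE))
      stopf("raw/normalized ratios must be positive")
  }
  structure(list(values = values, state = state, batch = batch, channel = channel),
            class = "ratio_matrix")
}

#' @exportS3Method base::print
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("ratio_matrix: %d proteins x %d samples [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  if (!is.null(x$batch))
    cat(sprintf("  batches: %d\n", length(unique(x$batch))))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.ratio_matrix <- function(x, ...) x$values

#' @exportS3Method
dim.ratio_matrix <- function(x) dim(x$values)

#' Studentize a ratio matrix per protein
#'
#' Each protein row is transformed to zero mean and unit sample standard
#' deviation over its non-missing entries, i.e. across all TMT experiments
#' of one cell population. Rows with fewer than two non-missing values or
#' zero variance are dropped with a warning.
#'
#' @param x a raw [ratio_matrix] holding one cell population's samples.
#' @return a [ratio_matrix] in state `"studentized"`; dropped row names are
#'   attached as attribute `"dropped"`.
#' @export
studentize_matrix <- function(x) {
  stopifnot(inherits(x, "ratio_matrix"))
  if (x$state != "raw") stopf("studentize_matrix() expects a raw matrix")
  v <- x$values
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1L, stats::sd, na.rm = TRUE)
  n_ok <- rowSums(is.finite(v))
  drop <- n_ok < 2L | !is.finite(sd_) | sd_ == 0
  if (any(drop))
    warnf("dropping %d protein row(s) with <2 values or zero variance", sum(drop))
  v <- (v - mu) / sd_
  v <- v[!drop, , drop = FALSE]
  out <- ratio_matrix(v, state = "studentized", batch = x$batch, channel = x$channel)
  attr(out, "dropped") <- rownames(x$values)[drop]
  out
}

#' Mean-normalize a ratio matrix per protein
#'
#' Each protein row is divided by its mean over non-missing entries, so the
#' output row mean is 1 and regression slopes against age read directly as
#' relative abundance change per year. Used for the pathway tendency slopes,
#' where studentization would inflate slopes of barely-changing proteins.
#'
#' @param x a raw [ratio_matrix].
#' @return a [ratio_matrix] in state `"mean_normalized"`.
#' @export
mean_normalize_matrix <- function(x) {
  stopifnot(inherits(x, "ratio_matrix"))
  if (x$state != "raw") stopf("mean_normalize_matrix() expects a raw matrix")
  v <- x$values
  mu <- rowMeans(v, na.rm = TRUE)
  drop <- !is.finite(mu) | mu <= 0
  if (any(drop))
    warnf("dropping %d protein row(s) with non-positive mean", sum(drop))
  v <- (v / mu)[!drop, , drop = FALSE]
  out <- ratio_matrix(v, state = "mean_normalized", batch = x$batch, channel = x$channel)
  attr(out, "dropped") <- rownames(x$values)[drop]
  out
}

#' Build per-population raw protein ratio matrices from a PSM table
#'
#' Convenience wrapper running the full TMT chain (filter, impute, normalize,
#' peptide and protein rollup) for every cell population present in
#' `samples`.
#'
#' @param psms PSM data.frame.
#' @param samples sample metadata.
#' @param min_unique_peptides minimum unique peptides per protein.
#' @return named list of raw [ratio_matrix] objects, one per population.
#' @export
tmt_protein_matrices <- function(psms, samples, min_unique_peptides = 2L) {
  sets <- filter_psms(psms)
  quant <- impute_missing_reporters(sets$quantification)
  ratios <- normalize_psm_ratios(quant)
  peptides <- rollup_peptides(ratios)
  pops <- unique(samples$population)
  out <- lapply(pops, function(pop) {
    smp <- samples[samples$population == pop, , drop = FALSE]
    pep <- peptides[peptides$batch_id %in% smp$batch_id, , drop = FALSE]
    rollup_proteins(pep, smp, min_unique_peptides = min_unique_peptides)
  })
  stats::setNames(out, pops)
}
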