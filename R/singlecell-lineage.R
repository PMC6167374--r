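#' Single-cell lineage priming: QC, classification, enrichment, slopes
#'
#' QC filters for single CD34+ cell count matrices, size-factor
#' normalization with per-cell mean adjustment, correlation-based marker
#' refinement, the conservative lymphoid/myeloid priming classifier, exact
#' enrichment tests of marker distributions per fraction, and lineage- and
#' age-resolved expression slopes for enzyme gene sets.
#'
#' @name singlecell_lineage
NULL

#' QC filter cells and genes
#'
#' Cells are kept when at least `min_genes` genes reach `min_reads` reads
#' each and the total read count is at least `min_total`; afterwards genes
#' are kept when they reach `min_reads` reads in at least `min_cells` of
#' the remaining cells.
#'
#' @param counts gene-by-cell integer matrix.
#' @param min_genes,min_reads,min_total,min_cells printed thresholds
#'   (defaults 1000 genes at >= 10 reads, total >= 150,000; genes with
#'   >= 10 reads in >= 5 cells).
#' @return list with `counts` (filtered), `removed_cells`, `removed_genes`,
#'   and `empty` (TRUE when nothing survives).
#' @export
qc_filter_cells_genes <- function(counts, min_genes = 1000L, min_reads = 10L,
                                  min_total = 150000, min_cells = 5L) {
  counts <- as.matrix(counts)
  genes_detected <- colSums(counts >= min_reads)
  totals <- colSums(counts)
  keep_cells <- genes_detected >= min_genes & totals >= min_total
  kept <- counts[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(kept >= min_reads) >= min_cells
  out <- kept[keep_genes, , drop = FALSE]
  list(counts = out,
       removed_cells = colnames(counts)[!keep_cells],
       removed_genes = rownames(counts)[!keep_genes],
       empty = ncol(out) == 0L || nrow(out) == 0L)
}

#' Normalize single-cell expression with per-cell mean adjustment
#'
#' Library-size factors (per-cell totals scaled to mean 1), log2 of the
#' size-factor-corrected counts plus one, then subtraction of each cell's
#' mean so the adjusted per-cell mean is zero.
#'
#' @param counts filtered gene-by-cell count matrix.
#' @param cells optional per-cell annotation data.frame (`cell_id`,
#'   `sample_id`, `donor_age`, ...), matched by column name.
#' @return object of class `cell_expression_set`: list with `counts`,
#'   `normalized` (log2, pre-adjustment), `adjusted` (per-cell mean zero),
#'   `size_factors`, `cells`.
#' @export
normalize_cell_expression <- function(counts, cells = NULL) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) stopf("zero-total cell(s); filter first")
  sf <- totals / mean(totals)
  normalized <- log2(sweep(counts, 2L, sf, `/`) + 1)
  adjusted <- sweep(normalized, 2L, colMeans(normalized), `-`)
  if (!is.null(cells)) {
    cells <- cells[match(colnames(counts), cells$cell_id), , drop = FALSE]
  }
  structure(list(counts = counts, normalized = normalized,
                 adjusted = adjusted, size_factors = sf, cells = cells),
            class = "cell_expression_set")
}

#' @exportS3Method base::print
print.cell_expression_set <- function(x, ...) {
  cat(sprintf("cell_expression_set: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Refine lineage marker sets by within-lineage correlation
#'
#' A marker is retained when it has a significant positive Pearson
#' correlation (p below `p_threshold`) with at least one other marker of
#' its own lineage, computed on the adjusted expression across all cells
#' (pooled). Removals are reported; an empty surviving set is an error.
#'
#' @param expr a `cell_expression_set`.
#' @param lymphoid,myeloid candidate marker gene sets (>= 2 genes each).
#' @param p_threshold Pearson significance gate (0.01).
#' @return list with `lymphoid`, `myeloid` (refined sets) and `removed`.
#' @export
refine_lineage_markers <- function(expr, lymphoid, myeloid, p_threshold = 0.01) {
  refine_one <- function(markers, label) {
    markers <- intersect(markers, rownames(expr$adjusted))
    if (length(markers) < 2L)
      stopf("fewer than two %s markers present in the matrix", label)
    keep <- vapply(markers, function(g) {
      others <- setdiff(markers, g)
      any(vapply(others, function(o) {
        a <- expr$adjusted[g, ]; b <- expr$adjusted[o, ]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(FALSE)
        ct <- stats::cor.test(a, b, method = "pearson")
        is.finite(ct$p.value) && ct$estimate > 0 && ct$p.value < p_threshold
      }, logical(1)))
    }, logical(1))
    markers[keep]
  }
  lym <- refine_one(lymphoid, "lymphoid")
  mye <- refine_one(myeloid, "myeloid")
  if (!length(lym) || !length(mye))
    stopf("all markers of one lineage were removed; review the marker sets")
  list(lymphoid = lym, myeloid = mye,
       removed = c(setdiff(intersect(lymphoid, rownames(expr$adjusted)), lym),
                   setdiff(intersect(myeloid, rownames(expr$adjusted)), mye)))
}

# Expression indicator used by the classifier: adjusted normalized value > 0
# (or raw count > 0 behind the flag).
expressed_matrix <- function(expr, genes, use_counts = FALSE) {
  src <- if (use_counts) expr$counts else expr$adjusted
  present <- intersect(genes, rownames(src))
  m <- matrix(FALSE, nrow = length(genes), ncol = ncol(src),
              dimnames = list(genes, colnames(src)))
  if (length(present)) m[present, ] <- src[present, , drop = FALSE] > 0
  m
}

#' Classify cells into lymphoid- or myeloid-primed
#'
#' A cell is called lymphoid-primed when at least half (ceiling) of the
#' refined lymphoid markers are expressed (> 0), neither exclusion gene is
#' expressed, and the symmetric myeloid criterion is not met at the same
#' time; symmetric for myeloid. Everything else is undefined, including
#' cells meeting both criteria.
#'
#' @param expr a `cell_expression_set`.
#' @param lymphoid,myeloid refined marker sets.
#' @param exclusion_genes genes that veto a primed call (default CD19,
#'   CD71).
#' @param use_counts evaluate "expressed" on raw counts instead of adjusted
#'   values.
#' @return data.frame with `cell_id`, `label`, `n_lymphoid_expressed`,
#'   `n_myeloid_expressed`, `exclusion_hit`.
#' @export
classify_cells <- function(expr, lymphoid, myeloid,
                           exclusion_genes = c("CD19", "CD71"),
                           use_counts = FALSE) {
  if (!length(lymphoid) || !length(myeloid)) stopf("empty marker set")
  lym_ex <- expressed_matrix(expr, lymphoid, use_counts)
  mye_ex <- expressed_matrix(expr, myeloid, use_counts)
  exc_ex <- expressed_matrix(expr, exclusion_genes, use_counts)
  n_lym <- colSums(lym_ex)
  n_mye <- colSums(mye_ex)
  exclusion_hit <- colSums(exc_ex) > 0L
  lym_ok <- n_lym >= ceiling(length(lymphoid) / 2)
  mye_ok <- n_mye >= ceiling(length(myeloid) / 2)
  label <- rep("undefined", ncol(expr$counts))
  label[lym_ok & !mye_ok & !exclusion_hit] <- "lymphoid"
  label[mye_ok & !lym_ok & !exclusion_hit] <- "myeloid"
  data.frame(cell_id = colnames(expr$counts), label = label,
             n_lymphoid_expressed = as.integer(n_lym),
             n_myeloid_expressed = as.integer(n_mye),
             exclusion_hit = exclusion_hit,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Marker enrichment of classified fractions (exact test)
#'
#' Per sample and fraction, a two-sided Fisher exact test of the 2x2 table
#' (cell in fraction vs not) x (cell marker-positive vs not), where
#' marker-positive means meeting the half-marker rule of the fraction's
#' lineage (either lineage for the undefined fraction). Degenerate tables
#' (an empty margin) yield p = 1 and are flagged. P values are reported per
#' sample and averaged across samples.
#'
#' @param calls output of [classify_cells()].
#' @param expr a `cell_expression_set` whose `cells` annotation carries
#'   `sample_id`.
#' @param lymphoid,myeloid refined marker sets.
#' @param use_counts passed to the expression indicator.
#' @return list with `per_sample` (data.frame: `sample_id`, `fraction`,
#'   `p`, `degenerate`) and `average` (data.frame: `fraction`, `mean_p`).
#' @export
fraction_marker_enrichment <- function(calls, expr, lymphoid, myeloid,
                                       use_counts = FALSE) {
  if (is.null(expr$cells) || is.null(expr$cells$sample_id))
    stopf("expr$cells with sample_id is required")
  lym_ok <- colSums(expressed_matrix(expr, lymphoid, use_counts)) >=
    ceiling(length(lymphoid) / 2)
  mye_ok <- colSums(expressed_matrix(expr, myeloid, use_counts)) >=
    ceiling(length(myeloid) / 2)
  positive <- list(lymphoid = lym_ok, myeloid = mye_ok,
                   undefined = lym_ok | mye_ok)
  samples <- unique(expr$cells$sample_id)
  rows <- list()
  for (s in samples) {
    in_sample <- expr$cells$sample_id == s
    for (fr in c("lymphoid", "myeloid", "undefined")) {
      in_fraction <- calls$label[in_sample] == fr
      pos <- positive[[fr]][in_sample]
      tab <- table(factor(in_fraction, c(TRUE, FALSE)),
                   factor(pos, c(TRUE, FALSE)))
      degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
      p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, fraction = fr, p = p, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  average <- stats::aggregate(p ~ fraction, data = per_sample, FUN = mean)
  names(average)[2] <- "mean_p"
  list(per_sample = per_sample, average = average)
}

#' Enzyme-marker correlation disparity between lineages
#'
#' Pearson correlations (adjusted expression, across all cells) of every
#' enzyme with every myeloid and every lymphoid marker; the disparity
#' between the myeloid- and lymphoid-correlation distributions is
#' summarized by Cohen's d (pooled sd) and a two-sample t test. Constant
#' genes are excluded; a zero pooled sd is flagged and yields d = NA.
#'
#' @param expr a `cell_expression_set`.
#' @param enzymes enzyme gene set to correlate.
#' @param lymphoid,myeloid marker sets.
#' @return list with `correlations` (data.frame: `enzyme`, `marker`,
#'   `lineage`, `r`), `cohen_d`, `t_p`, `degenerate`.
#' @export
enzyme_lineage_correlation <- function(expr, enzymes, lymphoid, myeloid) {
  a <- expr$adjusted
  usable <- function(genes) {
    genes <- intersect(genes, rownames(a))
    genes[apply(a[genes, , drop = FALSE], 1L, stats::sd) > 0]
  }
  enzymes <- usable(enzymes)
  marker_sets <- list(lymphoid = usable(lymphoid), myeloid = usable(myeloid))
  rows <- list()
  for (lin in names(marker_sets)) {
    for (e in enzymes) for (m in marker_sets[[lin]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = e, marker = m, lineage = lin,
        r = stats::cor(a[e, ], a[m, ]), stringsAsFactors = FALSE)
    }
  }
  cors <- do.call(rbind, rows)
  mye_r <- cors$r[cors$lineage == "myeloid"]
  lym_r <- cors$r[cors$lineage == "lymphoid"]
  d <- cohens_d(mye_r, lym_r)
  degenerate <- is.na(d) && length(mye_r) >= 2L && length(lym_r) >= 2L
  t_p <- if (length(mye_r) >= 2L && length(lym_r) >= 2L &&
             (stats::sd(mye_r) > 0 || stats::sd(lym_r) > 0))
    stats::t.test(mye_r, lym_r)$p.value else NA_real_
  list(correlations = cors, cohen_d = d, t_p = t_p, degenerate = degenerate)
}

#' Lineage- and age-resolved expression slopes for a gene set
#'
#' Per gene and lineage: the median adjusted expression across each
#' sample's cells of that lineage, regressed on donor age (ordinary least
#' squares). Samples lacking a lineage are skipped for it. Two summary
#' tests follow: the lineage effect compares per-gene lymphoid/myeloid
#' expression ratios between the age-regulated and age-stable sets
#' (two-sided rank-sum test); the age effect compares the slope
#' distributions of the two sets with a one-way analysis-of-variance F
#' test.
#'
#' @param expr a `cell_expression_set` with `cells` carrying `sample_id`
#'   and `donor_age`.
#' @param calls output of [classify_cells()].
#' @param age_regulated,age_stable gene sets to contrast.
#' @return list with `slopes` (data.frame: `gene`, `set`, `lineage`,
#'   `slope`, `n_samples`), `expression_ratios` (per gene,
#'   lymphoid/myeloid), `lineage_effect_p`, `age_effect_p`.
#' @export
lineage_age_slopes <- function(expr, calls, age_regulated, age_stable) {
  cells <- expr$cells
  if (is.null(cells$sample_id) || is.null(cells$donor_age))
    stopf("expr$cells needs sample_id and donor_age")
  genes <- list(age_regulated = intersect(age_regulated, rownames(expr$adjusted)),
                age_stable = intersect(age_stable, rownames(expr$adjusted)))
  samples <- unique(cells$sample_id)
  sample_age <- vapply(samples, function(s)
    cells$donor_age[match(s, cells$sample_id)], numeric(1))
  lin_expr <- sweep(expr$counts, 2L, expr$size_factors, `/`)  # linear scale
  slope_rows <- list(); ratio_rows <- list()
  for (set_name in names(genes)) for (g in genes[[set_name]]) {
    for (lin in c("lymphoid", "myeloid")) {
      med <- vapply(samples, function(s) {
        sel <- cells$sample_id == s & calls$label == lin
        if (!any(sel)) return(NA_real_)
        stats::median(expr$adjusted[g, sel])
      }, numeric(1))
      ok <- is.finite(med)
      slope <- if (sum(ok) >= 2L && stats::var(sample_age[ok]) > 0)
        ols_slope(sample_age[ok], med[ok]) else NA_real_
      slope_rows[[length(slope_rows) + 1L]] <- data.frame(
        gene = g, set = set_name, lineage = lin, slope = slope,
        n_samples = sum(ok), stringsAsFactors = FALSE)
    }
    med_lym <- stats::median(lin_expr[g, calls$label == "lymphoid"])
    med_mye <- stats::median(lin_expr[g, calls$label == "myeloid"])
    ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
      gene = g, set = set_name,
      ratio = if (is.finite(med_mye) && med_mye > 0) med_lym / med_mye else NA_real_,
      stringsAsFactors = FALSE)
  }
  slopes <- do.call(rbind, slope_rows)
  ratios <- do.call(rbind, ratio_rows)
  r_reg <- ratios$ratio[ratios$set == "age_regulated"]
  r_st <- ratios$ratio[ratios$set == "age_stable"]
  lineage_effect_p <- if (sum(is.finite(r_reg)) >= 2L && sum(is.finite(r_st)) >= 2L)
    suppressWarnings(stats::wilcox.test(r_reg, r_st, exact = FALSE)$p.value)
  else NA_real_
  sl <- slopes[is.finite(slopes$slope), , drop = FALSE]
  age_effect_p <- if (length(unique(sl$set)) == 2L) {
    fit <- stats::aov(slope ~ set, data = sl)
    summary(fit)[[1]][["Pr(>F)"]][1]
  } else NA_real_
  list(slopes = slopes, expression_ratios = ratios,
       lineage_effect_p = lineage_effect_p, age_effect_p = age_effect_p)
}
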