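#' Cross-cell-population ligand-receptor correlation
#'
#' Correlates age-altered MSC ligands (receptors) with age-altered
#' receptors (ligands) of the other bone marrow cell populations over
#' shared donors, with the inclusion gates and two-axis clustering used for
#' the niche-remodelling correlation matrix.
#'
#' @name ligand_receptor
NULL

#' Ligand-receptor correlations between MSC and the other populations
#'
#' For every annotated pair and both orientations (MSC ligand vs partner
#' receptor; MSC receptor vs partner ligand), the Spearman correlation over
#' shared donors is computed when (i) both proteins are age-altered in
#' their own population (`p < p_gate`, from `assoc`), and (ii) the donor
#' overlap is at least `min_overlap` of the smaller of the two proteins'
#' donor sets. MSC proteins without any partner correlation at
#' `p < p_gate` are removed from the output; non-significant retained cells
#' are marked, not dropped.
#'
#' @param pairs data.frame with `ligand`, `receptor` gene symbols.
#' @param matrices named list of studentized [ratio_matrix] objects (or
#'   plain matrices), one per population, including `"MSC"`.
#' @param assoc named list of age-association tables ([age_correlation()])
#'   per population.
#' @param samples sample metadata (maps columns to donor ids).
#' @param p_gate age-alteration and partner-significance gate (0.1).
#' @param min_overlap donor-overlap bound (0.85).
#' @return data.frame with `msc_protein`, `msc_role`, `partner_protein`,
#'   `partner_role`, `partner_population`, `rho`, `p`, `n_shared_donors`,
#'   `significant`.
#' @export
lr_correlation_matrix <- function(pairs, matrices, assoc, samples,
                                  p_gate = 0.1, min_overlap = 0.85) {
  vals <- lapply(matrices, function(m) if (inherits(m, "ratio_matrix")) m$values else as.matrix(m))
  if (!"MSC" %in% names(vals)) stopf("matrices must include 'MSC'")
  donor_of <- stats::setNames(samples$donor_id, samples$sample_id)
  altered <- lapply(assoc, function(a) a$protein[is.finite(a$p) & a$p < p_gate])
  other_pops <- setdiff(names(vals), "MSC")
  donor_values <- function(pop, protein) {
    m <- vals[[pop]]
    if (!protein %in% rownames(m)) return(NULL)
    v <- m[protein, ]
    ok <- is.finite(v)
    stats::setNames(v[ok], donor_of[colnames(m)[ok]])
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    orientations <- list(
      list(msc = pairs$ligand[i], msc_role = "L",
           partner = pairs$receptor[i], partner_role = "R"),
      list(msc = pairs$receptor[i], msc_role = "R",
           partner = pairs$ligand[i], partner_role = "L"))
    for (o in orientations) {
      if (!o$msc %in% altered$MSC) next
      vm <- donor_values("MSC", o$msc)
      if (is.null(vm)) next
      for (pop in other_pops) {
        if (!o$partner %in% (altered[[pop]] %||% character(0))) next
        vp <- donor_values(pop, o$partner)
        if (is.null(vp)) next
        shared <- intersect(names(vm), names(vp))
        overlap <- length(shared) / min(length(vm), length(vp))
        if (overlap < min_overlap || length(shared) < 3L) next
        st <- spearman_t(vm[shared], vp[shared])
        rows[[length(rows) + 1L]] <- data.frame(
          msc_protein = o$msc, msc_role = o$msc_role,
          partner_protein = o$partner, partner_role = o$partner_role,
          partner_population = pop, rho = st$rho, p = st$p,
          n_shared_donors = length(shared),
          significant = is.finite(st$p) && st$p < p_gate,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(msc_protein = character(), msc_role = character(),
                      partner_protein = character(), partner_role = character(),
                      partner_population = character(), rho = numeric(),
                      p = numeric(), n_shared_donors = integer(),
                      significant = logical(), stringsAsFactors = FALSE))
  # keep only MSC proteins with at least one significant partner correlation
  key <- paste(out$msc_protein, out$msc_role)
  has_sig <- tapply(out$significant, key, any)
  out <- out[has_sig[key], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster a ligand-receptor correlation matrix on both axes
#'
#' Reshapes the long-format correlations to an MSC-protein by
#' partner-protein/population matrix and applies deterministic
#' complete-linkage clustering with Euclidean distance to rows and columns.
#' Missing cells are imputed as 0 (uncorrelated) for the distance
#' computation and reported.
#'
#' @param lr long-format output of [lr_correlation_matrix()].
#' @return list with `matrix` (ordered rho matrix), `row_order`,
#'   `col_order`, `row_hclust`, `col_hclust`, `n_imputed`.
#' @export
cluster_correlation_matrix <- function(lr) {
  if (!nrow(lr)) stopf("empty correlation table")
  rid <- paste(lr$msc_protein, lr$msc_role, sep = ":")
  cid <- paste(lr$partner_population, lr$partner_protein, lr$partner_role, sep = ":")
  m <- matrix(NA_real_, nrow = length(unique(rid)), ncol = length(unique(cid)),
              dimnames = list(sort(unique(rid)), sort(unique(cid))))
  m[cbind(rid, cid)] <- lr$rho
  n_imputed <- sum(is.na(m))
  m0 <- m
  m0[is.na(m0)] <- 0
  row_cl <- if (nrow(m0) > 1L) complete_linkage(t(m0), "euclidean") else
    list(order = 1L, hclust = NULL, labels = rownames(m0))
  col_cl <- if (ncol(m0) > 1L) complete_linkage(m0, "euclidean") else
    list(order = 1L, hclust = NULL, labels = colnames(m0))
  ordered <- m[row_cl$labels[row_cl$order], col_cl$labels[col_cl$order], drop = FALSE]
  list(matrix = ordered, row_order = row_cl$labels[row_cl$order],
       col_order = col_cl$labels[col_cl$order],
       row_hclust = row_cl$hclust, col_hclust = col_cl$hclust,
       n_imputed = n_imputed)
}
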