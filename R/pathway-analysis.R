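#' Pathway-level analytics
#'
#' Gene-set handling (GMT plus a hierarchy sidecar), pathway stoichiometry
#' across cell populations, protein co-abundance distributions, and the
#' redundancy-aware selection plus up/down tendency calls for ageing
#' pathways.
#'
#' @name pathway_analysis
NULL

#' Read pathway definitions from a GMT file with a hierarchy sidecar
#'
#' One pathway per GMT row (`id<TAB>name<TAB>member...`). The hierarchy
#' table maps pathway id to its top-level category and an integer depth
#' (smaller = more general); pathways absent from it get level 0 with a
#' warning. Rows with no members are rejected with a warning; duplicate ids
#' are an error.
#'
#' @param gmt_file path to a GMT file.
#' @param hierarchy_file optional TSV with columns `id`, `top_hierarchy`,
#'   `level`.
#' @return data.frame with `id`, `name`, `top_hierarchy`, `level`,
#'   `n_members`, and a list-column `members`.
#' @export
load_pathways <- function(gmt_file, hierarchy_file = NULL) {
  lines <- readLines(gmt_file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("duplicate pathway id(s): %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  members <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warnf("rejecting %d pathway row(s) with no members", sum(empty))
  }
  out <- data.frame(id = ids[!empty],
                    name = vapply(parts[!empty], `[`, character(1), 2L),
                    top_hierarchy = NA_character_, level = 0L,
                    stringsAsFactors = FALSE)
  out$members <- members[!empty]
  out$n_members <- lengths(out$members)
  if (!is.null(hierarchy_file)) {
    h <- utils::read.delim(hierarchy_file, stringsAsFactors = FALSE)
    m <- match(out$id, h$id)
    unknown <- is.na(m)
    if (any(unknown))
      warnf("%d pathway(s) missing from the hierarchy table; level set to 0",
            sum(unknown))
    out$top_hierarchy[!unknown] <- h$top_hierarchy[m[!unknown]]
    out$level[!unknown] <- h$level[m[!unknown]]
  }
  out
}

#' Write pathway definitions to GMT (+ hierarchy sidecar)
#'
#' @param pathways data.frame as returned by [load_pathways()].
#' @param gmt_file,hierarchy_file output paths (hierarchy optional).
#' @return invisibly, the paths written.
#' @export
write_pathways <- function(pathways, gmt_file, hierarchy_file = NULL) {
  lines <- vapply(seq_len(nrow(pathways)), function(i)
    paste(c(pathways$id[i], pathways$name[i], pathways$members[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, gmt_file)
  if (!is.null(hierarchy_file)) {
    utils::write.table(
      data.frame(id = pathways$id, top_hierarchy = pathways$top_hierarchy,
                 level = pathways$level),
      hierarchy_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(gmt_file, hierarchy_file))
}

#' Pathway stoichiometry across cell populations
#'
#' For each pathway of 5--100 quantified members: within every population
#' and sample, member abundances are divided by the median abundance of the
#' pathway's quantified members in that sample, removing pathway-level
#' shifts. Each member with donor coverage above `min_coverage` in at least
#' two populations is cross-compared between all such population pairs with
#' a two-sided Wilcoxon rank-sum test; the mean of its pairwise p values is
#' recorded. Benjamini-Hochberg adjustment is applied over all member-level
#' mean p values across all pathways, and the fraction of a pathway that
#' changed is the share of tested members with adjusted p below `alpha`.
#' The pathway's mean abundance is the average over populations of the
#' median member abundance.
#'
#' @param lf_by_pop named list (by population) of protein-by-donor-sample
#'   abundance matrices (raw LF scores).
#' @param pathways pathway data.frame from [load_pathways()].
#' @param size_range pathway size window on quantified members (default
#'   c(5, 100)).
#' @param min_coverage strict per-population donor-coverage bound (0.15).
#' @param alpha significance level on adjusted p values.
#' @return list with `pathways` (data.frame: `id`, `mean_abundance`,
#'   `fraction_changed`, `n_quantified`, `n_tested`) and `members`
#'   (data.frame: `id`, `protein`, `mean_p`, `adj_p`).
#' @export
pathway_stoichiometry <- function(lf_by_pop, pathways, size_range = c(5, 100),
                                  min_coverage = 0.15, alpha = 0.05) {
  lf_by_pop <- lapply(lf_by_pop, function(m) if (inherits(m, "lf_matrix")) m$values else as.matrix(m))
  pops <- names(lf_by_pop)
  quantified <- unique(unlist(lapply(lf_by_pop, rownames)))
  member_rows <- list()
  path_rows <- list()
  for (i in seq_len(nrow(pathways))) {
    members <- intersect(pathways$members[[i]], quantified)
    nq <- length(members)
    if (nq < size_range[1] || nq > size_range[2]) next
    # per population: normalized member values (member x sample), divided by
    # the per-sample median over the pathway's quantified members
    norm_vals <- list()
    pop_medians <- numeric(0)
    for (pop in pops) {
      m <- lf_by_pop[[pop]]
      pm <- m[intersect(members, rownames(m)), , drop = FALSE]
      if (!nrow(pm)) next
      med_per_sample <- apply(pm, 2L, stats::median, na.rm = TRUE)
      ok_cols <- is.finite(med_per_sample) & med_per_sample > 0
      norm_vals[[pop]] <- sweep(pm[, ok_cols, drop = FALSE], 2L,
                                med_per_sample[ok_cols], `/`)
      pop_medians[pop] <- stats::median(pm, na.rm = TRUE)
    }
    mean_abundance <- mean(pop_medians, na.rm = TRUE)
    n_tested <- 0L
    for (g in members) {
      vals <- lapply(norm_vals, function(nv)
        if (g %in% rownames(nv)) nv[g, ][is.finite(nv[g, ])] else numeric(0))
      n_samples <- vapply(norm_vals, ncol, integer(1))
      covered <- names(vals)[mapply(function(v, n) n > 0 && length(v) / n > min_coverage,
                                    vals, n_samples[names(vals)])]
      if (length(covered) < 2L) next
      ps <- c()
      cmb <- utils::combn(covered, 2L)
      for (k in seq_len(ncol(cmb))) {
        a <- vals[[cmb[1, k]]]; b <- vals[[cmb[2, k]]]
        if (length(a) < 2L || length(b) < 2L) next
        ps <- c(ps, suppressWarnings(
          stats::wilcox.test(a, b, exact = FALSE)$p.value))
      }
      if (!length(ps)) next
      n_tested <- n_tested + 1L
      member_rows[[length(member_rows) + 1L]] <- data.frame(
        id = pathways$id[i], protein = g, mean_p = mean(ps),
        stringsAsFactors = FALSE)
    }
    path_rows[[length(path_rows) + 1L]] <- data.frame(
      id = pathways$id[i], mean_abundance = mean_abundance,
      n_quantified = nq, n_tested = n_tested, stringsAsFactors = FALSE)
  }
  members_df <- do.call(rbind, member_rows)
  paths_df <- do.call(rbind, path_rows)
  if (is.null(paths_df))
    return(list(pathways = data.frame(), members = data.frame()))
  if (!is.null(members_df)) {
    members_df$adj_p <- stats::p.adjust(members_df$mean_p, method = "BH")
    frac <- tapply(members_df$adj_p < alpha, members_df$id, mean)
    paths_df$fraction_changed <- as.numeric(frac[paths_df$id])
    paths_df$fraction_changed[is.na(paths_df$fraction_changed) & paths_df$n_tested == 0L] <- NA_real_
  } else {
    members_df <- data.frame(id = character(), protein = character(),
                             mean_p = numeric(), adj_p = numeric())
    paths_df$fraction_changed <- NA_real_
  }
  rownames(paths_df) <- NULL
  list(pathways = paths_df, members = members_df)
}

#' Co-abundance correlation distributions
#'
#' Pairwise Pearson correlations over shared samples for (i) pairs of
#' proteins in the same annotated complex, (ii) pairs in the same pathway
#' that are not already co-complexed, and (iii) background pairs of
#' proteins assigned to neither complexes nor pathways. Pairs sharing fewer
#' than `min_shared` samples are skipped.
#'
#' @param x a [ratio_matrix] or protein-by-sample matrix.
#' @param complexes,pathways named lists of member character vectors.
#' @param min_shared minimum shared samples per pair (default 3).
#' @param max_background cap on background pairs (sampled with `seed`).
#' @param seed seed for background subsampling.
#' @return list of numeric vectors `complex`, `pathway`, `background`.
#' @export
coabundance_distributions <- function(x, complexes, pathways, min_shared = 3L,
                                      max_background = 20000L, seed = 1L) {
  v <- if (inherits(x, "ratio_matrix")) x$values else as.matrix(x)
  prots <- rownames(v)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pairs_of <- function(sets) {
    out <- character(0)
    for (s in sets) {
      s <- sort(intersect(s, prots))
      if (length(s) >= 2L) {
        cmb <- utils::combn(s, 2L)
        out <- c(out, pair_key(cmb[1L, ], cmb[2L, ]))
      }
    }
    unique(out)
  }
  complex_pairs <- pairs_of(complexes)
  pathway_pairs <- setdiff(pairs_of(pathways), complex_pairs)
  annotated <- unique(c(unlist(complexes), unlist(pathways)))
  free <- sort(setdiff(prots, annotated))
  background_pairs <- character(0)
  if (length(free) >= 2L) {
    cmb <- utils::combn(free, 2L)
    background_pairs <- pair_key(cmb[1L, ], cmb[2L, ])
    if (length(background_pairs) > max_background) {
      set.seed(seed)
      background_pairs <- sample(background_pairs, max_background)
    }
  }
  corr_of <- function(keys) {
    if (!length(keys)) return(numeric(0))
    ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    r <- vapply(seq_len(nrow(ab)), function(k) {
      a <- v[ab[k, 1L], ]; b <- v[ab[k, 2L], ]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < min_shared) return(NA_real_)
      suppressWarnings(stats::cor(a[ok], b[ok]))
    }, numeric(1))
    r[is.finite(r)]
  }
  list(complex = corr_of(complex_pairs),
       pathway = corr_of(pathway_pairs),
       background = corr_of(background_pairs))
}

#' Select ageing pathways with redundancy removal
#'
#' Admission requires 5--150 members, a quantified fraction above
#' `min_quant_frac`, and a significant fraction above `min_sig_frac` with
#' at least `min_sig` significantly age-altered members. Candidates with
#' identical significant sets are collapsed to one representative (largest
#' membership, then smaller hierarchy level, then id). A remaining
#' candidate is dropped when its significant set is a strict subset of
#' another remaining candidate's set, unless it holds at least one
#' significant protein unique among all remaining candidates. Coverage is
#' evaluated simultaneously against all candidates, so the outcome is
#' independent of input order.
#'
#' @param pathways pathway data.frame from [load_pathways()].
#' @param assoc age-association table ([age_correlation()]) for one
#'   population; its proteins define what counts as quantified, its
#'   `significant` flags what counts as age-altered.
#' @param size_range member-count window (default c(5, 150)).
#' @param min_quant_frac strict bound on quantified fraction (0.30).
#' @param min_sig_frac strict bound on significant fraction of the
#'   quantified (0.20).
#' @param min_sig minimum significant members (3).
#' @return data.frame of retained pathways with `id`, `n_members`,
#'   `n_quantified`, `n_significant`, and list-column `sig_members`; the
#'   admitted-but-redundant ids are attached as attribute `"removed"`.
#' @export
select_age_pathways <- function(pathways, assoc, size_range = c(5, 150),
                                min_quant_frac = 0.30, min_sig_frac = 0.20,
                                min_sig = 3L) {
  quantified <- assoc$protein
  significant <- assoc$protein[assoc$significant]
  cand <- list()
  for (i in seq_len(nrow(pathways))) {
    mem <- pathways$members[[i]]
    nm <- length(mem)
    if (nm < size_range[1] || nm > size_range[2]) next
    q <- intersect(mem, quantified)
    if (length(q) / nm <= min_quant_frac) next
    s <- sort(intersect(mem, significant))
    if (length(q) == 0L || length(s) / length(q) <= min_sig_frac) next
    if (length(s) < min_sig) next
    cand[[length(cand) + 1L]] <- list(id = pathways$id[i], n_members = nm,
                                      n_quantified = length(q),
                                      n_significant = length(s),
                                      level = pathways$level[i], sig = s)
  }
  if (!length(cand))
    return(data.frame(id = character(), n_members = integer(),
                      n_quantified = integer(), n_significant = integer()))
  cand <- cand[order(vapply(cand, `[[`, character(1), "id"))]
  sig_key <- vapply(cand, function(p) paste(p$sig, collapse = "\r"), character(1))
  # collapse identical significant sets: largest pathway, then smaller
  # (more general) hierarchy level, then id
  keep_rep <- logical(length(cand))
  for (key in unique(sig_key)) {
    grp <- which(sig_key == key)
    if (length(grp) == 1L) { keep_rep[grp] <- TRUE; next }
    sz <- vapply(cand[grp], `[[`, numeric(1), "n_members")
    lv <- vapply(cand[grp], `[[`, numeric(1), "level")
    ord <- order(-sz, lv, vapply(cand[grp], `[[`, character(1), "id"))
    keep_rep[grp[ord[1L]]] <- TRUE
  }
  cand <- cand[keep_rep]
  all_sig <- unlist(lapply(cand, `[[`, "sig"))
  unique_prot <- names(table(all_sig))[table(all_sig) == 1L]
  removed <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (any(cand[[i]]$sig %in% unique_prot)) next
    covered <- any(vapply(seq_along(cand), function(j)
      j != i && all(cand[[i]]$sig %in% cand[[j]]$sig), logical(1)))
    removed[i] <- covered
  }
  kept <- cand[!removed]
  out <- data.frame(id = vapply(kept, `[[`, character(1), "id"),
                    n_members = vapply(kept, function(p) as.integer(p$n_members), integer(1)),
                    n_quantified = vapply(kept, function(p) as.integer(p$n_quantified), integer(1)),
                    n_significant = vapply(kept, function(p) as.integer(p$n_significant), integer(1)),
                    stringsAsFactors = FALSE)
  out$sig_members <- lapply(kept, `[[`, "sig")
  attr(out, "removed") <- vapply(cand[removed], `[[`, character(1), "id")
  out
}

#' Classify a pathway's ageing tendency
#'
#' The average per-year slope of a pathway's significantly age-altered
#' members is banded: absolute average within `band` (default 0.001 per
#' year, i.e. 4 percent over a 40-year span) means no tendency; above the
#' band, at least three up-regulated members make the call `strong_up` and
#' one or two make it `weak_up`; symmetric for down.
#'
#' @param slopes per-year slopes of the pathway's significant members.
#' @param band no-tendency half-width (0.001 per year).
#' @return one of `"strong_up"`, `"weak_up"`, `"strong_down"`,
#'   `"weak_down"`, `"none"`.
#' @export
classify_pathway_tendency <- function(slopes, band = 0.001) {
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) return("none")
  avg <- mean(slopes)
  if (abs(avg) <= band) return("none")
  if (avg > band) {
    n_up <- sum(slopes > 0)
    if (n_up >= 3L) return("strong_up")
    if (n_up >= 1L) return("weak_up")
    return("none")
  }
  n_down <- sum(slopes < 0)
  if (n_down >= 3L) return("strong_down")
  if (n_down >= 1L) return("weak_down")
  "none"
}

#' Ageing pathway results for one population
#'
#' Combines [select_age_pathways()] with per-pathway average slopes of the
#' significant members and the tendency call.
#'
#' @param pathways pathway data.frame.
#' @param assoc age-association table for the population.
#' @param slopes per-protein slope table from [age_slopes()].
#' @param population population label.
#' @inheritParams select_age_pathways
#' @param band tendency band (per year).
#' @return data.frame with `id`, `population`, `n_members`, `n_quantified`,
#'   `n_significant`, `avg_slope`, `tendency`.
#' @export
pathway_age_results <- function(pathways, assoc, slopes, population,
                                size_range = c(5, 150), min_quant_frac = 0.30,
                                min_sig_frac = 0.20, min_sig = 3L, band = 0.001) {
  sel <- select_age_pathways(pathways, assoc, size_range = size_range,
                             min_quant_frac = min_quant_frac,
                             min_sig_frac = min_sig_frac, min_sig = min_sig)
  if (!nrow(sel)) {
    sel$avg_slope <- numeric(0); sel$tendency <- character(0)
    sel$population <- character(0)
    return(sel)
  }
  slope_of <- stats::setNames(slopes$slope, slopes$protein)
  sel$population <- population
  sel$avg_slope <- vapply(sel$sig_members, function(s)
    mean(slope_of[s], na.rm = TRUE), numeric(1))
  sel$tendency <- vapply(sel$sig_members, function(s)
    classify_pathway_tendency(slope_of[s][is.finite(slope_of[s])], band = band),
    character(1))
  sel
}
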