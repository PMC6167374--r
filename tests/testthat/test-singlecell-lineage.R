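
test_that("QC removes exactly the cells and genes violating the thresholds", {
  m <- make_qc_fixture()
  res <- qc_filter_cells_genes(m)
  expect_setequal(res$removed_cells, c("few_genes", "low_total"))
  # genes with >= 10 reads in >= 5 cells: the five good cells express
  # genes 1..1100; everything else goes
  expect_setequal(res$removed_genes, sprintf("G%04d", 1101:1600))
  expect_equal(ncol(res$counts), 5L)
  expect_false(res$empty)
  # empty result is reported, not an error
  res0 <- qc_filter_cells_genes(m[, "low_total", drop = FALSE])
  expect_true(res0$empty)
})

test_that("normalization adjusts to zero per-cell mean and size invariance", {
  set.seed(101)
  counts <- matrix(rpois(30 * 10, 20), nrow = 30,
                   dimnames = list(paste0("G", 1:30), paste0("C", 1:10)))
  expr <- normalize_cell_expression(counts)
  expect_true(all(abs(colMeans(expr$adjusted)) < 1e-9))
  # doubling one cell's counts leaves its adjusted profile unchanged up to
  # the +1 pseudocount (the size factor absorbs the depth change)
  doubled <- counts
  doubled[, 3] <- doubled[, 3] * 2L
  expr2 <- normalize_cell_expression(doubled)
  expect_equal(expr2$adjusted[, 3], expr$adjusted[, 3], tolerance = 0.01)
  # single-gene matrix: everything adjusts to zero
  one <- matrix(5L, 1, 4, dimnames = list("G1", paste0("C", 1:4)))
  expect_true(all(normalize_cell_expression(one)$adjusted == 0))
})

test_that("marker refinement keeps co-driven markers and drops independents", {
  set.seed(103)
  n_cells <- 500
  factor_l <- rnorm(n_cells)
  mk_l <- paste0("L", 1:4); mk_m <- paste0("M", 1:4)
  a <- rbind(
    t(sapply(mk_l, function(g) factor_l + rnorm(n_cells, sd = 0.5))),
    t(sapply(mk_m, function(g) rnorm(n_cells) + rep(c(2, 0), each = n_cells / 2))),
    INDEP = rnorm(n_cells),
    BG1 = rnorm(n_cells))
  colnames(a) <- paste0("C", 1:n_cells)
  expr <- structure(list(counts = a, normalized = a, adjusted = a,
                         size_factors = rep(1, n_cells), cells = NULL),
                    class = "cell_expression_set")
  ref <- refine_lineage_markers(expr, c(mk_l, "INDEP"), mk_m)
  expect_setequal(ref$lymphoid, mk_l)
  expect_true("INDEP" %in% ref$removed)
  # two-marker lineage where both correlate stays intact
  ref2 <- refine_lineage_markers(expr, mk_l[1:2], mk_m)
  expect_setequal(ref2$lymphoid, mk_l[1:2])
})

test_that("an independent marker is removed in most replicates", {
  removed <- 0L
  set.seed(107)
  for (r in 1:50) {
    n_cells <- 300
    f <- rnorm(n_cells)
    mk <- t(sapply(1:4, function(i) f + rnorm(n_cells, sd = 0.5)))
    rownames(mk) <- paste0("L", 1:4)
    a <- rbind(mk, INDEP = rnorm(n_cells),
               M1 = f + rnorm(n_cells, sd = 0.5),
               M2 = f + rnorm(n_cells, sd = 0.5))
    colnames(a) <- paste0("C", 1:n_cells)
    expr <- structure(list(counts = a, normalized = a, adjusted = a,
                           size_factors = rep(1, n_cells), cells = NULL),
                      class = "cell_expression_set")
    ref <- refine_lineage_markers(expr, c(paste0("L", 1:4), "INDEP"),
                                  c("M1", "M2"))
    if ("INDEP" %in% ref$removed) removed <- removed + 1L
  }
  expect_gte(removed / 50, 0.95)
})

make_manual_expr <- function(adjusted, cells = NULL) {
  structure(list(counts = pmax(adjusted, 0), normalized = adjusted,
                 adjusted = adjusted,
                 size_factors = rep(1, ncol(adjusted)), cells = cells),
            class = "cell_expression_set")
}

test_that("classification applies the half-marker and exclusion rules", {
  lym <- paste0("L", 1:12); mye <- paste0("M", 1:8)
  genes <- c(lym, mye, "CD19", "CD71")
  cell <- function(l_on, m_on, cd19 = 0, cd71 = 0) {
    v <- setNames(rep(-1, length(genes)), genes)
    if (l_on > 0) v[lym[seq_len(l_on)]] <- 1
    if (m_on > 0) v[mye[seq_len(m_on)]] <- 1
    v["CD19"] <- cd19; v["CD71"] <- cd71
    v
  }
  adj <- cbind(lym7 = cell(7, 0),            # 7/12 lymphoid -> lymphoid
               lym_cd19 = cell(7, 0, cd19 = 1),  # exclusion veto
               both = cell(7, 4),            # meets both -> undefined
               mye4 = cell(0, 4),            # 4/8 myeloid -> myeloid
               weak = cell(5, 3))            # below half on both -> undefined
  expr <- make_manual_expr(adj)
  calls <- classify_cells(expr, lym, mye)
  expect_equal(calls$label,
               c("lymphoid", "undefined", "undefined", "myeloid", "undefined"))
  expect_equal(calls$exclusion_hit, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # a primed label implies no exclusion hit
  expect_true(all(!calls$exclusion_hit[calls$label != "undefined"]))
})

test_that("classification is invariant to gene order and non-marker scaling", {
  sim <- simulate_singlecell_counts(150, seed = 109)
  expr <- normalize_cell_expression(sim$counts, sim$cells)
  mk <- default_marker_sets()
  base <- classify_cells(expr, mk$lymphoid, mk$myeloid)
  # permute gene rows
  perm <- sample(nrow(sim$counts))
  expr_p <- normalize_cell_expression(sim$counts[perm, ], sim$cells)
  expect_equal(classify_cells(expr_p, mk$lymphoid, mk$myeloid)$label, base$label)
  # scaling a non-marker gene moves per-cell means only marginally and the
  # raw-count mode is exactly invariant
  counts2 <- sim$counts
  counts2["BG0001", ] <- counts2["BG0001", ] * 3L
  expr_s <- normalize_cell_expression(counts2, sim$cells)
  expect_equal(classify_cells(expr_s, mk$lymphoid, mk$myeloid,
                              use_counts = TRUE)$label,
               classify_cells(expr, mk$lymphoid, mk$myeloid,
                              use_counts = TRUE)$label)
})

test_that("Fisher enrichment p values match the hypergeometric oracle", {
  # {{10,0},{0,10}}: two-sided p = 2 / C(20,10)
  expect_equal(oracle_fisher_p(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               2 / choose(20, 10), tolerance = 1e-9)
  # exhaustive agreement for all tables with small totals
  for (n in 2:16) {
    for (r1 in 0:n) for (c1 in 0:n) {
      for (a in max(0, r1 + c1 - n):min(r1, c1)) {
        tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2)
        if (any(tab < 0)) next
        expect_equal(fisher.test(tab)$p.value,
                     oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("fraction enrichment flags degenerate tables and finds structure", {
  lym <- paste0("L", 1:4); mye <- paste0("M", 1:4)
  n <- 40
  adj <- rbind(matrix(rep(c(1, -1), each = 2 * n), nrow = 4,
                      dimnames = list(lym, NULL))[, 1:n],
               matrix(-1, 4, n, dimnames = list(mye, NULL)))
  adj[lym, 21:40] <- -1       # only cells 1..20 are lymphoid-positive
  colnames(adj) <- paste0("C", 1:n)
  cells <- data.frame(cell_id = colnames(adj), sample_id = "S1",
                      donor_age = 30, stringsAsFactors = FALSE)
  expr <- make_manual_expr(adj, cells)
  calls <- classify_cells(expr, lym, mye)
  res <- fraction_marker_enrichment(calls, expr, lym, mye)
  lym_row <- res$per_sample[res$per_sample$fraction == "lymphoid", ]
  expect_lt(lym_row$p, 1e-6)
  # myeloid fraction is empty -> degenerate, p = 1
  mye_row <- res$per_sample[res$per_sample$fraction == "myeloid", ]
  expect_true(mye_row$degenerate)
  expect_equal(mye_row$p, 1)
})

test_that("enzyme-marker correlation disparity is summarized by Cohen's d", {
  set.seed(113)
  sim <- simulate_singlecell_counts(400, seed = 113)
  expr <- normalize_cell_expression(sim$counts, sim$cells)
  mk <- default_marker_sets()
  res <- enzyme_lineage_correlation(expr, mk$enzymes_age, mk$lymphoid, mk$myeloid)
  # age-regulated enzymes are co-driven with the myeloid block
  expect_gt(res$cohen_d, 0)
  expect_lt(res$t_p, 0.05)
  # identical distributions give d = 0
  expect_equal(cohens_d_public <- marrowquant:::cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # zero-variance guard
  expect_true(is.na(marrowquant:::cohens_d(c(0, 0, 0, 0), c(2, 2, 2, 2))))
})

test_that("lineage and age effects on enzymes are recovered from a plant", {
  mk <- default_marker_sets()
  age_eff <- data.frame(gene = mk$enzymes_age,
                        lineage = "myeloid", slope = 0.03,
                        stringsAsFactors = FALSE)
  sim <- simulate_singlecell_counts(600, age_effect = age_eff, seed = 127)
  expr <- normalize_cell_expression(sim$counts, sim$cells)
  calls <- classify_cells(expr, mk$lymphoid, mk$myeloid)
  res <- lineage_age_slopes(expr, calls, mk$enzymes_age, mk$enzymes_stable)
  sl <- res$slopes
  mye_reg <- sl$slope[sl$set == "age_regulated" & sl$lineage == "myeloid"]
  mye_st <- sl$slope[sl$set == "age_stable" & sl$lineage == "myeloid"]
  expect_gt(mean(mye_reg, na.rm = TRUE), mean(mye_st, na.rm = TRUE))
  # age-regulated enzymes are myeloid-elevated: lymphoid/myeloid ratio < 1
  r <- res$expression_ratios
  expect_lt(median(r$ratio[r$set == "age_regulated"], na.rm = TRUE),
            median(r$ratio[r$set == "age_stable"], na.rm = TRUE))
  expect_lt(res$lineage_effect_p, 0.05)
  # lineage-neutral (age-stable) genes sit near ratio 1 on clean data
  expect_true(all(abs(r$ratio[r$set == "age_stable"] - 1) < 0.25))
  # constant expression yields slope zero
  adj <- matrix(0.5, nrow = 1, ncol = 8,
                dimnames = list("G1", paste0("C", 1:8)))
  cells <- data.frame(cell_id = colnames(adj),
                      sample_id = rep(c("S1", "S2", "S3", "S4"), each = 2),
                      donor_age = rep(c(25, 27, 53, 55), each = 2))
  expr0 <- make_manual_expr(adj, cells)
  calls0 <- data.frame(cell_id = colnames(adj),
                       label = rep(c("lymphoid", "myeloid"), 4),
                       stringsAsFactors = FALSE)
  res0 <- lineage_age_slopes(expr0, calls0, "G1", character(0))
  expect_equal(res0$slopes$slope, c(0, 0))
})
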