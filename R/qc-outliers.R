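#' Quality metrics and PCA/HDR sample outlier rejection
#'
#' Labelling efficiency, replicate reproducibility metrics, and sample-level
#' outlier detection: PCA on log2 ratios followed by a bivariate kernel
#' density on the first two components; samples outside the 97 percent
#' highest-density region (HDR) are flagged and discarded.
#'
#' @name qc_outliers
NULL

#' TMT labelling efficiency per batch
#'
#' Per batch: 100 times the number of completely labelled PSMs over the
#' total number of identified PSMs, plus the median across batches.
#'
#' @param psms PSM data.frame with a logical `fully_labelled` column.
#' @return list with `per_batch` (data.frame: `batch_id`, `n_total`,
#'   `n_labelled`, `efficiency_pct`) and `median_pct`.
#' @export
labelling_efficiency <- function(psms) {
  if (!"fully_labelled" %in% names(psms))
    stopf("'fully_labelled' flags are required")
  tab <- lapply(split(psms$fully_labelled, psms$batch_id), function(fl) {
    c(n_total = length(fl), n_labelled = sum(fl))
  })
  per_batch <- data.frame(batch_id = names(tab),
                          do.call(rbind, tab), row.names = NULL,
                          stringsAsFactors = FALSE)
  per_batch$efficiency_pct <- 100 * per_batch$n_labelled / per_batch$n_total
  list(per_batch = per_batch, median_pct = stats::median(per_batch$efficiency_pct))
}

#' Replicate reproducibility metrics
#'
#' Pairwise Pearson correlations between replicate ratio vectors and the
#' per-protein coefficient of variation (sd/mean, in percent) across
#' replicates, summarized by its median.
#'
#' @param ratios numeric matrix, proteins in rows, replicates in columns
#'   (at least two replicates sharing at least three proteins).
#' @return list with `pairwise` (data.frame: `rep_a`, `rep_b`, `r`),
#'   `mean_r`, `cv_pct` (per protein), `median_cv_pct`.
#' @export
replicate_metrics <- function(ratios) {
  ratios <- as.matrix(ratios)
  if (ncol(ratios) < 2L) stopf("at least two replicates required")
  if (is.null(colnames(ratios))) colnames(ratios) <- paste0("R", seq_len(ncol(ratios)))
  pairs <- utils::combn(ncol(ratios), 2L)
  pw <- apply(pairs, 2L, function(ij) {
    a <- ratios[, ij[1]]; b <- ratios[, ij[2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) stopf("replicates share fewer than three proteins")
    stats::cor(a[ok], b[ok])
  })
  pairwise <- data.frame(rep_a = colnames(ratios)[pairs[1L, ]],
                         rep_b = colnames(ratios)[pairs[2L, ]],
                         r = pw, stringsAsFactors = FALSE)
  mu <- rowMeans(ratios, na.rm = TRUE)
  sd_ <- apply(ratios, 1L, stats::sd, na.rm = TRUE)
  cv <- 100 * sd_ / mu
  list(pairwise = pairwise, mean_r = mean(pw), cv_pct = cv,
       median_cv_pct = stats::median(cv, na.rm = TRUE))
}

# Gaussian product-kernel density with Scott's bandwidth (h_j = sd_j *
# n^(-1/6) for two dimensions), evaluated at the data points themselves.
kde2_at_points <- function(pc) {
  n <- nrow(pc)
  h <- apply(pc, 2L, stats::sd) * n^(-1 / 6)
  if (any(!is.finite(h) | h == 0)) return(NULL)   # degenerate density
  dens <- numeric(n)
  for (i in seq_len(n)) {
    z1 <- (pc[i, 1] - pc[, 1]) / h[1]
    z2 <- (pc[i, 2] - pc[, 2]) / h[2]
    dens[i] <- mean(stats::dnorm(z1) * stats::dnorm(z2)) / (h[1] * h[2])
  }
  dens
}

#' Detect outlier samples by PCA and highest-density regions
#'
#' PCA is run on the log2 matrix restricted to proteins quantified in all
#' samples (rows centred, not scaled). A bivariate Gaussian kernel density
#' with Scott's bandwidth is estimated on (PC1, PC2) and evaluated at each
#' sample. Following the density-quantile HDR construction, the L percent
#' region is bounded by the `1 - L/100` quantile of the sample densities;
#' each sample is annotated with the smallest region of 50, 90, 95, or 97
#' percent that contains it, and samples outside the 97 percent region are
#' flagged as outliers. A degenerate (zero-variance) density yields no
#' outliers, with a warning.
#'
#' @param mat numeric matrix of log2 ratios, proteins in rows, samples in
#'   columns (at least 5 samples).
#' @param levels HDR probability levels in percent, increasing; the last is
#'   the rejection boundary.
#' @return object of class `outlier_report`: list with `samples`
#'   (data.frame: `sample_id`, `pc1`, `pc2`, `density`, `hdr_level`,
#'   `outlier`), `retained`, `discarded`, `n_retained`, `n_discarded`.
#' @export
detect_outlier_samples <- function(mat, levels = c(50, 90, 95, 97)) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 5L) stopf("at least 5 samples required")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  complete <- rowSums(!is.finite(mat)) == 0L
  x <- mat[complete, , drop = FALSE]
  if (nrow(x) < 2L) stopf("fewer than two completely quantified proteins")
  x <- x - rowMeans(x)                       # centre proteins, no scaling
  n <- ncol(x)
  pca <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  pc <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  if (ncol(pc) < 2L) pc <- cbind(pc, 0)
  dens <- kde2_at_points(pc)
  report <- data.frame(sample_id = colnames(mat), pc1 = pc[, 1], pc2 = pc[, 2],
                       density = NA_real_, hdr_level = NA_real_,
                       outlier = FALSE, stringsAsFactors = FALSE)
  if (is.null(dens)) {
    warnf("degenerate density (zero variance on a component); no outliers flagged")
    report$hdr_level <- levels[1]
  } else {
    report$density <- dens
    thresholds <- stats::quantile(dens, 1 - levels / 100, type = 7)
    lvl <- rep(Inf, n)
    for (k in rev(seq_along(levels))) lvl[dens >= thresholds[k]] <- levels[k]
    report$hdr_level <- lvl
    report$outlier <- dens < thresholds[length(levels)]
  }
  structure(list(samples = report,
                 retained = report$sample_id[!report$outlier],
                 discarded = report$sample_id[report$outlier],
                 n_retained = sum(!report$outlier),
                 n_discarded = sum(report$outlier)),
            class = "outlier_report")
}

#' @exportS3Method base::print
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d retained, %d discarded (>97%% HDR)\n",
              x$n_retained, x$n_discarded))
  if (x$n_discarded)
    cat("  discarded:", paste(x$discarded, collapse = ", "), "\n")
  invisible(x)
}
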