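#' Per-protein age-association statistics
#'
#' Spearman correlation of studentized TMT ratios with donor age, ordinary
#' least-squares per-year slopes on mean-normalized ratios, the slope to
#' percent-per-lifespan conversion, and the male-only sensitivity check for
#' the cohort's sex imbalance.
#'
#' @name ageing_stats
NULL

#' Spearman age correlation per protein
#'
#' For each protein whose donor coverage (fraction of the population's
#' donors with a non-missing value) exceeds `min_coverage`, the Spearman
#' rank correlation between its ratios and donor ages, with a two-sided p
#' value from the t approximation (ties receive average ranks). Proteins
#' with fewer than three paired observations are skipped.
#'
#' @param x a [ratio_matrix] (typically studentized) for one population, or
#'   a plain protein-by-sample matrix.
#' @param samples sample metadata with `sample_id`, `donor_id`, `age` for
#'   the matrix columns.
#' @param min_coverage strict lower bound on donor coverage (default 0.15).
#' @param p_threshold significance level for the `significant` flag.
#' @param population optional population label copied into the result.
#' @return data.frame with `protein`, `population`, `n`, `coverage`, `rho`,
#'   `p`, `slope` is *not* included here (see [age_slopes()]), `significant`.
#' @export
age_correlation <- function(x, samples, min_coverage = 0.15,
                            p_threshold = 0.05, population = NA_character_) {
  v <- if (inherits(x, "ratio_matrix")) x$values else as.matrix(x)
  idx <- match(colnames(v), samples$sample_id)
  if (anyNA(idx)) stopf("matrix columns missing from sample metadata")
  ages <- samples$age[idx]
  if (anyNA(ages)) stopf("every sample needs an age")
  n_donors <- length(unique(samples$donor_id[idx]))
  rows <- lapply(rownames(v), function(p) {
    vals <- v[p, ]
    ok <- is.finite(vals)
    coverage <- length(unique(samples$donor_id[idx][ok])) / n_donors
    if (coverage <= min_coverage) return(NULL)
    if (sum(ok) < 3L) return(NULL)
    st <- spearman_t(vals[ok], ages[ok])
    data.frame(protein = p, population = population, n = st$n,
               coverage = coverage, rho = st$rho, p = st$p,
               significant = is.finite(st$p) && st$p < p_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(), population = character(),
                      n = integer(), coverage = numeric(), rho = numeric(),
                      p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-year abundance slopes
#'
#' Ordinary least-squares slope of each protein's mean-normalized ratio on
#' donor age. On a mean-normalized matrix (baseline 1) the slope reads as
#' relative abundance change per year.
#'
#' @param x a [ratio_matrix] in state `"mean_normalized"` (enforced when a
#'   `ratio_matrix` is supplied), or a plain matrix.
#' @param samples sample metadata with ages.
#' @return data.frame with `protein`, `slope`, `n`.
#' @export
age_slopes <- function(x, samples) {
  if (inherits(x, "ratio_matrix")) {
    if (x$state != "mean_normalized")
      stopf("age_slopes() expects a mean-normalized matrix")
    v <- x$values
  } else v <- as.matrix(x)
  idx <- match(colnames(v), samples$sample_id)
  if (anyNA(idx)) stopf("matrix columns missing from sample metadata")
  ages <- samples$age[idx]
  if (stats::var(ages) == 0) stopf("zero age variance across samples")
  slope <- apply(v, 1L, function(vals) {
    ok <- is.finite(vals)
    if (sum(ok) < 2L || stats::var(ages[ok]) == 0) return(NA_real_)
    ols_slope(ages[ok], vals[ok])
  })
  data.frame(protein = rownames(v), slope = as.numeric(slope),
             n = as.integer(rowSums(is.finite(v))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert a per-year slope to percent change over a life span
#'
#' With a mean-normalized baseline of 1, a slope `b` per year corresponds to
#' `100 * b * span` percent change over `span` years; a slope of 0.001 over
#' the 40-year span from age 20 to 60 is a 4 percent increase.
#'
#' @param slope relative abundance change per year (vectorized).
#' @param span life span in years (default 40).
#' @return percent change over the span.
#' @examples
#' slope_to_percent(0.001, 40)   # 4
#' @export
slope_to_percent <- function(slope, span = 40) {
  if (any(span <= 0)) stopf("span must be positive")
  100 * slope * span
}

#' Sensitivity of age correlations to the cohort's sex imbalance
#'
#' Recomputes the per-protein Spearman rho after removing all female
#' samples and reports the Pearson correlation between the all-sample and
#' male-only rho vectors over shared proteins. With no female samples the
#' two analyses coincide and the result is flagged degenerate.
#'
#' @param x a [ratio_matrix] or matrix for one population.
#' @param samples sample metadata with `sex` (`"M"`/`"F"`).
#' @param min_coverage coverage rule applied to both analyses.
#' @return list with `r`, `n_shared`, `assoc_all`, `assoc_male`,
#'   `degenerate`.
#' @export
sex_sensitivity <- function(x, samples, min_coverage = 0.15) {
  v <- if (inherits(x, "ratio_matrix")) x$values else as.matrix(x)
  idx <- match(colnames(v), samples$sample_id)
  smp <- samples[idx, , drop = FALSE]
  assoc_all <- age_correlation(v, smp, min_coverage = min_coverage)
  male_cols <- colnames(v)[smp$sex == "M"]
  degenerate <- length(male_cols) == ncol(v)
  if (degenerate) {
    warnf("no female samples; male-only analysis identical by construction")
    return(list(r = 1, n_shared = nrow(assoc_all), assoc_all = assoc_all,
                assoc_male = assoc_all, degenerate = TRUE))
  }
  assoc_male <- age_correlation(v[, male_cols, drop = FALSE],
                                smp[smp$sex == "M", , drop = FALSE],
                                min_coverage = min_coverage)
  shared <- intersect(assoc_all$protein, assoc_male$protein)
  if (length(shared) < 3L) stopf("fewer than three shared proteins")
  r <- stats::cor(assoc_all$rho[match(shared, assoc_all$protein)],
                  assoc_male$rho[match(shared, assoc_male$protein)])
  list(r = r, n_shared = length(shared), assoc_all = assoc_all,
       assoc_male = assoc_male, degenerate = FALSE)
}
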