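# Internal helpers shared across modules. Nothing here is exported.

TMT_CHANNELS <- c(126L, 127L, 128L, 129L, 130L, 131L)
DONOR_CHANNELS <- TMT_CHANNELS[-1L]
REPORTER_COLS <- paste0("reporter_", TMT_CHANNELS)
DONOR_REPORTER_COLS <- paste0("reporter_", DONOR_CHANNELS)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Spearman rank correlation with two-sided p from the t approximation.
# Ties get average ranks. Deterministic for the cohort sizes used here
# (n ~ 40-59), where the t approximation is adequate.
spearman_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# OLS slope of y on x over finite pairs; returns NA with fewer than 2 points.
ols_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  vx <- stats::var(x)
  if (vx == 0) stopf("zero variance in the regressor; slope undefined")
  stats::cov(x, y) / vx
}

# Cohen's d with pooled standard deviation; NA (flagged upstream) when the
# pooled sd is zero.
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Canonical leaf order for an hclust object: at every merge the subtree whose
# lexicographically smallest label is smaller comes first. Makes dendrograms
# independent of input column order.
canonical_hclust <- function(hc) {
  n <- length(hc$labels)
  m <- hc$merge
  order_of <- vector("list", nrow(m))
  min_label <- character(nrow(m))
  leaf <- function(i) hc$labels[-i]
  for (k in seq_len(nrow(m))) {
    parts <- lapply(m[k, ], function(i) {
      if (i < 0) list(ord = -i, lab = leaf(i)) else list(ord = order_of[[i]], lab = min_label[i])
    })
    if (parts[[2]]$lab < parts[[1]]$lab) parts <- parts[c(2, 1)]
    order_of[[k]] <- c(parts[[1]]$ord, parts[[2]]$ord)
    min_label[k] <- parts[[1]]$lab
  }
  hc$order <- order_of[[nrow(m)]]
  hc
}

# Deterministic complete-linkage clustering on columns of `x`.
# dist_method: "correlation" (1 - Pearson r) or "euclidean".
complete_linkage <- function(x, dist_method = c("correlation", "euclidean")) {
  dist_method <- match.arg(dist_method)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  if (dist_method == "correlation") {
    sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
    bad <- !is.finite(sds) | sds == 0
    if (any(bad)) {
      warnf("excluding %d constant column(s) with undefined correlation: %s",
            sum(bad), paste(colnames(x)[bad], collapse = ", "))
      x <- x[, !bad, drop = FALSE]
    }
    if (ncol(x) < 1L) stopf("no usable columns left for clustering")
    if (ncol(x) == 1L) {
      return(list(hclust = NULL, order = 1L, labels = colnames(x)))
    }
    d <- stats::as.dist(1 - stats::cor(x, use = "pairwise.complete.obs"))
  } else {
    if (ncol(x) == 1L) {
      return(list(hclust = NULL, order = 1L, labels = colnames(x)))
    }
    d <- stats::dist(t(x), method = "euclidean")
  }
  hc <- canonical_hclust(stats::hclust(d, method = "complete"))
  list(hclust = hc, order = hc$order, labels = colnames(x))
}

# Derive a child seed from a base seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

assert_in_unit <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", name)
}
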