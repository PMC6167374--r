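#' Readers and writers for the pipeline's table formats
#'
#' PSM tables and ratio/LF matrices travel as TSV (with a commented header
#' recording provenance), sample metadata as CSV, sequences as FASTA,
#' single-cell counts as matrix-market sparse triplets with row/column name
#' sidecars, and ground truth / run manifests as JSON.
#'
#' @name io
NULL

#' @rdname io
#' @param psms PSM data.frame.
#' @param file output path.
#' @export
write_psm_table <- function(psms, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# PSM table: one row per peptide-spectrum match; ",
                    "reporter_126 is the internal standard"), con)
  utils::write.table(psms, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_psm_table <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname io
#' @param samples sample metadata data.frame.
#' @export
write_sample_meta <- function(samples, file) {
  utils::write.csv(samples, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_sample_meta <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param x matrix-like object with a `values` element, or a matrix.
#' @export
write_matrix_tsv <- function(x, file) {
  v <- if (is.list(x) && !is.null(x$values)) x$values else as.matrix(x)
  state <- if (is.list(x) && !is.null(x$state)) x$state else "raw"
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", state), con)
  utils::write.table(data.frame(protein = rownames(v), v, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param sequences named character vector or `AAStringSet`.
#' @export
write_fasta <- function(sequences, file) {
  if (!inherits(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, file)
  invisible(file)
}

#' @rdname io
#' @export
read_fasta <- function(file) {
  Biostrings::readAAStringSet(file)
}

#' @rdname io
#' @param counts gene-by-cell matrix.
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.genes.txt`,
#'   `<prefix>.cells.txt`.
#' @export
write_counts_mm <- function(counts, prefix) {
  sp <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".genes.txt"))
  writeLines(colnames(counts), paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' @rdname io
#' @export
read_counts_mm <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".cells.txt"))
  storage.mode(m) <- "integer"
  m
}

#' @rdname io
#' @param truth `ground_truth` list.
#' @export
write_ground_truth <- function(truth, file) {
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname io
#' @param pairs data.frame with `ligand`, `receptor`.
#' @export
write_lr_pairs <- function(pairs, file) {
  utils::write.table(pairs[, c("ligand", "receptor")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_lr_pairs <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
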