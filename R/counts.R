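#' Assemble a counts matrix with its experimental design
#'
#' Bundles a gene-by-sample matrix of raw read counts with per-gene lengths,
#' the sample sheet describing the design (species, tissue, time point,
#' replicate) and per-sample totals of mapped reads. All downstream
#' normalization and testing starts from this container.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param gene_lengths numeric vector of gene lengths in bp, named by gene id
#'   (or in row order of `counts`).
#' @param samples data.frame with columns `sample_id`, `species`, `tissue`,
#'   `timepoint`, `replicate`; one row per column of `counts`.
#' @param totals optional per-sample totals of mapped reads; defaults to the
#'   column sums of `counts`.
#' @return An object of class `counts_matrix`.
#' @export
counts_matrix <- function(counts, gene_lengths, samples, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(gene_lengths))) names(gene_lengths) <- rownames(counts)
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths)) stop("gene_lengths missing for some genes")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  samples <- as.data.frame(samples)
  needed <- c("sample_id", "species", "tissue", "replicate")
  if (!all(needed %in% names(samples)))
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "))
  if (!"timepoint" %in% names(samples)) samples$timepoint <- NA
  if (!setequal(samples$sample_id, colnames(counts)))
    stop("sample sheet and counts columns disagree")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(totals)) totals <- colSums(counts)
  if (is.null(names(totals))) names(totals) <- colnames(counts)
  totals <- totals[colnames(counts)]
  structure(
    list(counts = counts, gene_lengths = gene_lengths,
         samples = samples, totals = totals),
    class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat("counts_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' Read a counts TSV and sample sheet from disk
#'
#' Counts TSV: first column `gene_id`, remaining columns one per sample,
#' integer cells. Sample sheet TSV: columns `sample_id`, `species`, `tissue`,
#' `timepoint`, `replicate`. Gene lengths come either from a `length` column
#' in `lengths_file` (`gene_id`, `length`) or from an annotation table.
#'
#' @param counts_file,samples_file,lengths_file paths to TSV files.
#' @return A [counts_matrix()].
#' @export
read_counts <- function(counts_file, samples_file, lengths_file) {
  ct <- utils::read.delim(counts_file, check.names = FALSE)
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- ct[[1]]
  storage.mode(m) <- "double"
  samples <- utils::read.delim(samples_file)
  len <- utils::read.delim(lengths_file)
  lv <- stats::setNames(len$length, len$gene_id)
  counts_matrix(m, lv, samples)
}

#' Write the pieces of a counts_matrix to TSV files
#'
#' @param x a [counts_matrix()].
#' @param counts_file,samples_file,lengths_file output paths.
#' @export
write_counts <- function(x, counts_file, samples_file, lengths_file) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write_tsv(df, counts_file)
  write_tsv(x$samples, samples_file)
  write_tsv(data.frame(gene_id = names(x$gene_lengths),
                       length = unname(x$gene_lengths)), lengths_file)
  invisible(x)
}

# TSV conventions used for every output table: header row, tab-separated,
# no quoting, no row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
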