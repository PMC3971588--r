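#' RPKM normalization
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `count * 1e9 / (length_bp * total_mapped)`.
#'
#' @param x a [counts_matrix()].
#' @return A `normalized_matrix`: list with `values` (same shape as the
#'   counts), `method` (`"RPKM"`), per-sample `scale_factors` (total mapped
#'   reads), plus the gene lengths and sample sheet carried through.
#' @export
rpkm <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  if (any(x$totals <= 0)) stop("zero total mapped reads in: ",
                               paste(names(x$totals)[x$totals <= 0], collapse = ", "))
  if (any(x$gene_lengths <= 0)) stop("zero gene length")
  values <- x$counts * 1e9 /
    (matrix(x$gene_lengths, nrow(x$counts), ncol(x$counts)) *
       matrix(x$totals, nrow(x$counts), ncol(x$counts), byrow = TRUE))
  structure(list(values = values, method = "RPKM",
                 scale_factors = x$totals,
                 gene_lengths = x$gene_lengths, samples = x$samples),
            class = "normalized_matrix")
}

#' Upper-quartile normalization
#'
#' Each sample is scaled by the 75th percentile of its nonzero gene counts;
#' the geometric mean of the per-sample factors is multiplied back in so the
#' normalized values stay on a count-like scale that is stable under taking
#' sample subsets.
#'
#' @param x a [counts_matrix()].
#' @return A `normalized_matrix` with `method = "UQ"` and the per-sample
#'   upper-quartile `scale_factors` recorded.
#' @export
upper_quartile <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  f <- apply(x$counts, 2, function(col) {
    nz <- col[col > 0]
    if (!length(nz)) NA_real_ else stats::quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(f)) stop("all-zero sample(s): ",
                     paste(colnames(x$counts)[is.na(f)], collapse = ", "))
  gm <- exp(mean(log(f)))
  values <- sweep(x$counts, 2, f, "/") * gm
  structure(list(values = values, method = "UQ", scale_factors = f,
                 gene_lengths = x$gene_lengths, samples = x$samples),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (", x$method, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Normalize counts by method name
#'
#' @param x a [counts_matrix()].
#' @param method `"RPKM"` or `"UQ"`.
#' @return A `normalized_matrix`.
#' @export
normalize_counts <- function(x, method = c("RPKM", "UQ")) {
  method <- match.arg(toupper(method), c("RPKM", "UQ"))
  if (method == "RPKM") rpkm(x) else upper_quartile(x)
}
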