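#' Call strictly duplicated paralog pairs from synteny anchors
#'
#' A strictly duplicated pair is a focal-genome (Gr) gene pair that (i) forms
#' an anchor of a Gr-Gr collinear block spanning two duplicated regions,
#' (ii) whose two members map to the same single Tc block region, and
#' (iii) to the same single Vv block region. Genes occurring in more than two
#' Gr copies (more than one Gr-Gr anchor pair), or whose outgroup ortholog
#' occurs in more than one syntenic region, are excluded. Anchors within a
#' single Gr block (tandem duplicates) are not pairs.
#'
#' @param gr_gr,gr_tc,gr_vv anchor tables: data.frames with columns `geneA`,
#'   `genomeA`, `blockA`, `geneB`, `genomeB`, `blockB`.
#' @param annotation data.frame of focal-genome gene models with columns
#'   `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @return data.frame of pairs with columns `pair_id`, `gene1`, `gene2`
#'   (canonically `gene1 < gene2`), coordinates of both members,
#'   `tc_region_id` and `vv_region_id`; ordered by `gene1`.
#' @export
call_strict_duplicates <- function(gr_gr, gr_tc, gr_vv, annotation) {
  gg <- orient_anchors(gr_gr, "Gr", "Gr")
  gt <- orient_anchors(gr_tc, "Gr", "Tc")
  gv <- orient_anchors(gr_vv, "Gr", "Vv")

  gr_genes <- unique(c(gg$geneA, gg$geneB, gt$geneA, gv$geneA))
  missing <- setdiff(gr_genes, annotation$gene_id)
  if (length(missing))
    stop("anchor genes absent from annotation: ",
         paste(sort(missing), collapse = ", "))

  gg <- gg[gg$blockA != gg$blockB, , drop = FALSE]  # drop tandem anchors
  if (nrow(gg) == 0) return(empty_pairs())
  g1 <- pmin(gg$geneA, gg$geneB)
  g2 <- pmax(gg$geneA, gg$geneB)
  cand <- unique(data.frame(gene1 = g1, gene2 = g2, stringsAsFactors = FALSE))
  cand <- cand[cand$gene1 != cand$gene2, , drop = FALSE]

  # strictly duplicated = the gene participates in exactly one Gr-Gr pair
  copies <- table(c(cand$gene1, cand$gene2))
  ok <- copies[cand$gene1] == 1 & copies[cand$gene2] == 1
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_pairs())

  region_of <- function(anchors) {
    # per Gr gene: the set of distinct outgroup blocks it maps to
    split(anchors$blockB, anchors$geneA)
  }
  single_region <- function(map, gene) {
    blocks <- unique(map[[gene]])
    if (length(blocks) == 1) blocks else NA_character_
  }
  tc_map <- region_of(gt); vv_map <- region_of(gv)
  tc1 <- vapply(cand$gene1, single_region, "", map = tc_map)
  tc2 <- vapply(cand$gene2, single_region, "", map = tc_map)
  vv1 <- vapply(cand$gene1, single_region, "", map = vv_map)
  vv2 <- vapply(cand$gene2, single_region, "", map = vv_map)
  keep <- !is.na(tc1) & !is.na(tc2) & tc1 == tc2 &
    !is.na(vv1) & !is.na(vv2) & vv1 == vv2
  cand$tc_region_id <- tc1
  cand$vv_region_id <- vv1
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_pairs())

  cand <- cand[order(cand$gene1, cand$gene2), , drop = FALSE]
  ann <- annotation[match(cand$gene1, annotation$gene_id), ]
  ann2 <- annotation[match(cand$gene2, annotation$gene_id), ]
  out <- data.frame(
    pair_id = sprintf("pair%05d", seq_len(nrow(cand))),
    gene1 = cand$gene1, gene2 = cand$gene2,
    chrom1 = ann$chrom, start1 = ann$start, end1 = ann$end,
    chrom2 = ann2$chrom, start2 = ann2$start, end2 = ann2$end,
    tc_region_id = cand$tc_region_id, vv_region_id = cand$vv_region_id,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# normalize an anchor table so genomeA is the focal genome
orient_anchors <- function(tab, focal, other) {
  tab <- as.data.frame(tab)
  needed <- c("geneA", "genomeA", "blockA", "geneB", "genomeB", "blockB")
  if (!all(needed %in% names(tab)))
    stop("anchor table needs columns: ", paste(needed, collapse = ", "))
  flip <- tab$genomeA != focal
  if (any(flip)) {
    tmp <- tab[flip, ]
    tab[flip, c("geneA", "genomeA", "blockA")] <- tmp[, c("geneB", "genomeB", "blockB")]
    tab[flip, c("geneB", "genomeB", "blockB")] <- tmp[, c("geneA", "genomeA", "blockA")]
  }
  if (!all(tab$genomeA == focal & tab$genomeB == other))
    stop("anchor table is not a ", focal, "-", other, " comparison")
  tab
}

empty_pairs <- function() {
  data.frame(pair_id = character(), gene1 = character(), gene2 = character(),
             chrom1 = character(), start1 = integer(), end1 = integer(),
             chrom2 = character(), start2 = integer(), end2 = integer(),
             tc_region_id = character(), vv_region_id = character(),
             stringsAsFactors = FALSE)
}

#' Write a Circos-style links file for paralog pairs
#'
#' One line per pair: `chrom1 start1 end1 chrom2 start2 end2 pair_id`,
#' tab-separated with a header, coordinates 1-based inclusive as stored.
#'
#' @param pairs pair table from [call_strict_duplicates()].
#' @param path output path.
#' @export
write_links_file <- function(pairs, path) {
  write_tsv(pairs[, c("chrom1", "start1", "end1",
                      "chrom2", "start2", "end2", "pair_id")], path)
}

#' Read a links file back into a data.frame
#'
#' @param path path written by [write_links_file()].
#' @return data.frame with the seven links columns.
#' @export
read_links_file <- function(path) read_tsv(path)

#' Read gene models from GFF3 or BED
#'
#' GFF3 coordinates are 1-based inclusive; BED intervals (0-based half-open)
#' are converted to 1-based inclusive on import. Requires the rtracklayer
#' package.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file.
#' @param feature_type for GFF3, the feature type to keep (default `"gene"`).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3/BED requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == feature_type))
    df <- df[df$type == feature_type, , drop = FALSE]
  id <- if ("ID" %in% names(df)) df$ID else if ("name" %in% names(df))
    df$name else df$Name
  if (is.null(id)) stop("no gene identifier (ID/name) found in ", path)
  data.frame(gene_id = as.character(id), chrom = as.character(df$seqnames),
             start = df$start, end = df$end, stringsAsFactors = FALSE)
}

#' Read a paralog pair table from TSV
#'
#' Accepts either the full table written by the strict-duplicate caller or a
#' minimal `gene1`/`gene2` listing (a `pair_id` is generated if absent).
#'
#' @param path TSV path.
#' @return data.frame with at least `pair_id`, `gene1`, `gene2`.
#' @export
read_pairs <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("gene1", "gene2") %in% names(tab)))
    stop("pair table needs gene1 and gene2 columns")
  if (!"pair_id" %in% names(tab))
    tab$pair_id <- sprintf("pair%05d", seq_len(nrow(tab)))
  tab
}
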