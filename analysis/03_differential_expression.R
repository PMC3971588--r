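#!/usr/bin/env Rscript
# Per-pair, per-tissue differential expression: RPKM (and UQ) normalization,
# one-sample t-tests of within-replicate log2 expression ratios, BH
# correction per tissue, fold-change stratification, tissue overlaps and
# tissue-specific reciprocal silencing.

suppressPackageStartupMessages(library(paleodup))
counts <- read_counts("results/data/counts.tsv", "results/data/samples.tsv",
                      "results/data/lengths.tsv")
pairs <- read_pairs("results/data/pairs.tsv")

norm <- rpkm(counts)
de <- paralog_de(norm, pairs, pseudocount = 0.5, min_expr = 1, fdr = 0.05)
write.table(de, "results/pair_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ov <- overlap_summary(de)
cat("pairs analysed:", ov$n_pairs, "\n")
for (ti in names(ov$per_tissue))
  cat(sprintf("  DE in %-6s %5d (%.1f%%)\n", ti, ov$per_tissue[[ti]],
              100 * ov$per_tissue[[ti]] / ov$n_pairs))
cat(sprintf("  DE in all tissues: %d   in any tissue: %d (%.1f%%)\n",
            ov$all_tissues, ov$any_tissue, 100 * ov$any_tissue / ov$n_pairs))

ft <- fold_change_table(de, thresholds = c(1.5, 2, 5))
print(ft)
write.table(ft, "results/fold_change_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ov$pairwise, "results/overlap_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sil <- detect_reciprocal_silencing(norm, pairs, de, threshold = 0.95)
cat("reciprocal silencing calls at the 95% rule:", nrow(sil), "\n")
if (nrow(sil)) print(table(paste(sil$condition_a, "vs", sil$condition_b)))
write.table(sil, "results/silencing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# sanity: UQ normalization calls nearly the same DE set
de_uq <- paralog_de(upper_quartile(counts), pairs)
for (ti in unique(de$tissue)) {
  a <- de$pair_id[de$tissue == ti & !is.na(de$q) & de$q <= 0.05]
  b <- de_uq$pair_id[de_uq$tissue == ti & !is.na(de_uq$q) & de_uq$q <= 0.05]
  cat(sprintf("  RPKM/UQ DE overlap in %-6s %.3f\n", ti,
              length(intersect(a, b)) / length(union(a, b))))
}
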