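#!/usr/bin/env Rscript
# Generate the synthetic study data set: NB read counts for paralog pairs
# in three tissues (3 replicates each) with a planted mixture of divergence
# scenarios, plus the matching pair list and aligned CDS pairs for dN/dS.
# All later analysis steps consume the files written here.

suppressPackageStartupMessages(library(paleodup))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

design <- simulation_design(n_pairs = 1971, seed = 20140301)
sim <- simulate_counts(design)

write_counts(sim$counts, "results/data/counts.tsv",
             "results/data/samples.tsv", "results/data/lengths.tsv")
write_tsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE)
write_tsv(sim$truth, "results/data/truth.tsv")

pairs <- truth_pairs(sim$truth)
# synthetic genomic coordinates: the two duplicated regions of a pair live
# on different chromosome sets, and which member sits in which set is
# randomized per pair (as after a WGD, member role carries no positional
# information) so the positional-bias stage sees an unbiased layout
n <- nrow(pairs)
set.seed(design$seed + 1L)
chromA <- paste0("Chr", sprintf("%02d", rep(1:6, length.out = n)))
startA <- ave(seq_len(n), chromA, FUN = seq_along) * 1500
chromB <- paste0("Chr", sprintf("%02d", 6 + rep(1:6, length.out = n)))
flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
pairs$chrom1 <- ifelse(flip, chromB, chromA)
pairs$chrom2 <- ifelse(flip, chromA, chromB)
pairs$start1 <- pairs$start2 <- startA
pairs$end1 <- pairs$end2 <- startA + 1000
write_tsv(pairs, "results/data/pairs.tsv")

# aligned CDS pairs with planted synonymous/nonsynonymous substitutions;
# substitution loads vary across pairs so omega spans a range
set.seed(design$seed)
aln <- lapply(setNames(pairs$pair_id, pairs$pair_id), function(id)
  unname(simulate_codon_pair(n_codons = 200,
                             syn_subs = sample(0:12, 1),
                             nonsyn_subs = sample(0:8, 1),
                             seed = sample(.Machine$integer.max - 1, 1))))
write_codon_alignments(aln, "results/data/alignments.fasta")

cat("simulated", n, "paralog pairs x", ncol(sim$counts$counts), "samples\n")
cat("scenario mix:\n")
print(table(sim$truth$scenario))
cat("files under results/data/\n")
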