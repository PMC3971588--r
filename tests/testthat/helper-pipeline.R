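# Builds a complete on-disk input set (counts, sample sheet, lengths, pair
# table with coordinates, aligned CDS pairs) from the synthetic generators.
write_pipeline_inputs <- function(dir, n_pairs = 40, seed = 51,
                                  with_alignments = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- simulation_design(n_pairs = n_pairs, seed = seed)
  sim <- simulate_counts(d)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                lengths = file.path(dir, "lengths.tsv"),
                pairs = file.path(dir, "pairs.tsv"),
                alignments = if (with_alignments)
                  file.path(dir, "alignments.fasta") else NULL)
  write_counts(sim$counts, paths$counts, paths$samples, paths$lengths)
  pairs <- truth_pairs(sim$truth)
  # arbitrary fixed coordinates so the positional stage runs
  n <- nrow(pairs)
  pairs$chrom1 <- paste0("chr", rep(1:2, length.out = n))
  pairs$start1 <- seq_len(n) * 1500
  pairs$end1 <- pairs$start1 + 1000
  pairs$chrom2 <- paste0("chr", 2 + rep(1:2, length.out = n))
  pairs$start2 <- pairs$start1; pairs$end2 <- pairs$end1
  utils::write.table(pairs, paths$pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (with_alignments) {
    aln <- lapply(stats::setNames(pairs$pair_id, pairs$pair_id), function(id)
      unname(simulate_codon_pair(60, sample(0:3, 1), sample(0:3, 1),
                                 seed = sum(utf8ToInt(id)))))
    write_codon_alignments(aln, paths$alignments)
  }
  paths
}

run_once <- function(paths, outdir, seed = 1) {
  cfg <- pipeline_config(counts_file = paths$counts,
                         samples_file = paths$samples,
                         lengths_file = paths$lengths,
                         pairs_file = paths$pairs,
                         alignments_file = paths$alignments,
                         outdir = outdir, seed = seed)
  suppressMessages(run_pipeline(cfg))
}
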