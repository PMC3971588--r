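#' Describe a paralog-pair count simulation
#'
#' A simulation design fixes the experimental layout (tissues, replicates),
#' the mixture of divergence scenarios planted across pairs, the planted
#' effect magnitudes, and the sampling model (negative binomial with
#' mean/dispersion parameterization, variance = mu + phi * mu^2).
#'
#' Scenarios:
#' \describe{
#'   \item{null}{both paralogs share the same mean everywhere.}
#'   \item{G_only}{gene 1 exceeds gene 2 by `effect_log2fc` in every tissue.}
#'   \item{GxT}{opposite biases of `interaction_log2fc` in the first two
#'     tissues, no bias elsewhere; the average gene effect is zero.}
#'   \item{G_T_GxT}{gene effect plus tissue main effects plus an interaction
#'     pattern, so all three GLM effects are present.}
#'   \item{reciprocal_silencing}{gene 1 carries 99% of the pair total in the
#'     first tissue and 1% in the second (mirrored), beyond the 95% rule.}
#'   \item{complementary}{gene 1 carries 80% of the pair total in the first
#'     tissue and 20% in the second: reversed dominance without silencing.}
#' }
#'
#' @param n_pairs number of paralog pairs.
#' @param tissues ordered character vector of tissue labels.
#' @param n_reps biological replicates per tissue (>= 2).
#' @param scenario_mix named proportions over the six scenarios; must sum to 1.
#' @param effect_log2fc planted gene-effect magnitude (log2 fold change).
#' @param interaction_log2fc planted interaction magnitude (log2).
#' @param dispersion NB dispersion phi (> 0); phi = 0 gives Poisson counts.
#' @param lib_size_range range of per-sample total counts (a scaled-down
#'   stand-in for 20-40 M mapped reads).
#' @param length_range range of gene lengths in bp; both members of a pair
#'   share one length so length never mimics expression divergence.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-pair baseline expression rate (RPKM-like units).
#' @param seed RNG seed; identical seeds reproduce identical output.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_pairs = 200,
                              tissues = c("petal", "leaf", "seed"),
                              n_reps = 3,
                              scenario_mix = c(null = 0.25, G_only = 0.20,
                                               GxT = 0.15, G_T_GxT = 0.20,
                                               reciprocal_silencing = 0.10,
                                               complementary = 0.10),
                              effect_log2fc = 2,
                              interaction_log2fc = 2,
                              dispersion = 0.05,
                              lib_size_range = c(2e5, 4e5),
                              length_range = c(300, 3000),
                              baseline_meanlog = log(100),
                              baseline_sdlog = 1,
                              seed = 1) {
  known <- c("null", "G_only", "GxT", "G_T_GxT",
             "reciprocal_silencing", "complementary")
  if (is.null(names(scenario_mix)) || !all(names(scenario_mix) %in% known))
    stop("scenario_mix must be named with scenarios among: ",
         paste(known, collapse = ", "))
  if (abs(sum(scenario_mix) - 1) > 1e-8)
    stop("scenario_mix must sum to 1 (got ", sum(scenario_mix), ")")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (length(tissues) < 2) stop("need at least 2 tissues")
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(all(lib_size_range > 0), all(length_range > 0),
            diff(lib_size_range) >= 0, diff(length_range) >= 0)
  structure(list(
    n_pairs = n_pairs, tissues = tissues, n_reps = n_reps,
    scenario_mix = scenario_mix, effect_log2fc = effect_log2fc,
    interaction_log2fc = interaction_log2fc, dispersion = dispersion,
    lib_size_range = lib_size_range, length_range = length_range,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    seed = seed), class = "simulation_design")
}

# planted per-tissue log2(gene1/gene2) and log2 tissue shifts for a scenario;
# the tissue-shift pattern is permuted at random per pair: were every pair
# given the same pattern, the planted tissue effect would shift the whole
# transcriptome and be absorbed by (correctly functioning) normalization
scenario_effects <- function(scenario, tissues, effect, interaction) {
  nt <- length(tissues)
  delta <- rep(0, nt)   # log2 gene1/gene2 per tissue
  tau <- rep(0, nt)     # log2 shift of the pair total per tissue
  if (scenario == "G_only") {
    delta[] <- effect
  } else if (scenario == "GxT") {
    delta[1] <- interaction; delta[2] <- -interaction
  } else if (scenario == "G_T_GxT") {
    delta[] <- effect
    delta[1] <- delta[1] + interaction
    delta[2] <- delta[2] - interaction
    tau <- effect * sample(seq(-1, 1, length.out = nt))
  } else if (scenario == "reciprocal_silencing") {
    delta[1] <- log2(0.99 / 0.01); delta[2] <- -log2(0.99 / 0.01)
  } else if (scenario == "complementary") {
    delta[1] <- log2(0.80 / 0.20); delta[2] <- -log2(0.80 / 0.20)
  }
  list(delta = delta, tau = tau)
}

scenario_category <- function(scenario) {
  switch(scenario,
         null = "none",
         G_only = "G",
         GxT = "GxT",
         G_T_GxT = "G+T+GxT",
         reciprocal_silencing = "GxT",
         complementary = "GxT")
}

#' Simulate NB-distributed paralog-pair counts with planted truth
#'
#' Draws a gene-by-sample matrix of negative binomial counts for `n_pairs`
#' paralog pairs across tissues and replicates. The NB mean for gene g in
#' sample s is `baseline * 2^(planted effects) * (length_bp/1e3) *
#' (lib_size/1e6)`, i.e. library size and gene length enter as a
#' multiplicative exposure, mirroring the offset treatment in the GLM stage.
#' Within a pair the two genes split a common pair-total so planted log2
#' gene ratios are exact.
#'
#' @param design a [simulation_design()].
#' @return list with elements `counts` (a [counts_matrix()]) and `truth`
#'   (data.frame: `pair_id`, `gene1`, `gene2`, `scenario`, `true_category`,
#'   `true_silenced_tissues`, `true_complementary_tissues`, and one
#'   `log2fc_<tissue>` column per tissue holding the planted log2
#'   gene1/gene2 ratio).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  nt <- length(design$tissues)
  P <- design$n_pairs
  scen <- sample(names(design$scenario_mix), P, replace = TRUE,
                 prob = design$scenario_mix)
  gene1 <- sprintf("pair%05d_g1", seq_len(P))
  gene2 <- sprintf("pair%05d_g2", seq_len(P))
  pair_id <- sprintf("pair%05d", seq_len(P))

  samples <- data.frame(
    sample_id = paste0(rep(design$tissues, each = design$n_reps), "_r",
                       rep(seq_len(design$n_reps), nt)),
    species = "Gr",
    tissue = rep(design$tissues, each = design$n_reps),
    timepoint = NA_integer_,
    replicate = rep(seq_len(design$n_reps), nt))
  ns <- nrow(samples)
  lib <- round(stats::runif(ns, design$lib_size_range[1], design$lib_size_range[2]))
  names(lib) <- samples$sample_id

  len <- round(stats::runif(P, design$length_range[1], design$length_range[2]))
  base <- stats::rlnorm(P, design$baseline_meanlog, design$baseline_sdlog)

  eff <- lapply(scen, scenario_effects, tissues = design$tissues,
                effect = design$effect_log2fc,
                interaction = design$interaction_log2fc)
  delta <- do.call(rbind, lapply(eff, `[[`, "delta"))  # P x nt
  tau <- do.call(rbind, lapply(eff, `[[`, "tau"))

  # per-pair, per-tissue means: pair total 2*base*2^tau split by the planted
  # log2 ratio so that log2(mu1/mu2) = delta exactly
  share1 <- 2^delta / (1 + 2^delta)
  total <- 2 * base * 2^tau                      # P x nt (recycles base)
  mu1_rate <- total * share1
  mu2_rate <- total * (1 - share1)

  tiss_of <- match(samples$tissue, design$tissues)
  expo <- (len / 1000) %o% (lib / 1e6)            # P x ns exposure
  mu1 <- mu1_rate[, tiss_of] * expo
  mu2 <- mu2_rate[, tiss_of] * expo

  draw <- function(mu) {
    if (design$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
             nrow = nrow(mu))
    }
  }
  x1 <- draw(mu1); x2 <- draw(mu2)

  counts <- matrix(0, nrow = 2 * P, ncol = ns,
                   dimnames = list(rep(NA, 2 * P), samples$sample_id))
  counts[seq(1, 2 * P, by = 2), ] <- x1
  counts[seq(2, 2 * P, by = 2), ] <- x2
  rownames(counts) <- as.vector(rbind(gene1, gene2))
  lengths <- stats::setNames(rep(len, each = 2), rownames(counts))

  sil <- ifelse(scen == "reciprocal_silencing",
                paste(design$tissues[1], design$tissues[2], sep = "|"), "")
  # every scenario with reversed dominance between the first two tissues is
  # complementary by construction (silencing is its extreme case, and the
  # GxT pattern plants opposite biases)
  comp <- ifelse(scen %in% c("GxT", "complementary", "reciprocal_silencing"),
                 paste(design$tissues[1], design$tissues[2], sep = "|"), "")
  truth <- data.frame(pair_id = pair_id, gene1 = gene1, gene2 = gene2,
                      scenario = scen,
                      true_category = vapply(scen, scenario_category, ""),
                      true_silenced_tissues = sil,
                      true_complementary_tissues = comp)
  lfc <- as.data.frame(delta)
  names(lfc) <- paste0("log2fc_", design$tissues)
  truth <- cbind(truth, lfc)
  rownames(truth) <- NULL

  list(counts = counts_matrix(counts, lengths, samples, totals = colSums(counts)),
       truth = truth)
}

#' Pair list implied by a simulation truth table
#'
#' @param truth the truth table from [simulate_counts()].
#' @return data.frame with columns `pair_id`, `gene1`, `gene2`.
#' @export
truth_pairs <- function(truth) {
  truth[, c("pair_id", "gene1", "gene2")]
}

# fourfold-degenerate codon families with a pyrimidine third base: every
# single-nucleotide change keeps the codon sense (stops need A/G third base),
# third-position transitions are synonymous, second-position changes are not
.codon_pool <- c("GGT", "GGC", "GCT", "GCC", "GTT", "GTC", "CCT", "CCC",
                 "ACT", "ACC", "CGT", "CGC", "TCT", "TCC", "CTT", "CTC")

#' Simulate an aligned codon pair with planted substitution classes
#'
#' Builds a random coding sequence from fourfold-degenerate codon families and
#' introduces exactly `syn_subs` synonymous and `nonsyn_subs` nonsynonymous
#' single-nucleotide changes, each in a distinct codon, so Nei-Gojobori
#' counting recovers the planted classes exactly (every changed codon differs
#' at a single site, leaving a single unambiguous mutational pathway).
#'
#' @param n_codons alignment length in codons; must be >= syn_subs + nonsyn_subs.
#' @param syn_subs,nonsyn_subs planted substitution counts.
#' @param seed RNG seed.
#' @return named character vector of two aligned sequences (`seq1`, `seq2`),
#'   each of 3 * n_codons bases.
#' @export
simulate_codon_pair <- function(n_codons, syn_subs, nonsyn_subs, seed = 1) {
  if (syn_subs + nonsyn_subs > n_codons)
    stop("infeasible: syn_subs + nonsyn_subs (", syn_subs + nonsyn_subs,
         ") exceeds n_codons (", n_codons, "); one substitution per codon")
  if (syn_subs < 0 || nonsyn_subs < 0) stop("substitution counts must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  code <- genetic_code()
  cod1 <- sample(.codon_pool, n_codons, replace = TRUE)
  cod2 <- cod1
  idx <- sample(n_codons, syn_subs + nonsyn_subs)
  syn_idx <- idx[seq_len(syn_subs)]
  non_idx <- idx[seq_len(nonsyn_subs) + syn_subs]
  for (i in syn_idx) {  # third-position pyrimidine swap: always synonymous
    third <- substr(cod1[i], 3, 3)
    substr(cod2[i], 3, 3) <- if (third == "T") "C" else "T"
  }
  for (i in non_idx) {  # second-position change to a sense codon, new amino acid
    cands <- setdiff(c("A", "C", "G", "T"), substr(cod1[i], 2, 2))
    for (b in sample(cands)) {
      cand <- cod1[i]; substr(cand, 2, 2) <- b
      if (code[cand] != "*" && code[cand] != code[cod1[i]]) {
        cod2[i] <- cand; break
      }
    }
  }
  c(seq1 = paste(cod1, collapse = ""), seq2 = paste(cod2, collapse = ""))
}

#' Write aligned sequence pairs to a FASTA file
#'
#' Records are written two per pair, named `<pair_id>_1` and `<pair_id>_2`.
#'
#' @param pairs named list of two-sequence character vectors (names = pair ids).
#' @param path output FASTA path.
#' @export
write_codon_alignments <- function(pairs, path) {
  seqs <- unlist(lapply(names(pairs), function(id) {
    stats::setNames(pairs[[id]], paste0(id, "_", 1:2))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80)
  invisible(path)
}

#' Read aligned sequence pairs from FASTA
#'
#' Records are taken two at a time; the pair id is the shared record-name
#' prefix once a trailing `_1`/`_2` (or `.1`/`.2`) is stripped.
#'
#' @param path FASTA path with an even number of records.
#' @return named list of length-2 character vectors.
#' @export
read_codon_alignments <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) %% 2 != 0) stop("alignment FASTA must hold an even number of records")
  seqs <- as.character(ss)
  out <- list()
  for (k in seq(1, length(seqs), by = 2)) {
    nm <- sub("[._-][12]$", "", names(seqs)[k])
    out[[nm]] <- unname(seqs[k:(k + 1)])
  }
  out
}

#' Simulate a three-genome synteny fixture with planted strict duplicates
#'
#' Emulates the comparative layout used to call strictly duplicated pairs: a
#' focal genome (Gr) in which ancestral regions are duplicated, and two
#' outgroup genomes (Tc, Vv) in which each region is single-copy. A planted
#' fraction of genes per block is "strict" (present in both Gr block copies,
#' single-copy in Tc and Vv). The remaining genes are decoys cycling over:
#' Gr singletons, Gr triplicates (a third Gr copy in a decoy block), genes
#' whose Tc ortholog sits in two Tc regions, and genes whose Vv ortholog sits
#' in two Vv regions.
#'
#' @param n_blocks number of ancestral syntenic regions.
#' @param genes_per_block genes per region.
#' @param fraction_strict fraction of genes per block planted as strict pairs.
#' @param seed RNG seed (controls which gene slots are strict).
#' @return list with gene-order tables (`gr_genes`, `tc_genes`, `vv_genes`),
#'   anchor tables (`gr_gr`, `gr_tc`, `gr_vv`), the Gr `annotation`
#'   (gene_id, chrom, start, end) and the planted `truth_pairs`
#'   (gene1 < gene2).
#' @export
simulate_synteny_fixture <- function(n_blocks = 6, genes_per_block = 20,
                                     fraction_strict = 0.5, seed = 1) {
  if (fraction_strict < 0 || fraction_strict > 1)
    stop("fraction_strict must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  decoy_classes <- c("singleton", "triplicate", "tc_dup", "vv_dup")
  gr <- tc <- vv <- list(); aa <- at <- av <- list()
  truth <- list()
  for (b in seq_len(n_blocks)) {
    n_strict <- round(fraction_strict * genes_per_block)
    status <- rep("decoy", genes_per_block)
    status[sample(genes_per_block, n_strict)] <- "strict"
    dk <- 0
    blkA <- sprintf("Gr_b%02dA", b); blkB <- sprintf("Gr_b%02dB", b)
    blkC <- sprintf("Gr_b%02dC", b)
    tblk <- sprintf("Tc_b%02d", b); tblkX <- sprintf("Tc_b%02dX", b)
    vblk <- sprintf("Vv_b%02d", b); vblkX <- sprintf("Vv_b%02dX", b)
    for (j in seq_len(genes_per_block)) {
      gid <- function(copy) sprintf("Gr%02dg%02d%s", b, j, copy)
      tgene <- sprintf("Tc%02dg%02d", b, j)
      vgene <- sprintf("Vv%02dg%02d", b, j)
      cls <- if (status[j] == "strict") "strict" else {
        dk <- dk + 1
        decoy_classes[(dk - 1) %% length(decoy_classes) + 1]
      }
      copies <- switch(cls,
                       singleton = "a",
                       triplicate = c("a", "b", "c"),
                       c("a", "b"))
      blk_of <- c(a = blkA, b = blkB, c = blkC)
      for (cp in copies)
        gr[[length(gr) + 1]] <- data.frame(gene_id = gid(cp), block = blk_of[[cp]],
                                           slot = j, stringsAsFactors = FALSE)
      tc[[length(tc) + 1]] <- data.frame(gene_id = tgene, block = tblk, slot = j)
      vv[[length(vv) + 1]] <- data.frame(gene_id = vgene, block = vblk, slot = j)
      if (cls == "tc_dup")
        tc[[length(tc) + 1]] <- data.frame(gene_id = paste0(tgene, "x"),
                                           block = tblkX, slot = j)
      if (cls == "vv_dup")
        vv[[length(vv) + 1]] <- data.frame(gene_id = paste0(vgene, "x"),
                                           block = vblkX, slot = j)
      # Gr-Gr anchors between all Gr copy combinations
      if (length(copies) >= 2) {
        cmb <- utils::combn(copies, 2)
        for (k in seq_len(ncol(cmb)))
          aa[[length(aa) + 1]] <- data.frame(
            geneA = gid(cmb[1, k]), genomeA = "Gr", blockA = blk_of[[cmb[1, k]]],
            geneB = gid(cmb[2, k]), genomeB = "Gr", blockB = blk_of[[cmb[2, k]]])
      }
      # Gr-outgroup anchors: every Gr copy to every outgroup copy
      tc_copies <- if (cls == "tc_dup") c(tgene, paste0(tgene, "x")) else tgene
      tc_blocks <- if (cls == "tc_dup") c(tblk, tblkX) else tblk
      vv_copies <- if (cls == "vv_dup") c(vgene, paste0(vgene, "x")) else vgene
      vv_blocks <- if (cls == "vv_dup") c(vblk, vblkX) else vblk
      for (cp in copies) {
        for (k in seq_along(tc_copies))
          at[[length(at) + 1]] <- data.frame(
            geneA = gid(cp), genomeA = "Gr", blockA = blk_of[[cp]],
            geneB = tc_copies[k], genomeB = "Tc", blockB = tc_blocks[k])
        for (k in seq_along(vv_copies))
          av[[length(av) + 1]] <- data.frame(
            geneA = gid(cp), genomeA = "Gr", blockA = blk_of[[cp]],
            geneB = vv_copies[k], genomeB = "Vv", blockB = vv_blocks[k])
      }
      if (cls == "strict")
        truth[[length(truth) + 1]] <- data.frame(gene1 = gid("a"), gene2 = gid("b"))
    }
  }
  gr <- do.call(rbind, gr); tc <- do.call(rbind, tc); vv <- do.call(rbind, vv)

  # lay genes out along chromosomes: one chromosome per block copy,
  # 1 kb genes separated by 500 bp, 1-based inclusive coordinates
  layout_genome <- function(tab, genome) {
    tab <- tab[order(tab$block, tab$slot), , drop = FALSE]
    pos <- stats::ave(seq_len(nrow(tab)), tab$block, FUN = seq_along)
    data.frame(genome = genome, gene_id = tab$gene_id,
               chrom = paste0(genome, "_", tab$block),
               start = (pos - 1) * 1500 + 1,
               end = (pos - 1) * 1500 + 1000,
               block = tab$block, stringsAsFactors = FALSE)
  }
  gr_genes <- layout_genome(gr, "Gr")
  tc_genes <- layout_genome(tc, "Tc")
  vv_genes <- layout_genome(vv, "Vv")

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene1 = character(), gene2 = character())
  truth <- truth[order(truth$gene1), , drop = FALSE]
  rownames(truth) <- NULL

  list(gr_genes = gr_genes, tc_genes = tc_genes, vv_genes = vv_genes,
       gr_gr = do.call(rbind, aa), gr_tc = do.call(rbind, at),
       gr_vv = do.call(rbind, av),
       annotation = gr_genes[, c("gene_id", "chrom", "start", "end")],
       truth_pairs = truth)
}
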