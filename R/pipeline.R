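#' Configuration for a full pipeline run
#'
#' Collects input paths and every analysis threshold. `pairs_file` may be
#' omitted when anchor tables are given, in which case pairs are called from
#' synteny first. `alignments_file` is optional; without it the dN/dS stage
#' and the category comparison are skipped with a logged notice.
#'
#' @param counts_file,samples_file,lengths_file counts TSV, sample sheet TSV
#'   and gene-length TSV (see [read_counts()]).
#' @param outdir output directory (created if needed).
#' @param pairs_file TSV with `gene1`/`gene2` (and optionally coordinates).
#' @param anchors_files named list with elements `gr_gr`, `gr_tc`, `gr_vv`
#'   (anchor TSVs) used when `pairs_file` is NULL.
#' @param annotation_file gene-model TSV (`gene_id`, `chrom`, `start`,
#'   `end`) or GFF3/BED; required when calling pairs from anchors or running
#'   the positional test.
#' @param alignments_file aligned CDS FASTA, two records per pair.
#' @param norm_method `"RPKM"` or `"UQ"` for the log-ratio stage.
#' @param fdr,pseudocount,min_expr,silencing_threshold,fold_thresholds,window_size
#'   analysis thresholds (defaults: FDR 5%, pseudocount 0.5, floor 1,
#'   silencing 0.95, folds 1.5/2/5, window 20).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts_file, samples_file, lengths_file, outdir,
                            pairs_file = NULL, anchors_files = NULL,
                            annotation_file = NULL, alignments_file = NULL,
                            norm_method = "RPKM", fdr = 0.05,
                            pseudocount = 0.5, min_expr = 1,
                            silencing_threshold = 0.95,
                            fold_thresholds = c(1.5, 2, 5),
                            window_size = 20, seed = 1) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (silencing_threshold <= 0.5 || silencing_threshold > 1)
    stop("silencing_threshold must be in (0.5, 1]")
  if (any(fold_thresholds <= 1)) stop("fold thresholds must exceed 1")
  if (is.null(pairs_file) && is.null(anchors_files))
    stop("either pairs_file or anchors_files must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full paralog-divergence pipeline
#'
#' Stages, each feeding the next: strict-duplicate calling (when anchors are
#' given) -> normalization -> per-pair log-ratio DE -> fold-change and
#' overlap summaries -> reciprocal silencing -> per-pair NB GLM with
#' categories, complementary expression and the pooled ANOVA -> dN/dS (when
#' alignments are given) -> category rank-sum and positional binomial tests
#' -> machine-readable summary. All outputs are TSV files in
#' `config$outdir`; a JSON manifest records the configuration, row counts,
#' warning counts and an md5 checksum of every output. Re-running with
#' identical inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- character()
  warn_count <- 0
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warn_count <<- warn_count + 1
        note("warning [", name, "]: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    res
  }

  counts <- run_stage("read_counts", read_counts(
    config$counts_file, config$samples_file, config$lengths_file))
  note("read counts: ", nrow(counts$counts), " genes, ",
       ncol(counts$counts), " samples")

  annotation <- NULL
  if (!is.null(config$annotation_file)) {
    annotation <- run_stage("annotation", {
      if (grepl("[.](gff3?|bed)$", config$annotation_file, ignore.case = TRUE))
        read_annotation(config$annotation_file)
      else read_tsv(config$annotation_file)
    })
  }

  if (is.null(config$pairs_file)) {
    pairs <- run_stage("call_pairs", call_strict_duplicates(
      read_tsv(config$anchors_files$gr_gr),
      read_tsv(config$anchors_files$gr_tc),
      read_tsv(config$anchors_files$gr_vv), annotation))
    note("called ", nrow(pairs), " strict duplicate pairs from anchors")
    emit(pairs, "pairs.tsv")
    emit(pairs[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                   "pair_id")], "links.tsv")
  } else {
    pairs <- run_stage("read_pairs", read_pairs(config$pairs_file))
    note("read ", nrow(pairs), " pairs")
    emit(pairs, "pairs.tsv")
    if (all(c("chrom1", "start1") %in% names(pairs)))
      emit(pairs[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     "pair_id")], "links.tsv")
  }

  norm <- run_stage("normalize", normalize_counts(counts, config$norm_method))
  emit(data.frame(gene_id = rownames(norm$values), norm$values,
                  check.names = FALSE), "normalized.tsv")

  de <- run_stage("de", paralog_de(norm, pairs,
                                   pseudocount = config$pseudocount,
                                   min_expr = config$min_expr,
                                   fdr = config$fdr))
  note("log-ratio DE: ", sum(!is.na(de$q) & de$q <= config$fdr),
       " significant pair x tissue tests")
  emit(de, "pair_de.tsv")
  emit(run_stage("fold_change", fold_change_table(
    de, thresholds = config$fold_thresholds, fdr = config$fdr)),
    "fold_change_table.tsv")

  ov <- run_stage("overlap", overlap_summary(de, fdr = config$fdr))
  emit(data.frame(tissue = names(ov$per_tissue),
                  n_de = as.integer(ov$per_tissue)), "de_per_tissue.tsv")
  emit(ov$pairwise, "overlap_summary.tsv")

  sil <- run_stage("silencing", detect_reciprocal_silencing(
    norm, pairs, de, threshold = config$silencing_threshold, fdr = config$fdr))
  note("reciprocal silencing: ", nrow(sil), " calls")
  emit(sil, "silencing.tsv")

  glm <- run_stage("glm", glm_divergence(counts, pairs, fdr = config$fdr))
  note("GLM categories: ",
       paste(names(table(glm$results$category)),
             as.integer(table(glm$results$category)),
             sep = "=", collapse = " "))
  emit(glm$results, "glm_results.tsv")
  emit(glm$complementary, "complementary.tsv")
  emit(run_stage("anova", pooled_anova(upper_quartile(counts), pairs)),
       "anova_table.tsv")

  dn <- NULL
  if (!is.null(config$alignments_file) && file.exists(config$alignments_file)) {
    aln <- run_stage("read_alignments", read_codon_alignments(config$alignments_file))
    dn <- run_stage("dnds", dnds_table(aln))
    note("dN/dS computed for ", nrow(dn), " pairs")
    emit(dn, "dnds.tsv")
    cw <- run_stage("category_wilcoxon",
                    suppressMessages(category_wilcoxon(glm$results, dn)))
    emit(cw, "category_wilcoxon.tsv")
  } else {
    note("no alignments given: dN/dS and category comparison skipped")
  }

  if (all(c("chrom1", "start1") %in% names(pairs))) {
    pb <- run_stage("positional_bias", positional_bias_test(
      de, pairs, window_size = config$window_size, fdr = config$fdr))
    emit(pb, "positional_bias.tsv")
  } else {
    note("pairs carry no coordinates: positional test skipped")
  }

  summ <- run_stage("summary", render_summary(
    de = de, glm = glm, silencing = sil, fdr = config$fdr))
  emit(summ, "summary.tsv")

  writeLines(log_lines, file.path(config$outdir, "run.log"))
  manifest <- list(
    tool = "paleodup",
    version = as.character(utils::packageVersion("paleodup")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config[!vapply(config, is.null, TRUE)],
    n_pairs = nrow(pairs),
    n_warnings = warn_count,
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p)
      list(md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)) - 1L)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Figure-ready summary tables of a pipeline run
#'
#' Emits the machine-readable analogues of the study's figures: per-tissue
#' DE counts and percentages, pairwise and all-tissue intersections with
#' same-direction counts, silencing counts per comparison, exclusive GLM
#' category counts and percentages, and complementary-expression counts per
#' tissue pair.
#'
#' @param de result of [paralog_de()].
#' @param glm result of [glm_divergence()].
#' @param silencing result of [detect_reciprocal_silencing()].
#' @param fdr significance level used for DE counting.
#' @return long-format data.frame with columns `section`, `item`, `value`.
#' @export
render_summary <- function(de, glm, silencing, fdr = 0.05) {
  ov <- overlap_summary(de, fdr = fdr)
  n <- ov$n_pairs
  rows <- list()
  add <- function(section, item, value)
    rows[[length(rows) + 1]] <<- data.frame(section = section, item = item,
                                            value = value)
  for (ti in names(ov$per_tissue)) {
    add("de_per_tissue", ti, ov$per_tissue[[ti]])
    add("de_per_tissue_pct", ti, round(100 * ov$per_tissue[[ti]] / n, 1))
  }
  for (k in seq_len(nrow(ov$pairwise))) {
    lab <- paste(ov$pairwise$tissue_a[k], ov$pairwise$tissue_b[k], sep = "|")
    add("de_intersection", lab, ov$pairwise$n_both[k])
    add("de_same_direction", lab, ov$pairwise$n_same_direction[k])
  }
  add("de_intersection", "all_tissues", ov$all_tissues)
  add("de_intersection", "any_tissue", ov$any_tissue)
  add("de_intersection_pct", "any_tissue", round(100 * ov$any_tissue / n, 1))

  if (nrow(silencing)) {
    tab <- table(paste(silencing$condition_a, silencing$condition_b, sep = "|"))
    for (lab in names(tab)) add("reciprocal_silencing", lab, as.integer(tab[[lab]]))
  }
  add("reciprocal_silencing", "total_calls", nrow(silencing))
  add("reciprocal_silencing", "pairs_any_comparison",
      length(unique(silencing$pair_id)))

  cat_tab <- table(glm$results$category)
  for (lab in names(cat_tab)) {
    add("glm_category", lab, as.integer(cat_tab[[lab]]))
    add("glm_category_pct", lab, round(100 * cat_tab[[lab]] / n, 1))
  }
  comp <- glm$complementary
  if (nrow(comp)) {
    tab <- table(paste(comp$tissue_a, comp$tissue_b, sep = "|"))
    for (lab in names(tab)) add("complementary", lab, as.integer(tab[[lab]]))
  }
  add("complementary", "total_calls", nrow(comp))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
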