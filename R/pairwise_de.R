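#' Per-replicate log2 expression ratios for one paralog pair
#'
#' Within each replicate library the two paralogs are measured together, so
#' the ratio cancels sample effects; a pseudocount keeps ratios finite at
#' zero expression while preserving antisymmetry under paralog swap.
#'
#' @param norm a `normalized_matrix`.
#' @param gene1,gene2 gene ids of the pair.
#' @param tissue tissue (or time-point) label selecting replicate columns.
#' @param pseudocount value added to both paralogs before the ratio.
#' @return numeric vector `log2((x1 + pc) / (x2 + pc))`, one per replicate.
#' @export
pair_log_ratios <- function(norm, gene1, gene2, tissue, pseudocount = 0.5) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!all(c(gene1, gene2) %in% rownames(norm$values)))
    stop("pair gene(s) missing from matrix: ",
         paste(setdiff(c(gene1, gene2), rownames(norm$values)), collapse = ", "))
  reps <- norm$samples$sample_id[norm$samples$tissue == tissue]
  if (length(reps) < 2) stop("tissue ", tissue, " has fewer than 2 replicates")
  x1 <- norm$values[gene1, reps]
  x2 <- norm$values[gene2, reps]
  unname(log2((x1 + pseudocount) / (x2 + pseudocount)))
}

#' One-sample t-test of log ratios against zero
#'
#' Two-sided Student's t-test of the mean log ratio against 0 with
#' `df = n - 1`. A zero-variance vector is degenerate: all-zero ratios give
#' `t = 0, p = 1`; a nonzero constant gives `p = 0` with the degenerate flag
#' set (the ratio is measured without replicate noise).
#'
#' @param log_ratios numeric vector of at least 2 finite values.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
pair_ttest <- function(log_ratios) {
  r <- log_ratios[is.finite(log_ratios)]
  n <- length(r)
  if (n < 2) stop("need at least 2 finite log ratios")
  m <- mean(r); s <- stats::sd(r)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, degenerate = FALSE))
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1),
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in `[0, 1]` (NAs carried through).
#' @param fdr target false discovery rate for the reject flags.
#' @return list with `q` (BH-adjusted values) and `reject` (`q <= fdr`).
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Per-pair, per-tissue differential expression between paralogs
#'
#' For every pair and tissue, computes per-replicate log2 ratios of
#' normalized expression (with pseudocount), a one-sample t-test of the mean
#' ratio against zero, and BH-adjusted q-values within each tissue. Pairs in
#' which both paralogs fall below the minimum-expression floor in a tissue
#' are excluded from testing there (`tested = FALSE`, NA statistics) and do
#' not enter the BH family.
#'
#' @param norm a `normalized_matrix`.
#' @param pairs pair table with `pair_id`, `gene1`, `gene2`.
#' @param pseudocount added to normalized values before the log ratio.
#' @param min_expr minimum-expression floor: a pair is tested in a tissue
#'   only if at least one paralog has mean normalized expression >= this.
#' @param fdr FDR level used for the direction call.
#' @param tissues tissues to test (default: all in the sample sheet).
#' @return data.frame, one row per pair x tissue: `pair_id`, `tissue`,
#'   `n_reps`, `mean_log2_ratio`, `t`, `df`, `p`, `q`, `fold_change`
#'   (`2^|mean|`, linear, >= 1), `direction`
#'   (`gene1_higher`/`gene2_higher`/`none`), `tested`, `degenerate_variance`.
#'   Attributes `fdr` and `method` record the analysis settings.
#' @export
paralog_de <- function(norm, pairs, pseudocount = 0.5, min_expr = 1,
                       fdr = 0.05, tissues = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (is.null(tissues)) tissues <- unique(norm$samples$tissue)
  missing <- setdiff(c(pairs$gene1, pairs$gene2), rownames(norm$values))
  if (length(missing))
    stop("pair genes missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- lapply(tissues, function(ti) {
    reps <- norm$samples$sample_id[norm$samples$tissue == ti]
    if (length(reps) < 2) stop("tissue ", ti, " has fewer than 2 replicates")
    X1 <- norm$values[pairs$gene1, reps, drop = FALSE]
    X2 <- norm$values[pairs$gene2, reps, drop = FALSE]
    tested <- rowMeans(X1) >= min_expr | rowMeans(X2) >= min_expr
    R <- log2((X1 + pseudocount) / (X2 + pseudocount))
    n <- ncol(R)
    m <- rowMeans(R)
    s <- sqrt(pmax(rowSums((R - m)^2), 0) / (n - 1))
    t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
    p <- ifelse(s > 0, 2 * stats::pt(-abs(t), df = n - 1), ifelse(m == 0, 1, 0))
    degenerate <- s == 0 & m != 0
    p[!tested] <- NA; t[!tested] <- NA; m_out <- m; m_out[!tested] <- NA
    q <- rep(NA_real_, length(p))
    q[tested] <- bh_adjust(p[tested])$q
    sig <- !is.na(q) & q <= fdr
    data.frame(pair_id = pairs$pair_id, tissue = ti, n_reps = n,
               mean_log2_ratio = m_out, t = t, df = n - 1, p = p, q = q,
               fold_change = 2^abs(m_out),
               direction = ifelse(sig & m_out > 0, "gene1_higher",
                                  ifelse(sig & m_out < 0, "gene2_higher", "none")),
               tested = tested, degenerate_variance = degenerate & tested,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fdr") <- fdr
  attr(res, "method") <- norm$method
  res
}

#' Fold-change stratification of differentially expressed pairs
#'
#' Counts pairs that are both BH-significant and meet each linear fold-change
#' threshold, per tissue, plus a maximum-in-any-tissue row counting pairs
#' that meet the condition in at least one tissue. Cells are nested:
#' the 5x count can never exceed the 2x or 1.5x counts.
#'
#' @param de result of [paralog_de()].
#' @param thresholds linear fold-change thresholds.
#' @param fdr significance level on the q-values (default: the level stored
#'   on `de`).
#' @return data.frame with a `tissue` column (tissues plus `"any_tissue"`)
#'   and one `fold_<threshold>` column per threshold.
#' @export
fold_change_table <- function(de, thresholds = c(1.5, 2, 5), fdr = NULL) {
  if (is.null(fdr)) fdr <- attr(de, "fdr") %||% 0.05
  tissues <- unique(de$tissue)
  sig <- !is.na(de$q) & de$q <= fdr
  rows <- lapply(c(tissues, "any_tissue"), function(ti) {
    cnt <- vapply(thresholds, function(th) {
      hit <- sig & de$fold_change >= th
      if (ti == "any_tissue") length(unique(de$pair_id[hit]))
      else sum(hit & de$tissue == ti, na.rm = TRUE)
    }, 0L)
    as.data.frame(c(list(tissue = ti), stats::setNames(as.list(cnt),
                                                       paste0("fold_", thresholds))))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap of differential-expression calls across tissues (and species)
#'
#' Counts DE pairs per tissue, every pairwise tissue intersection (with the
#' number biased in the same direction in both tissues), the all-tissue
#' intersection and the any-tissue union. When a second result set over the
#' same pair universe is supplied (e.g. a sister species), per-tissue and
#' overall cross-set intersections are added.
#'
#' @param de result of [paralog_de()].
#' @param de2 optional second result set over the same pairs.
#' @param fdr significance level on q-values.
#' @return list with `n_pairs`, `per_tissue`, `pairwise` (data.frame with
#'   `n_both` and `n_same_direction`), `all_tissues`, `any_tissue`, and, when
#'   `de2` is given, `cross` (per-tissue and joint intersections).
#' @export
overlap_summary <- function(de, de2 = NULL, fdr = NULL) {
  if (is.null(fdr)) fdr <- attr(de, "fdr") %||% 0.05
  universe <- sort(unique(de$pair_id))
  de_sets <- function(d) {
    if (!identical(sort(unique(d$pair_id)), universe))
      stop("mismatched pair universes between result sets")
    split(d[!is.na(d$q) & d$q <= fdr, c("pair_id", "direction")],
          d$tissue[!is.na(d$q) & d$q <= fdr])
  }
  sets <- de_sets(de)
  tissues <- unique(de$tissue)
  per_tissue <- vapply(tissues, function(ti)
    length(sets[[ti]]$pair_id %||% character()), 0L)
  cmb <- utils::combn(tissues, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- sets[[cmb[1, k]]]; b <- sets[[cmb[2, k]]]
    common <- intersect(a$pair_id, b$pair_id)
    same <- sum(a$direction[match(common, a$pair_id)] ==
                  b$direction[match(common, b$pair_id)])
    data.frame(tissue_a = cmb[1, k], tissue_b = cmb[2, k],
               n_both = length(common), n_same_direction = same)
  }))
  ids <- lapply(tissues, function(ti) sets[[ti]]$pair_id %||% character())
  out <- list(n_pairs = length(universe),
              per_tissue = stats::setNames(per_tissue, tissues),
              pairwise = pairwise,
              all_tissues = length(Reduce(intersect, ids)),
              any_tissue = length(Reduce(union, ids)))
  if (!is.null(de2)) {
    sets2 <- de_sets(de2)
    cross_t <- vapply(tissues, function(ti)
      length(intersect(sets[[ti]]$pair_id %||% character(),
                       sets2[[ti]]$pair_id %||% character())), 0L)
    ids2 <- lapply(tissues, function(ti) sets2[[ti]]$pair_id %||% character())
    out$cross <- list(
      per_tissue = stats::setNames(cross_t, tissues),
      all_tissues_both = length(intersect(Reduce(intersect, ids),
                                          Reduce(intersect, ids2))),
      any_tissue_both = length(intersect(Reduce(union, ids),
                                         Reduce(union, ids2))))
  }
  out
}

#' Detect tissue-specific reciprocal silencing
#'
#' Among pairs differentially expressed in both conditions of a comparison,
#' calls reciprocal silencing when one paralog accounts for at least
#' `threshold` of the pair's total normalized expression in one condition
#' and at most `1 - threshold` in the other (boundaries inclusive).
#' Proportions are computed from replicate-mean normalized expression.
#' Pairs with zero total expression in a condition are excluded with a
#' warning.
#'
#' @param norm a `normalized_matrix`.
#' @param pairs pair table (`pair_id`, `gene1`, `gene2`).
#' @param de result of [paralog_de()] defining the DE universe.
#' @param conditions tissues/time points to compare (default: all tissues
#'   present in `de`); every unordered pair of conditions is examined.
#' @param threshold dominance threshold (default 0.95: the "95% or more"
#'   silencing rule).
#' @param fdr significance level on q-values.
#' @return data.frame of calls: `pair_id`, `condition_a`, `condition_b`,
#'   `dominant_gene_in_a`, `dominant_gene_in_b`, `proportion_a`,
#'   `proportion_b` (proportions are gene1's share of the pair total).
#' @export
detect_reciprocal_silencing <- function(norm, pairs, de, conditions = NULL,
                                        threshold = 0.95, fdr = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  if (is.null(fdr)) fdr <- attr(de, "fdr") %||% 0.05
  if (is.null(conditions)) conditions <- unique(de$tissue)
  sig <- function(ti) {
    d <- de[de$tissue == ti, ]
    d$pair_id[!is.na(d$q) & d$q <= fdr]
  }
  prop1 <- function(ti) {
    reps <- norm$samples$sample_id[norm$samples$tissue == ti]
    m1 <- rowMeans(norm$values[pairs$gene1, reps, drop = FALSE])
    m2 <- rowMeans(norm$values[pairs$gene2, reps, drop = FALSE])
    stats::setNames(ifelse(m1 + m2 > 0, m1 / (m1 + m2), NA_real_), pairs$pair_id)
  }
  props <- lapply(stats::setNames(conditions, conditions), prop1)
  cmb <- utils::combn(conditions, 2)
  calls <- list()
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    elig <- intersect(sig(a), sig(b))
    pa <- props[[a]][elig]; pb <- props[[b]][elig]
    if (anyNA(pa) || anyNA(pb)) {
      bad <- elig[is.na(pa) | is.na(pb)]
      warning("pair(s) with zero total expression excluded in ", a, " vs ",
              b, ": ", paste(bad, collapse = ", "))
      elig <- setdiff(elig, bad); pa <- props[[a]][elig]; pb <- props[[b]][elig]
    }
    hit <- (pa >= threshold & pb <= 1 - threshold) |
      (pa <= 1 - threshold & pb >= threshold)
    if (any(hit)) {
      g1 <- pairs$gene1[match(elig[hit], pairs$pair_id)]
      g2 <- pairs$gene2[match(elig[hit], pairs$pair_id)]
      calls[[length(calls) + 1]] <- data.frame(
        pair_id = elig[hit], condition_a = a, condition_b = b,
        dominant_gene_in_a = ifelse(pa[hit] >= threshold, g1, g2),
        dominant_gene_in_b = ifelse(pb[hit] >= threshold, g1, g2),
        proportion_a = unname(pa[hit]), proportion_b = unname(pb[hit]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(pair_id = character(), condition_a = character(),
                      condition_b = character(),
                      dominant_gene_in_a = character(),
                      dominant_gene_in_b = character(),
                      proportion_a = numeric(), proportion_b = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}
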