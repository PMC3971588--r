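#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided rank-sum test of a location shift between two independent
#' groups. `W` is the rank sum of group A in the combined ranking. The exact
#' null distribution is used when the smaller group has at most 10 values
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_max largest min-group size for the exact distribution.
#' @return list with `W` (rank sum of `a`), `U` (Mann-Whitney statistic),
#'   `p`, `exact`.
#' @export
wilcoxon_compare <- function(a, b, exact_max = 10) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (min(na, nb) <= exact_max && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)))
    return(list(W = W, U = U, p = p, exact = TRUE))
  }
  mu <- na * nb / 2
  tie_tab <- table(r)
  n <- na + nb
  sigma2 <- na * nb / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 == 0) return(list(W = W, U = U, p = 1, exact = FALSE))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(W = W, U = U, p = min(1, 2 * stats::pnorm(-z)), exact = FALSE)
}

#' Compare dN/dS between GLM effect categories
#'
#' Runs [wilcoxon_compare()] on the omega values of every pair of non-empty
#' categories. Pairs with undefined or non-finite omega (e.g. dS = 0) are
#' excluded; the number excluded is reported as a message.
#'
#' @param glm_results per-pair results from [glm_divergence()] (needs
#'   `pair_id` and `category`).
#' @param dnds_results table from [dnds_table()] (needs `pair_id`, `omega`).
#' @return data.frame: `category_a`, `category_b`, `n_a`, `n_b`, `W`, `p`.
#' @export
category_wilcoxon <- function(glm_results, dnds_results) {
  omega <- dnds_results$omega[match(glm_results$pair_id, dnds_results$pair_id)]
  keep <- is.finite(omega) & !is.na(glm_results$category)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " pair(s) without a finite omega excluded")
  cat_f <- droplevels(glm_results$category[keep])
  groups <- split(omega[keep], cat_f)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2)
    return(data.frame(category_a = character(), category_b = character(),
                      n_a = integer(), n_b = integer(), W = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  cmb <- utils::combn(names(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    w <- wilcoxon_compare(groups[[cmb[1, k]]], groups[[cmb[2, k]]])
    data.frame(category_a = cmb[1, k], category_b = cmb[2, k],
               n_a = length(groups[[cmb[1, k]]]),
               n_b = length(groups[[cmb[2, k]]]),
               W = w$W, p = w$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Positional bias of paralog expression dominance
#'
#' Tests whether duplicates in a chromosomal region tend to be over- or
#' under-expressed relative to their partner. Each pair member gene with a
#' significant per-tissue direction contributes one observation: "success"
#' when that member is the higher-expressed copy. Genes are ordered along
#' each chromosome and scanned in sliding windows of `window_size`
#' consecutive pair-anchoring genes with 50% overlap (a chromosome shorter
#' than one window forms a single window). Each window gets a two-sided
#' exact binomial test against 0.5; BH correction is applied across windows
#' within each tissue.
#'
#' @param de result of [paralog_de()].
#' @param pairs pair table with member coordinates (`gene1`, `chrom1`,
#'   `start1`, `end1`, and the gene2 equivalents).
#' @param window_size genes per window.
#' @param fdr FDR level for the `significant` flag.
#' @return data.frame: `tissue`, `chrom`, `start`, `end`,
#'   `n_pairs_in_window` (informative members), `n_higher`, `p`, `q`,
#'   `significant`. Windows with no informative member are skipped.
#' @export
positional_bias_test <- function(de, pairs, window_size = 20, fdr = 0.05) {
  members <- rbind(
    data.frame(pair_id = pairs$pair_id, gene = pairs$gene1, member = "gene1",
               chrom = pairs$chrom1, start = pairs$start1, end = pairs$end1,
               stringsAsFactors = FALSE),
    data.frame(pair_id = pairs$pair_id, gene = pairs$gene2, member = "gene2",
               chrom = pairs$chrom2, start = pairs$start2, end = pairs$end2,
               stringsAsFactors = FALSE))
  out <- list()
  for (ti in unique(de$tissue)) {
    d <- de[de$tissue == ti, ]
    dir <- d$direction[match(members$pair_id, d$pair_id)]
    m <- members
    m$informative <- dir != "none" & !is.na(dir)
    m$higher <- (m$member == "gene1" & dir == "gene1_higher") |
      (m$member == "gene2" & dir == "gene2_higher")
    for (ch in unique(m$chrom)) {
      mc <- m[m$chrom == ch, ]
      mc <- mc[order(mc$start), ]
      nG <- nrow(mc)
      starts <- if (nG <= window_size) 1 else
        unique(c(seq(1, nG - window_size + 1, by = max(1, floor(window_size / 2))),
                 nG - window_size + 1))
      for (s in starts) {
        idx <- s:min(s + window_size - 1, nG)
        w <- mc[idx, ]
        n <- sum(w$informative)
        if (n == 0) next
        k <- sum(w$higher & w$informative)
        p <- stats::binom.test(k, n, p = 0.5)$p.value
        out[[length(out) + 1]] <- data.frame(
          tissue = ti, chrom = ch, start = min(w$start), end = max(w$end),
          n_pairs_in_window = n, n_higher = k, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(tissue = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_pairs_in_window = integer(), n_higher = integer(),
                      p = numeric(), q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (ti in unique(res$tissue)) {
    sel <- res$tissue == ti
    res$q[sel] <- bh_adjust(res$p[sel])$q
  }
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  res
}
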