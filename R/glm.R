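#' Fit the per-pair negative binomial GLM
#'
#' Models the counts of the two paralogs of one pair across tissues and
#' replicates as `log mu = intercept + gene + tissue + gene:tissue + offset`,
#' with reference coding (gene 1 and the alphabetically first tissue are the
#' references). The NB dispersion phi (variance = mu + phi * mu^2) is
#' estimated per pair by maximum likelihood; when the MLE sits at the
#' equidispersion boundary (or the NB fit fails to converge) the fit falls
#' back to Poisson with `phi = 0` and the `boundary_dispersion` flag set.
#' Offsets carry normalization (e.g. log upper-quartile size factors) into
#' the count likelihood instead of pre-dividing the counts.
#'
#' @param y non-negative integer counts, one per observation.
#' @param gene factor (2 levels) identifying the paralog of each observation.
#' @param tissue factor (>= 2 levels) of each observation.
#' @param offset optional log-scale offset per observation (default 0).
#' @param dispersion `"mle"` (per-pair ML estimate), `"poisson"` (phi = 0),
#'   or a fixed numeric phi > 0.
#' @return A `pair_glm` object: coefficients, covariance matrix, `phi`,
#'   `converged`, `boundary_dispersion`, `near_boundary` (separation-scale
#'   coefficients), `loglik`, and the factor levels used.
#' @export
fit_pair_glm <- function(y, gene, tissue, offset = NULL,
                         dispersion = "mle") {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("counts must be non-negative integers")
  gene <- factor(gene)
  tissue <- factor(tissue, levels = sort(unique(as.character(tissue))))
  if (nlevels(gene) != 2) stop("gene must have exactly 2 levels")
  if (nlevels(tissue) < 2) stop("need at least 2 tissues")
  if (min(table(gene, tissue)) < 2) stop("need >= 2 replicates per gene x tissue cell")
  if (is.null(offset)) offset <- rep(0, length(y))
  dat <- data.frame(y = y, gene = gene, tissue = tissue, off = offset)

  boundary <- FALSE
  if (identical(dispersion, "mle")) {
    fit <- withCallingHandlers(
      tryCatch(MASS::glm.nb(y ~ gene * tissue + offset(off), data = dat),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    # theta -> Inf (or a failed NB fit) is the Poisson boundary
    if (is.null(fit) || !isTRUE(fit$converged) || fit$theta > 1e8) {
      boundary <- TRUE
      fit <- stats::glm(y ~ gene * tissue + offset(off), data = dat,
                        family = stats::poisson())
      phi <- 0
    } else {
      phi <- max(1 / fit$theta, 1e-8)
    }
  } else if (identical(dispersion, "poisson") ||
             (is.numeric(dispersion) && dispersion == 0)) {
    fit <- stats::glm(y ~ gene * tissue + offset(off), data = dat,
                      family = stats::poisson())
    phi <- 0
  } else if (is.numeric(dispersion) && dispersion > 0) {
    fit <- suppressWarnings(
      stats::glm(y ~ gene * tissue + offset(off), data = dat,
                 family = MASS::negative.binomial(theta = 1 / dispersion)))
    phi <- dispersion
  } else stop("dispersion must be 'mle', 'poisson', or a numeric phi")

  cf <- stats::coef(fit)
  structure(list(
    coefficients = cf,
    vcov = stats::vcov(fit),
    phi = phi,
    converged = isTRUE(fit$converged),
    boundary_dispersion = boundary,
    near_boundary = any(abs(cf[-1]) > 15, na.rm = TRUE),
    loglik = as.numeric(stats::logLik(fit)),
    X = stats::model.matrix(~ gene * tissue, data = dat),
    y = y, offset = offset,
    gene_levels = levels(gene),
    tissue_levels = levels(tissue)), class = "pair_glm")
}

#' @export
print.pair_glm <- function(x, ...) {
  cat("pair_glm: phi =", signif(x$phi, 3),
      if (x$boundary_dispersion) "(Poisson boundary)" else "", "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Contrast tests for gene, tissue and interaction effects
#'
#' From one fitted pair GLM, tests:
#' \describe{
#'   \item{G}{the gene contrast averaged over tissues (1 df): do the paralogs
#'     differ in mean expression combined across tissues?}
#'   \item{T}{joint test (T-1 df) that the pooled-paralog mean differs
#'     between any two tissues.}
#'   \item{GxT}{joint test (T-1 df) of all gene-by-tissue interactions: is
#'     the paralog difference tissue-dependent?}
#'   \item{G|T}{the within-tissue gene contrast (1 df) for each tissue.}
#' }
#' The default statistic is a likelihood-ratio test at the full-model
#' dispersion: the design is reparameterized so the contrast rows become
#' coordinates, the constrained model drops them, and twice the
#' log-likelihood difference is referred to a chi-square. This stays
#' powerful when a gene is unobserved in a tissue (separation), where the
#' Wald statistic collapses towards zero (Hauck-Donner effect). Wald
#' chi-square tests on the coefficient vector are available with
#' `type = "wald"`; a singular contrast covariance yields `NA` with the
#' `singular` flag.
#'
#' @param fit a `pair_glm`.
#' @param type `"lrt"` (default) or `"wald"`.
#' @return list with `p_G`, `p_T`, `p_GxT`, `p_G_by_T` (named per tissue),
#'   `gene_lfc_by_tissue` (natural-log gene2/gene1 difference per tissue,
#'   used downstream for dominance), and `singular`.
#' @export
contrast_tests <- function(fit, type = c("lrt", "wald")) {
  stopifnot(inherits(fit, "pair_glm"))
  type <- match.arg(type)
  cf <- fit$coefficients; V <- fit$vcov
  nm <- names(cf)
  tiss <- fit$tissue_levels; Tn <- length(tiss)
  g2 <- paste0("gene", fit$gene_levels[2])
  tt <- paste0("tissue", tiss[-1])
  it <- paste0(g2, ":tissue", tiss[-1])
  stopifnot(all(c(g2, tt, it) %in% nm))
  unit <- function(cols, w = 1) {
    v <- stats::setNames(rep(0, length(nm)), nm); v[cols] <- w; v
  }
  wald <- function(C) {
    C <- rbind(C)
    est <- C %*% cf
    Vc <- C %*% V %*% t(C)
    s <- try(solve(Vc, est), silent = TRUE)
    if (inherits(s, "try-error")) return(NA_real_)
    stat <- drop(t(est) %*% s)
    stats::pchisq(stat, df = nrow(C), lower.tail = FALSE)
  }
  fam <- if (fit$phi == 0) stats::poisson() else
    MASS::negative.binomial(theta = 1 / fit$phi)
  dev_of <- function(Xm) {
    f <- suppressWarnings(stats::glm.fit(Xm, fit$y, family = fam,
                                         offset = fit$offset))
    f$deviance
  }
  dev_full <- dev_of(fit$X)
  lrt <- function(C) {
    C <- rbind(C)
    k <- nrow(C)
    # complete C to an invertible reparameterization; the hypothesis
    # C beta = 0 becomes "the first k new coordinates vanish"
    Tm <- rbind(C, t(MASS::Null(t(C))))
    Xs <- fit$X %*% solve(Tm)
    stat <- dev_of(Xs[, -seq_len(k), drop = FALSE]) - dev_full
    stats::pchisq(max(stat, 0), df = k, lower.tail = FALSE)
  }
  test <- if (type == "lrt") lrt else wald
  # gene difference within each tissue (natural log, gene2 - gene1)
  L_t <- lapply(tiss, function(ti) {
    if (ti == tiss[1]) unit(g2)
    else unit(c(g2, paste0(g2, ":tissue", ti)))
  })
  names(L_t) <- tiss
  p_gt <- vapply(L_t, test, 0)
  # G: gene difference averaged over tissues
  L_G <- unit(g2) + Reduce(`+`, lapply(it, function(cn) unit(cn, 1 / Tn)))
  # T: pooled-paralog tissue shifts (tissue main + half the interaction)
  C_T <- do.call(rbind, lapply(seq_along(tt), function(k)
    unit(tt[k]) + unit(it[k], 0.5)))
  C_I <- do.call(rbind, lapply(it, unit))
  est_t <- vapply(L_t, function(v) drop(v %*% cf), 0)
  p_G <- test(L_G); p_T <- test(C_T); p_GxT <- test(C_I)
  list(p_G = p_G, p_T = p_T, p_GxT = p_GxT,
       p_G_by_T = p_gt, gene_lfc_by_tissue = est_t,
       singular = anyNA(c(p_G, p_T, p_GxT, p_gt)))
}

#' Exclusive effect categories from significance indicators
#'
#' Every pair falls in exactly one of eight exclusive categories given by the
#' combination of its significant effects after FDR correction:
#' i = none, ii = G, iii = T, iv = GxT, v = G+T, vi = G+GxT, vii = T+GxT,
#' viii = G+T+GxT.
#'
#' @param q_G,q_T,q_GxT BH-adjusted p-values (vectors of equal length).
#' @param fdr significance threshold on the q-values.
#' @return character vector of roman-numeral categories; `NA` where any
#'   q-value is missing.
#' @export
assign_categories <- function(q_G, q_T, q_GxT, fdr = 0.05) {
  codes <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii")
  sg <- q_G <= fdr; st <- q_T <= fdr; si <- q_GxT <= fdr
  idx <- 1L + sg * 1L + st * 2L + si * 4L
  # order: none, G, T, G+T, GxT, G+GxT, T+GxT, G+T+GxT
  map <- c("i", "ii", "iii", "v", "iv", "vi", "vii", "viii")
  out <- map[idx]
  out[is.na(q_G) | is.na(q_T) | is.na(q_GxT)] <- NA_character_
  factor(out, levels = codes)
}

#' Run the GLM contrast analysis over all paralog pairs
#'
#' Fits one NB GLM per pair (counts with log offsets from upper-quartile
#' scale factors), runs G / T / GxT / per-tissue G|T Wald contrasts, applies
#' BH correction within each effect family across pairs (per tissue for the
#' G|T family), assigns exclusive categories, and detects complementary
#' expression.
#'
#' @param counts a [counts_matrix()].
#' @param pairs pair table (`pair_id`, `gene1`, `gene2`).
#' @param fdr FDR level for all effect families.
#' @param dispersion passed to [fit_pair_glm()].
#' @param contrast_type passed to [contrast_tests()].
#' @param species restrict to one species from the sample sheet (default:
#'   all samples).
#' @return list with `results` (one row per pair: p/q per effect, per-tissue
#'   p/q and gene1 dominance proportions, `category`, fit flags) and
#'   `complementary` (calls from [detect_complementary()]).
#' @export
glm_divergence <- function(counts, pairs, fdr = 0.05, dispersion = "mle",
                           contrast_type = "lrt", species = NULL) {
  stopifnot(inherits(counts, "counts_matrix"))
  samples <- counts$samples
  if (!is.null(species)) samples <- samples[samples$species == species, ]
  sids <- samples$sample_id
  missing <- setdiff(c(pairs$gene1, pairs$gene2), rownames(counts$counts))
  if (length(missing)) stop("pair genes missing from counts: ",
                            paste(utils::head(missing, 5), collapse = ", "))

  # upper-quartile size factors as offsets inside the NB likelihood
  uq <- upper_quartile(counts)
  f <- uq$scale_factors[sids]
  off_sample <- log(f / exp(mean(log(f))))
  tissue <- factor(samples$tissue,
                   levels = sort(unique(as.character(samples$tissue))))
  tiss <- levels(tissue)

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    y <- c(counts$counts[pairs$gene1[i], sids], counts$counts[pairs$gene2[i], sids])
    gene <- factor(rep(c("g1", "g2"), each = length(sids)))
    fit <- fit_pair_glm(y, gene, rep(tissue, 2), offset = rep(off_sample, 2),
                        dispersion = dispersion)
    ct <- contrast_tests(fit, type = contrast_type)
    prop1 <- 1 / (1 + exp(ct$gene_lfc_by_tissue))  # gene1 share per tissue
    rows[[i]] <- c(list(pair_id = pairs$pair_id[i], p_G = ct$p_G,
                        p_T = ct$p_T, p_GxT = ct$p_GxT),
                   stats::setNames(as.list(ct$p_G_by_T), paste0("p_GbyT_", tiss)),
                   stats::setNames(as.list(prop1), paste0("prop1_", tiss)),
                   list(phi = fit$phi, converged = fit$converged,
                        boundary_dispersion = fit$boundary_dispersion,
                        near_boundary = fit$near_boundary))
  }
  res <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))

  res$q_G <- bh_adjust(res$p_G)$q
  res$q_T <- bh_adjust(res$p_T)$q
  res$q_GxT <- bh_adjust(res$p_GxT)$q
  for (ti in tiss)
    res[[paste0("q_GbyT_", ti)]] <- bh_adjust(res[[paste0("p_GbyT_", ti)]])$q
  res$category <- assign_categories(res$q_G, res$q_T, res$q_GxT, fdr = fdr)

  comp <- detect_complementary(res, tissues = tiss, fdr = fdr, pairs = pairs)
  attr(res, "fdr") <- fdr
  attr(res, "tissues") <- tiss
  list(results = res, complementary = comp)
}

#' Detect complementary expression between tissues
#'
#' For each unordered tissue pair (A, B), a paralog pair is complementary
#' when it is significantly differentially expressed within both tissues
#' (G|T q-values at or below the FDR) and the dominant paralog (estimated
#' expression share > 0.5) differs between A and B. Unlike reciprocal
#' silencing this does not require near-total silencing of either copy. A
#' share of exactly 0.5 names no dominant paralog and blocks the call.
#'
#' @param res per-pair GLM results with `q_GbyT_<tissue>` and
#'   `prop1_<tissue>` columns (from [glm_divergence()]).
#' @param tissues tissues to compare.
#' @param fdr significance level.
#' @param pairs optional pair table used to report dominant gene ids.
#' @return data.frame: `pair_id`, `tissue_a`, `tissue_b`, `dominant_in_a`,
#'   `dominant_in_b`, `prop1_a`, `prop1_b`.
#' @export
detect_complementary <- function(res, tissues, fdr = 0.05, pairs = NULL) {
  cmb <- utils::combn(tissues, 2)
  calls <- list()
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    qa <- res[[paste0("q_GbyT_", a)]]; qb <- res[[paste0("q_GbyT_", b)]]
    pa <- res[[paste0("prop1_", a)]]; pb <- res[[paste0("prop1_", b)]]
    hit <- !is.na(qa) & !is.na(qb) & qa <= fdr & qb <= fdr &
      ((pa > 0.5 & pb < 0.5) | (pa < 0.5 & pb > 0.5))
    if (any(hit)) {
      ids <- res$pair_id[hit]
      g1 <- if (!is.null(pairs)) pairs$gene1[match(ids, pairs$pair_id)] else "gene1"
      g2 <- if (!is.null(pairs)) pairs$gene2[match(ids, pairs$pair_id)] else "gene2"
      calls[[length(calls) + 1]] <- data.frame(
        pair_id = ids, tissue_a = a, tissue_b = b,
        dominant_in_a = ifelse(pa[hit] > 0.5, g1, g2),
        dominant_in_b = ifelse(pb[hit] > 0.5, g1, g2),
        prop1_a = pa[hit], prop1_b = pb[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(pair_id = character(), tissue_a = character(),
                      tissue_b = character(), dominant_in_a = character(),
                      dominant_in_b = character(), prop1_a = numeric(),
                      prop1_b = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Pooled two-way ANOVA of normalized expression across all pairs
#'
#' Classical fixed-effects two-way ANOVA of (log) normalized expression with
#' gene (one level per paralog, 2 x n_pairs levels), tissue, and their
#' interaction. Computed by direct mean decomposition, which is exact for a
#' balanced design (equal replicates per gene x tissue cell); missing cells
#' are an error. With P pairs, T tissues and n replicates the degrees of
#' freedom are 2P - 1 (gene), T - 1 (tissue), (2P - 1)(T - 1) (interaction)
#' and 2PT(n - 1) (residual).
#'
#' @param norm a `normalized_matrix`.
#' @param pairs pair table; both members of every pair enter as gene levels.
#' @param log2_scale take `log2(value + pseudocount)` before the ANOVA.
#' @param pseudocount pseudocount for the log transform.
#' @return data.frame with rows Gene, Tissue, Gene:Tissue, Residuals and
#'   columns `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
pooled_anova <- function(norm, pairs, log2_scale = TRUE, pseudocount = 0.5) {
  stopifnot(inherits(norm, "normalized_matrix"))
  genes <- c(rbind(pairs$gene1, pairs$gene2))
  vals <- norm$values[genes, , drop = FALSE]
  y <- as.vector(vals)
  if (log2_scale) y <- log2(y + pseudocount)
  gene_f <- factor(rep(genes, times = ncol(vals)), levels = genes)
  tiss_f <- factor(rep(norm$samples$tissue, each = length(genes)))

  cell_n <- table(gene_f, tiss_f)
  if (any(cell_n == 0)) {
    bad <- which(cell_n == 0, arr.ind = TRUE)
    stop("missing design cells: ",
         paste(rownames(cell_n)[bad[, 1]], colnames(cell_n)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  if (length(unique(as.vector(cell_n))) != 1)
    stop("unbalanced design: pooled ANOVA requires equal replicates per cell")
  n <- cell_n[1, 1]
  G <- nlevels(gene_f); Tn <- nlevels(tiss_f)

  gm <- mean(y)
  m_g <- tapply(y, gene_f, mean)
  m_t <- tapply(y, tiss_f, mean)
  m_gt <- tapply(y, list(gene_f, tiss_f), mean)
  ss_g <- Tn * n * sum((m_g - gm)^2)
  ss_t <- G * n * sum((m_t - gm)^2)
  ss_i <- n * sum((m_gt - outer(m_g, rep(1, Tn)) -
                     outer(rep(1, G), m_t) + gm)^2)
  ss_r <- sum((y - m_gt[cbind(gene_f, tiss_f)])^2)
  df <- c(G - 1, Tn - 1, (G - 1) * (Tn - 1), G * Tn * (n - 1))
  ss <- c(ss_g, ss_t, ss_i, ss_r)
  ms <- ss / df
  F <- c(ms[1:3] / ms[4], NA)
  if (ms[4] == 0) F[1:3] <- NA  # no residual variation: F undefined
  p <- c(stats::pf(F[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  data.frame(term = c("Gene", "Tissue", "Gene:Tissue", "Residuals"),
             df = df, sum_sq = ss, mean_sq = ms, F = F, p = p,
             stringsAsFactors = FALSE)
}
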