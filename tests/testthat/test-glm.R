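toy_layout <- function(n_reps = 3, tissues = c("leaf", "petal")) {
  list(gene = factor(rep(c("g1", "g2"), each = n_reps * length(tissues))),
       tissue = factor(rep(rep(tissues, each = n_reps), 2)))
}

test_that("symmetric input yields null gene and interaction coefficients", {
  lay <- toy_layout()
  y <- rep(c(30, 35, 28, 60, 62, 58), 2)  # identical counts for both genes
  fit <- fit_pair_glm(y, lay$gene, lay$tissue, dispersion = 0.05)
  cf <- fit$coefficients
  expect_lt(abs(cf[["geneg2"]]), 1e-6)
  expect_lt(abs(cf[["geneg2:tissuepetal"]]), 1e-6)
  ct <- contrast_tests(fit)
  expect_gt(ct$p_G, 0.99)
  expect_gt(ct$p_GxT, 0.99)
  expect_true(all(ct$p_G_by_T > 0.99))
})

test_that("constant offsets only shift the intercept", {
  lay <- toy_layout()
  set.seed(1)
  y <- rpois(12, 40)
  f0 <- fit_pair_glm(y, lay$gene, lay$tissue, offset = rep(0, 12),
                     dispersion = 0.05)
  f2 <- fit_pair_glm(y, lay$gene, lay$tissue, offset = rep(2, 12),
                     dispersion = 0.05)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f0$coefficients[["(Intercept)"]] - 2, tolerance = 1e-6)
  expect_equal(f2$coefficients[-1], f0$coefficients[-1], tolerance = 1e-6)
})

test_that("non-integer and under-replicated inputs are rejected", {
  lay <- toy_layout()
  expect_error(fit_pair_glm(rep(1.5, 12), lay$gene, lay$tissue),
               "non-negative integers")
  expect_error(fit_pair_glm(rep(5L, 4), factor(rep(c("a", "b"), 2)),
                            factor(rep("t1", 4))), "2 tissues")
})

test_that("separation is flagged, not fatal", {
  lay <- toy_layout()
  y <- c(40, 45, 42, 50, 48, 52,   # gene1 expressed everywhere
         0, 0, 0, 47, 55, 49)      # gene2 silent in leaf
  fit <- fit_pair_glm(y, lay$gene, lay$tissue, dispersion = 0.05)
  expect_true(fit$near_boundary)
  ct <- contrast_tests(fit)
  # the LRT keeps its power where the Wald statistic collapses
  expect_lt(ct$p_G_by_T[["leaf"]], 1e-4)
  wd <- contrast_tests(fit, type = "wald")
  expect_gt(wd$p_G_by_T[["leaf"]], ct$p_G_by_T[["leaf"]])
})

test_that("Wald statistics in the Poisson limit match a hand-rolled IRLS", {
  # printed toy table: 2 genes x 2 tissues x 3 reps
  y <- c(12, 15, 11, 30, 28, 33,
         22, 25, 19, 31, 27, 35)
  lay <- toy_layout()
  fit <- fit_pair_glm(y, lay$gene, lay$tissue, dispersion = "poisson")
  X <- stats::model.matrix(~ gene * tissue,
                           data = data.frame(gene = lay$gene, tissue = lay$tissue))
  oracle <- irls_poisson(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle$coef), tolerance = 1e-6)
  expect_equal(unname(fit$vcov), unname(oracle$vcov), tolerance = 1e-6)
  # 1-df Wald for the gene effect in the reference tissue, from the oracle
  c_vec <- c(0, 1, 0, 0)
  z2 <- drop(c_vec %*% oracle$coef)^2 / drop(t(c_vec) %*% oracle$vcov %*% c_vec)
  p_oracle <- stats::pchisq(z2, 1, lower.tail = FALSE)
  wd <- contrast_tests(fit, type = "wald")
  expect_equal(unname(wd$p_G_by_T[["leaf"]]), p_oracle, tolerance = 1e-8)
})

test_that("the GLM recovers a planted ln(2) gene effect at high replication", {
  d <- simulation_design(n_pairs = 5, scenario_mix = c(G_only = 1),
                         effect_log2fc = 1, n_reps = 50, seed = 14)
  sim <- simulate_counts(d)
  pairs <- truth_pairs(sim$truth)
  sam <- sim$counts$samples
  for (i in 1:5) {
    # code gene2 first so the fitted gene contrast estimates log(mu1/mu2)
    y <- c(sim$counts$counts[pairs$gene2[i], ], sim$counts$counts[pairs$gene1[i], ])
    fit <- fit_pair_glm(y, rep(c("g1", "g2"), each = nrow(sam)),
                        rep(sam$tissue, 2))
    est <- mean(contrast_tests(fit)$gene_lfc_by_tissue)
    expect_lt(abs(est - log(2)), 0.1)
  }
})

test_that("interaction-only divergence is attributed to GxT, not G", {
  d <- simulation_design(n_pairs = 150, scenario_mix = c(GxT = 1), seed = 21)
  sim <- simulate_counts(d)
  g <- glm_divergence(sim$counts, truth_pairs(sim$truth))
  r <- g$results
  expect_gte(mean(r$q_GxT <= 0.05 & r$q_G > 0.05), 0.9)
})

test_that("category assignment enumerates all effect combinations", {
  q <- c(1, 0.01, 1, 1, 0.01, 0.01, 1, 0.01)
  t_ <- c(1, 1, 0.01, 1, 0.01, 1, 0.01, 0.01)
  i_ <- c(1, 1, 1, 0.01, 1, 0.01, 0.01, 0.01)
  expect_equal(as.character(assign_categories(q, t_, i_)),
               c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii"))
  expect_true(is.na(assign_categories(NA, 0.01, 0.01)))
})

test_that("categories partition the pairs and survive paralog relabeling", {
  d <- simulation_design(n_pairs = 40, seed = 37)
  sim <- simulate_counts(d)
  pairs <- truth_pairs(sim$truth)
  g <- glm_divergence(sim$counts, pairs)
  expect_equal(sum(table(g$results$category)), nrow(pairs))
  swapped <- data.frame(pair_id = pairs$pair_id, gene1 = pairs$gene2,
                        gene2 = pairs$gene1)
  g2 <- glm_divergence(sim$counts, swapped)
  expect_equal(as.character(g$results$category),
               as.character(g2$results$category))
  expect_equal(g$results$p_GxT, g2$results$p_GxT, tolerance = 1e-6)
  # complementary calls invariant too (dominant gene ids track the swap)
  expect_equal(g$complementary$pair_id, g2$complementary$pair_id)
  expect_equal(g$complementary$dominant_in_a, g2$complementary$dominant_in_a)
})

test_that("complementary detection follows dominance reversal exactly", {
  res <- data.frame(pair_id = c("p1", "p2", "p3", "p4"),
                    q_GbyT_petal = c(0.01, 0.01, 0.20, 0.01),
                    q_GbyT_leaf = c(0.01, 0.01, 0.01, 0.01),
                    prop1_petal = c(0.60, 0.70, 0.30, 0.50),
                    prop1_leaf = c(0.30, 0.80, 0.70, 0.30))
  calls <- detect_complementary(res, tissues = c("leaf", "petal"), fdr = 0.05)
  # p1: DE in both, dominance reversed -> called
  # p2: DE in both, gene1 dominant in both -> not called
  # p3: DE in one tissue only -> not called
  # p4: proportion exactly 0.5 -> no dominant paralog, no call
  expect_equal(calls$pair_id, "p1")
})

test_that("pooled ANOVA matches aov on a tiny balanced layout", {
  set.seed(7)
  v <- matrix(exp(rnorm(16, 4)), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  norm <- toy_norm(v, c("petal", "leaf"), n_reps = 2)
  pairs <- data.frame(pair_id = c("p1", "p2"), gene1 = c("g1", "g3"),
                      gene2 = c("g2", "g4"))
  got <- pooled_anova(norm, pairs)
  y <- log2(as.vector(v) + 0.5)
  dat <- data.frame(y = y,
                    gene = factor(rep(rownames(v), 4)),
                    tissue = factor(rep(c("petal", "petal", "leaf", "leaf"),
                                        each = 4)))
  ref <- summary(stats::aov(y ~ gene * tissue, data = dat))[[1]]
  expect_equal(got$df, ref$Df)
  expect_equal(got$sum_sq[1:3], ref$`Sum Sq`[c(1, 2, 3)], tolerance = 1e-8)
  expect_equal(got$sum_sq[4], ref$`Sum Sq`[4], tolerance = 1e-8)
  expect_equal(got$F[1:3], ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(got$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-8)
})

test_that("pooled ANOVA handles degenerate and incomplete designs", {
  v <- matrix(8, nrow = 2, ncol = 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  norm <- toy_norm(v, c("petal", "leaf"), n_reps = 2)
  pairs <- data.frame(pair_id = "p1", gene1 = "g1", gene2 = "g2")
  got <- pooled_anova(norm, pairs)
  expect_equal(got$sum_sq, rep(0, 4))
  expect_true(all(is.na(got$F)))
  # df structure: gene 2P-1, tissue T-1, interaction product, residual
  d <- simulation_design(n_pairs = 5, seed = 38)
  sim <- simulate_counts(d)
  a <- pooled_anova(upper_quartile(sim$counts), truth_pairs(sim$truth))
  expect_equal(a$df, c(9, 2, 18, 60))
})
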