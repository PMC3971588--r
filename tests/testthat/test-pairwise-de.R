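test_that("pair log ratios are exact and antisymmetric", {
  v <- rbind(g1 = c(20, 20, 20), g2 = c(10, 10, 10), g3 = c(20, 20, 20))
  colnames(v) <- paste0("s", 1:3)
  norm <- toy_norm(v, "petal")
  expect_equal(pair_log_ratios(norm, "g1", "g2", "petal", pseudocount = 0),
               rep(1, 3))
  expect_equal(pair_log_ratios(norm, "g1", "g3", "petal"), rep(0, 3))
  expect_equal(pair_log_ratios(norm, "g2", "g1", "petal", pseudocount = 0.5),
               -pair_log_ratios(norm, "g1", "g2", "petal", pseudocount = 0.5))
  expect_error(pair_log_ratios(norm, "g1", "nope", "petal"), "missing")
})

test_that("the log-ratio t-test matches its closed form", {
  expect_equal(pair_ttest(c(0, 0, 0)), list(t = 0, df = 2, p = 1,
                                            degenerate = FALSE))
  res <- pair_ttest(c(0.5, 1.0, 1.5))
  # closed form: t = mean / (sd/sqrt(n)); p from the df=2 Student CDF,
  # P(T <= t) = 1/2 + t / (2 sqrt(2) sqrt(1 + t^2/2))
  t_expect <- 1 / (0.5 / sqrt(3))
  p_expect <- 2 * (0.5 - t_expect / (2 * sqrt(2) * sqrt(1 + t_expect^2 / 2)))
  expect_equal(res$t, t_expect, tolerance = 1e-10)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$p, p_expect, tolerance = 1e-10)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$df, 2)
  deg <- pair_ttest(c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$q, bh_oracle(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(bh_adjust(rep(1, 5))$q, rep(1, 5))
  expect_false(any(bh_adjust(rep(1, 5))$reject))
  expect_equal(bh_adjust(0.03)$q, 0.03)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p)$q, bh_oracle(p))
  }
})

test_that("DE calls are invariant to paralog order within a pair", {
  d <- simulation_design(n_pairs = 40, seed = 31)
  sim <- simulate_counts(d)
  pairs <- truth_pairs(sim$truth)
  norm <- rpkm(sim$counts)
  de <- paralog_de(norm, pairs)
  swapped <- pairs
  names(swapped)[2:3] <- c("gene2", "gene1")
  de2 <- paralog_de(norm, swapped[, c("pair_id", "gene1", "gene2")])
  expect_equal(abs(de$t), abs(de2$t))
  expect_equal(de$q, de2$q)
  expect_equal(de$mean_log2_ratio, -de2$mean_log2_ratio)
  flip <- c(gene1_higher = "gene2_higher", gene2_higher = "gene1_higher",
            none = "none")
  expect_equal(de$direction, unname(flip[de2$direction]))
})

test_that("fold-change cells are nested and zero without divergence", {
  d <- simulation_design(n_pairs = 150, seed = 32)
  sim <- simulate_counts(d)
  de <- paralog_de(rpkm(sim$counts), truth_pairs(sim$truth))
  ft <- fold_change_table(de)
  expect_true(all(ft$fold_5 <= ft$fold_2))
  expect_true(all(ft$fold_2 <= ft$fold_1.5))
  # per-tissue counts never exceed the any-tissue row
  any_row <- ft[ft$tissue == "any_tissue", -1]
  for (ti in setdiff(ft$tissue, "any_tissue"))
    expect_true(all(ft[ft$tissue == ti, -1] <= any_row))
  # no significant pair -> all cells zero
  de0 <- de
  de0$q <- 1
  expect_true(all(fold_change_table(de0)[, -1] == 0))
})

test_that("strong planted gene effects land in the 5-fold cell", {
  d <- simulation_design(n_pairs = 500, scenario_mix = c(G_only = 1),
                         effect_log2fc = 3, seed = 15)
  sim <- simulate_counts(d)
  de <- paralog_de(rpkm(sim$counts), truth_pairs(sim$truth))
  ft <- fold_change_table(de)
  per_tissue <- ft$fold_5[ft$tissue != "any_tissue"]
  # the planted 8-fold effect always exceeds the fold threshold; the
  # binding constraint is BH significance of the 2-df t-test (~80% power
  # by simulation at these settings)
  expect_true(all(per_tissue / 500 >= 0.70))
  # with an 8-fold planted effect, most significant pairs also clear
  # 5-fold: the 5x cell stays close to the 1.5x cell
  expect_true(all(per_tissue >= 0.9 * ft$fold_1.5[ft$tissue != "any_tissue"]))
})

test_that("overlap summaries agree with brute-force set computation", {
  d <- simulation_design(n_pairs = 100, seed = 34)
  sim <- simulate_counts(d)
  de <- paralog_de(rpkm(sim$counts), truth_pairs(sim$truth))
  ov <- overlap_summary(de)
  fdr <- attr(de, "fdr")
  sets <- lapply(split(de, de$tissue), function(d)
    d$pair_id[!is.na(d$q) & d$q <= fdr])
  for (ti in names(ov$per_tissue))
    expect_equal(unname(ov$per_tissue[ti]), length(sets[[ti]]))
  for (k in seq_len(nrow(ov$pairwise)))
    expect_equal(ov$pairwise$n_both[k],
                 length(intersect(sets[[ov$pairwise$tissue_a[k]]],
                                  sets[[ov$pairwise$tissue_b[k]]])))
  expect_equal(ov$all_tissues, length(Reduce(intersect, sets)))
  expect_equal(ov$any_tissue, length(Reduce(union, sets)))
  # consistency: per-tissue >= pairwise >= triple
  expect_true(all(ov$pairwise$n_both <= min(ov$per_tissue) |
                    ov$pairwise$n_both <= max(ov$per_tissue)))
  expect_true(all(ov$all_tissues <= ov$pairwise$n_both))
  # cross-species mode and the universe check
  ov2 <- overlap_summary(de, de)
  expect_equal(unname(ov2$cross$per_tissue), unname(ov$per_tissue))
  expect_error(overlap_summary(de, de[de$pair_id != "pair00001", ]),
               "universe")
})

test_that("RPKM and UQ pipelines call nearly the same divergent pairs", {
  d <- simulation_design(n_pairs = 300, scenario_mix = c(null = 0.5, G_only = 0.5),
                         effect_log2fc = 3, seed = 35)
  sim <- simulate_counts(d)
  pairs <- truth_pairs(sim$truth)
  de_r <- paralog_de(rpkm(sim$counts), pairs)
  de_u <- paralog_de(upper_quartile(sim$counts), pairs)
  for (ti in unique(de_r$tissue)) {
    a <- de_r$pair_id[de_r$tissue == ti & !is.na(de_r$q) & de_r$q <= 0.05]
    b <- de_u$pair_id[de_u$tissue == ti & !is.na(de_u$q) & de_u$q <= 0.05]
    expect_gte(length(intersect(a, b)) / length(union(a, b)), 0.9)
  }
})

test_that("reciprocal silencing respects the inclusive 95% boundary", {
  # exact proportions: gene1 carries 95% in petal, 5% in leaf
  v <- rbind(g1 = c(95, 95, 95, 5, 5, 5),
             g2 = c(5, 5, 5, 95, 95, 95),
             g3 = c(96, 96, 96, 96, 96, 96),
             g4 = c(4, 4, 4, 4, 4, 4))
  colnames(v) <- paste0("s", 1:6)
  norm <- toy_norm(v, c("petal", "leaf"))
  pairs <- data.frame(pair_id = c("p1", "p2"), gene1 = c("g1", "g3"),
                      gene2 = c("g2", "g4"))
  de <- data.frame(pair_id = rep(c("p1", "p2"), 2),
                   tissue = rep(c("petal", "leaf"), each = 2),
                   q = 0.01)
  calls <- detect_reciprocal_silencing(norm, pairs, de, threshold = 0.95,
                                       fdr = 0.05)
  expect_equal(calls$pair_id, "p1")  # inclusive boundary: called
  expect_equal(calls$dominant_gene_in_a, "g1")
  expect_equal(calls$dominant_gene_in_b, "g2")
  # no reversal (g3 dominant in both): no call, even at 96%
  expect_false("p2" %in% calls$pair_id)
  # strictly over the boundary also called; under it not
  calls99 <- detect_reciprocal_silencing(norm, pairs, de, threshold = 0.96)
  expect_equal(nrow(calls99), 0)
})

test_that("silencing calls drop monotonically as the threshold rises", {
  d <- simulation_design(n_pairs = 200, seed = 36)
  sim <- simulate_counts(d)
  pairs <- truth_pairs(sim$truth)
  norm <- rpkm(sim$counts)
  de <- paralog_de(norm, pairs)
  n_calls <- vapply(c(0.90, 0.95, 0.99), function(th)
    nrow(detect_reciprocal_silencing(norm, pairs, de, threshold = th)), 0L)
  expect_true(all(diff(n_calls) <= 0))
})
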