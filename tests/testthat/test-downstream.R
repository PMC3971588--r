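test_that("rank-sum test matches exhaustive enumeration for small groups", {
  r <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p, 0.1)
  expect_equal(r$W, 6)
  expect_true(r$exact)
  set.seed(21)
  for (i in 1:30) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    a <- sample(1000, na); b <- sample(2000:3000, nb)  # no ties
    a <- a + runif(na); b <- b + runif(nb)
    got <- wilcoxon_compare(a, b)
    expect_equal(got$p, ranksum_oracle(a, b))
  }
})

test_that("rank-sum test is symmetric and handles degenerate groups", {
  set.seed(22)
  a <- rnorm(12); b <- rnorm(15) + 1
  expect_equal(wilcoxon_compare(a, b)$p, wilcoxon_compare(b, a)$p)
  # identical values in both groups: no shift detectable
  expect_gte(wilcoxon_compare(rep(1, 5), rep(1, 8))$p, 0.99)
  expect_error(wilcoxon_compare(numeric(), 1:3), "non-empty")
  # large-sample path agrees with wilcox.test's normal approximation
  big_a <- rnorm(40); big_b <- rnorm(45) + 0.3
  got <- wilcoxon_compare(big_a, big_b)
  ref <- stats::wilcox.test(big_a, big_b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("category comparison excludes undefined omega values", {
  glm_res <- data.frame(pair_id = paste0("p", 1:8),
                        category = factor(rep(c("i", "viii"), each = 4),
                                          levels = c("i", "ii", "iii", "iv",
                                                     "v", "vi", "vii", "viii")))
  dn <- data.frame(pair_id = paste0("p", 1:8),
                   omega = c(0.8, 0.7, 0.9, NA, 0.1, 0.2, 0.15, 0.12))
  expect_message(out <- category_wilcoxon(glm_res, dn), "excluded")
  expect_equal(out$n_a, 3)
  expect_equal(out$n_b, 4)
  expect_equal(out$p, ranksum_oracle(c(0.8, 0.7, 0.9), c(0.1, 0.2, 0.15, 0.12)))
})

test_that("positional binomial test matches closed-form tails", {
  # 10 pairs on one chromosome, all biased towards the located member
  pairs <- data.frame(pair_id = paste0("p", 1:10),
                      gene1 = paste0("a", 1:10), gene2 = paste0("b", 1:10),
                      chrom1 = "chr1", start1 = (1:10) * 1000,
                      end1 = (1:10) * 1000 + 500,
                      chrom2 = "chr2", start2 = (1:10) * 1000,
                      end2 = (1:10) * 1000 + 500)
  de <- data.frame(pair_id = paste0("p", 1:10), tissue = "petal",
                   direction = "gene1_higher")
  res <- positional_bias_test(de, pairs, window_size = 20)
  chr1 <- res[res$chrom == "chr1", ]
  expect_equal(chr1$n_pairs_in_window, 10)
  expect_equal(chr1$n_higher, 10)
  expect_equal(chr1$p, 2 * 0.5^10, tolerance = 1e-12)
  # the partner chromosome mirrors it: k <-> n - k, same p
  chr2 <- res[res$chrom == "chr2", ]
  expect_equal(chr2$n_higher, 0)
  expect_equal(chr2$p, chr1$p)
  # exact null center: 5 of 10 -> p = 1
  de$direction <- rep(c("gene1_higher", "gene2_higher"), 5)
  res50 <- positional_bias_test(de, pairs, window_size = 20)
  expect_equal(res50$p, rep(1, 2))
})

test_that("positional test controls false positives under the null", {
  # direction null: every pair's higher member is a fair coin, no
  # positional clustering planted
  set.seed(41)
  n <- 2000
  pairs <- data.frame(pair_id = sprintf("p%04d", 1:n),
                      gene1 = paste0("a", 1:n), gene2 = paste0("b", 1:n),
                      chrom1 = paste0("chr", rep(1:5, length.out = n)),
                      start1 = seq_len(n) * 1500,
                      chrom2 = paste0("chr", 5 + rep(1:5, length.out = n)),
                      start2 = seq_len(n) * 1500)
  pairs$end1 <- pairs$start1 + 1000; pairs$end2 <- pairs$start2 + 1000
  de <- data.frame(pair_id = pairs$pair_id, tissue = "petal",
                   direction = sample(c("gene1_higher", "gene2_higher"), n,
                                      replace = TRUE))
  res <- positional_bias_test(de, pairs, window_size = 20)
  expect_gt(nrow(res), 100)
  mc_se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lte(mean(res$significant), 0.05 + 3 * mc_se)
})
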