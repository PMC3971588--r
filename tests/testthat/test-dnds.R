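test_that("site counts match mutation-enumeration oracles", {
  expect_equal(count_sites("GGG"), c(S = 1, N = 2))
  code <- genetic_code()
  expect_equal(count_sites("ATG"), site_oracle("ATG", code))
  # every sense codon: counts match the oracle and S + N = 3
  sense <- names(code)[code != "*"]
  for (cod in sense) {
    got <- count_sites(cod)
    expect_equal(got, site_oracle(cod, code))
    expect_equal(unname(sum(got)), 3)
  }
  expect_warning(s <- count_sites("TAA"), "stop codon")
  expect_true(all(is.na(s)))
})

test_that("difference counts average over mutational pathways", {
  expect_equal(count_diffs("GGG", "GGG"), c(Sd = 0, Nd = 0))
  expect_equal(count_diffs("TTT", "TTC"), c(Sd = 1, Nd = 0))
  code <- genetic_code()
  # random sense-codon pairs against the explicit path-enumeration oracle
  sense <- names(code)[code != "*"]
  set.seed(11)
  n_checked <- 0
  for (i in 1:200) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    oracle <- suppressWarnings(diff_oracle(c1, c2, code))
    if (anyNA(oracle)) next
    got <- count_diffs(c1, c2)
    expect_equal(got, oracle)
    ndiff <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(unname(sum(got)), ndiff)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("Jukes-Cantor correction matches its closed form", {
  expect_equal(jukes_cantor(0)$d, 0)
  jc <- jukes_cantor(0.3)
  expect_equal(jc$d, -0.75 * log(1 - 0.4), tolerance = 1e-10)
  expect_equal(jc$d, 0.3831192, tolerance = 1e-6)
  expect_false(jc$saturated)
  expect_true(jukes_cantor(0.75)$saturated)
  expect_true(is.na(jukes_cantor(0.9)$d))
  # correction inflates: d >= p, equality only at zero
  for (p in seq(0.01, 0.7, by = 0.07))
    expect_gt(jukes_cantor(p)$d, p)
})

test_that("dN/dS on constructed alignments matches closed forms", {
  # identical sequences: zero rates, undefined omega
  s <- strrep("GGGACT", 30)
  same <- dnds(s, s)
  expect_equal(same$S_diffs + same$N_diffs, 0)
  expect_true(same$identical)
  expect_true(same$undefined_omega)
  # 100 GGG codons, one synonymous third-position change
  a <- strrep("GGG", 100)
  b <- paste0(strrep("GGG", 99), "GGA")
  res <- dnds(a, b)
  expect_equal(res$S_sites, 100)
  expect_equal(res$N_sites, 200)
  expect_equal(res$pS, 0.01)
  expect_equal(res$dS, -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-10)
  expect_equal(res$dS, 0.010067, tolerance = 1e-4)
  expect_equal(res$dN, 0)
  expect_equal(res$omega, 0)
  # symmetry under sequence swap
  pair <- simulate_codon_pair(120, 4, 6, seed = 12)
  f <- dnds(pair[["seq1"]], pair[["seq2"]])
  r <- dnds(pair[["seq2"]], pair[["seq1"]])
  expect_equal(f, r)
})

test_that("planted substitution classes are recovered exactly", {
  pair <- simulate_codon_pair(200, 5, 5, seed = 1)
  res <- dnds(pair[["seq1"]], pair[["seq2"]])
  expect_equal(res$S_diffs, 5)
  expect_equal(res$N_diffs, 5)
  set.seed(13)
  for (i in 1:100) {
    ns <- sample(0:4, 1); nn <- sample(0:4, 1)
    p <- simulate_codon_pair(30, ns, nn, seed = sample(1e6, 1))
    r <- dnds(p[["seq1"]], p[["seq2"]])
    expect_equal(r$S_diffs, ns)
    expect_equal(r$N_diffs, nn)
  }
})

test_that("gap and N codons are excluded pairwise without side effects", {
  a <- strrep("GGG", 10)
  b <- paste0(strrep("GGG", 9), "GGA")
  base <- dnds(a, b)
  # masking one clean codon removes its sites, nothing else
  a_gap <- sub("^GGG", "---", a)
  res <- dnds(a_gap, b)
  expect_equal(res$n_codons_used, 9)
  expect_equal(res$S_sites, base$S_sites - 1)
  expect_equal(res$S_diffs, base$S_diffs)
  a_n <- sub("^GGG", "GNG", a)
  expect_equal(dnds(a_n, b), res)
  # stop codons are skipped with a warning
  a_stop <- sub("^GGG", "TAA", a)
  expect_warning(res_stop <- dnds(a_stop, b), "stop")
  expect_equal(res_stop$n_codons_used, 9)
  expect_error(dnds("---", "GGG"), "no comparable codons")
  expect_error(dnds("GGGA", "GGGA"), "multiple of 3")
})

test_that("alignment FASTA files round-trip in pairs", {
  pairs <- list(pA = simulate_codon_pair(20, 1, 1, seed = 2),
                pB = simulate_codon_pair(20, 0, 2, seed = 3))
  pairs <- lapply(pairs, unname)
  path <- tempfile(fileext = ".fasta")
  write_codon_alignments(pairs, path)
  back <- read_codon_alignments(path)
  expect_equal(back, pairs)
  tab <- dnds_table(back)
  expect_equal(tab$pair_id, c("pA", "pB"))
  expect_equal(tab$S_diffs, c(1, 0))
  expect_equal(tab$N_diffs, c(1, 2))
})
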