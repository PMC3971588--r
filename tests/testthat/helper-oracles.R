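# Independent brute-force oracles used to pin down expected values.

# Benjamini-Hochberg step-up, written literally from the definition:
# sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, map back.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided rank-sum p-value by enumerating every assignment of the
# combined ranks to group A (no ties assumed)
ranksum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  sets <- utils::combn(na + nb, na)
  Ws <- colSums(matrix(seq_len(na + nb)[sets], nrow = na))
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# NG86 site counts by direct mutation enumeration (per-position
# renormalization over non-stop neighbours)
site_oracle <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      m <- codon
      substr(m, pos, pos) <- b
      if (code[[m]] == "*") next
      valid <- valid + 1
      if (code[[m]] == code[[codon]]) syn <- syn + 1
    }
    s <- s + if (valid > 0) syn / valid else 0
  }
  c(S = s, N = 3 - s)
}

# NG86 difference counts by explicit enumeration of all orderings of the
# differing positions, dropping stop-crossing paths
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms(v[-i]), function(r) c(v[i], r))))
}

diff_oracle <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  res <- NULL
  for (p in perms(pos)) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (k in p) {
      nxt <- cur
      substr(nxt, k, k) <- substr(c2, k, k)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res <- rbind(res, c(sd, nd))
  }
  if (is.null(res)) return(c(Sd = NA_real_, Nd = NA_real_))
  c(Sd = mean(res[, 1]), Nd = mean(res[, 2]))
}

# Poisson GLM by hand-rolled IRLS (log link), for Wald cross-checks
irls_poisson <- function(X, y, offset = rep(0, length(y))) {
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1))
  for (it in 1:100) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- mu
    z <- eta - offset + (y - mu) / mu
    XtWX <- t(X) %*% (W * X)
    new <- drop(solve(XtWX, t(X) %*% (W * z)))
    if (max(abs(new - beta)) < 1e-12) { beta <- new; break }
    beta <- new
  }
  eta <- drop(X %*% beta) + offset
  list(coef = beta, vcov = solve(t(X) %*% (exp(eta) * X)))
}

# a normalized_matrix with hand-chosen values: lengths 1000 bp and totals
# 1e6 make RPKM equal the raw count, so planted proportions are exact
toy_norm <- function(values, tissues, n_reps = 3) {
  samples <- data.frame(
    sample_id = colnames(values), species = "Gr",
    tissue = rep(tissues, each = n_reps), timepoint = NA,
    replicate = rep(seq_len(n_reps), length(tissues)))
  structure(list(values = values, method = "RPKM",
                 scale_factors = rep(1e6, ncol(values)),
                 gene_lengths = stats::setNames(rep(1000, nrow(values)),
                                                rownames(values)),
                 samples = samples),
            class = "normalized_matrix")
}
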