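# Nei-Gojobori (1986) site/difference counting with Jukes-Cantor correction.
# Site and pathway tables are enumerated once from the standard genetic code
# and cached in the package namespace.

.dnds_env <- new.env(parent = emptyenv())

#' Standard genetic code as a named vector
#'
#' Codon (DNA alphabet) to one-letter amino acid, `*` for stop; translation
#' table 1 from Biostrings.
#'
#' @return named character vector of length 64.
#' @export
genetic_code <- function() {
  if (is.null(.dnds_env$code)) {
    code <- Biostrings::GENETIC_CODE
    names(code) <- chartr("U", "T", names(code))
    .dnds_env$code <- code
  }
  .dnds_env$code
}

.bases <- c("A", "C", "G", "T")

site_table <- function() {
  if (!is.null(.dnds_env$sites)) return(.dnds_env$sites)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  tab <- t(vapply(sense, function(cod) {
    aa <- code[[cod]]
    s <- 0
    for (pos in 1:3) {
      muts <- vapply(setdiff(.bases, substr(cod, pos, pos)), function(b) {
        m <- cod; substr(m, pos, pos) <- b; code[[m]]
      }, "")
      valid <- muts[muts != "*"]
      # renormalize over non-stop neighbours so every sense codon carries
      # 3 sites; a position with only stop neighbours cannot occur for
      # sense codons in the standard code
      s <- s + if (length(valid)) sum(valid == aa) / length(valid) else 0
    }
    c(S = s, N = 3 - s)
  }, c(S = 0, N = 0)))
  .dnds_env$sites <- tab
  tab
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Per position, the synonymous fraction is the share of single-nucleotide
#' neighbours that preserve the amino acid, computed over non-stop
#' neighbours; nonsynonymous sites are the complement, so every sense codon
#' contributes 3 sites in total.
#'
#' @param codon 3-letter DNA codon.
#' @return named numeric `c(S = ..., N = ...)`; `NA`s with a warning for a
#'   stop codon.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  code <- genetic_code()
  if (!codon %in% names(code)) stop("not a codon: ", codon)
  if (code[[codon]] == "*") {
    warning("stop codon skipped: ", codon)
    return(c(S = NA_real_, N = NA_real_))
  }
  site_table()[codon, ]
}

# all orderings of the differing positions between two codons
path_orders <- function(pos) {
  if (length(pos) == 1) return(list(pos))
  if (length(pos) == 2) return(list(pos, rev(pos)))
  do.call(c, lapply(seq_along(pos), function(i)
    lapply(path_orders(pos[-i]), function(rest) c(pos[i], rest))))
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Counts differences by averaging over all minimal mutational pathways
#' between the codons (1, 2 or 6 orderings for 1, 2 or 3 differing
#' positions). Each pathway step is classified synonymous if it preserves
#' the amino acid; pathways passing through a stop codon are excluded and
#' the average renormalized over the remaining pathways.
#'
#' @param codon1,codon2 sense codons.
#' @return named numeric `c(Sd = ..., Nd = ...)`; their sum equals the
#'   number of differing positions. `NA`s with a warning when every pathway
#'   crosses a stop codon.
#' @export
count_diffs <- function(codon1, codon2) {
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  code <- genetic_code()
  if (code[[codon1]] == "*" || code[[codon2]] == "*")
    stop("count_diffs requires sense codons")
  pos <- which(strsplit(codon1, "")[[1]] != strsplit(codon2, "")[[1]])
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  paths <- path_orders(pos)
  acc <- matrix(NA_real_, length(paths), 2)
  for (k in seq_along(paths)) {
    cur <- codon1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in paths[[k]]) {
      nxt <- cur; substr(nxt, p, p) <- substr(codon2, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc[k, ] <- c(sd, nd)
  }
  valid <- !is.na(acc[, 1])
  if (!any(valid)) {
    warning("all mutational pathways between ", codon1, " and ", codon2,
            " cross a stop codon; codon pair skipped")
    return(c(Sd = NA_real_, Nd = NA_real_))
  }
  c(Sd = mean(acc[valid, 1]), Nd = mean(acc[valid, 2]))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` for an observed proportion of differences
#' `p`; the formula saturates at `p = 0.75`.
#'
#' @param p observed proportion of differences per site, in `[0, 0.75)`.
#' @return list with `d` (the corrected distance, `NA` when saturated) and
#'   `saturated`.
#' @export
jukes_cantor <- function(p) {
  if (p < 0) stop("p must be >= 0")
  if (p >= 0.75) return(list(d = NA_real_, saturated = TRUE))
  list(d = -0.75 * log(1 - 4 * p / 3) + 0, saturated = FALSE)  # + 0 avoids -0
}

#' dN/dS for one aligned codon pair
#'
#' Nei-Gojobori counting over an aligned CDS pair: codons containing a gap
#' or N in either sequence are excluded pairwise; codons where either
#' sequence holds a stop are skipped with a warning. Site counts are
#' averaged over the two sequences; `pN = Nd/N`, `pS = Sd/S`; `dN` and `dS`
#' apply the Jukes-Cantor correction; `omega = dN/dS` when `dS > 0`.
#'
#' @param seq1,seq2 aligned nucleotide strings of equal length, a multiple
#'   of 3; alphabet `A C G T - N`.
#' @param pair_id identifier carried into the result.
#' @return one-row data.frame: `pair_id`, `n_codons_used`, `S_sites`,
#'   `N_sites`, `S_diffs`, `N_diffs`, `pS`, `pN`, `dS`, `dN`, `omega` and
#'   flags `identical`, `saturated_dS`, `saturated_dN`, `undefined_omega`.
#' @export
dnds <- function(seq1, seq2, pair_id = "pair") {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("aligned sequences must have equal length")
  if (nchar(seq1) %% 3 != 0) stop("alignment length must be a multiple of 3")
  starts <- seq(1, nchar(seq1), by = 3)
  c1 <- substring(seq1, starts, starts + 2)
  c2 <- substring(seq2, starts, starts + 2)
  clean <- !grepl("[-N]", c1) & !grepl("[-N]", c2)
  c1 <- c1[clean]; c2 <- c2[clean]
  code <- genetic_code()
  is_stop <- code[c1] == "*" | code[c2] == "*"
  if (any(is_stop)) {
    warning(sum(is_stop), " codon(s) containing a stop skipped")
    c1 <- c1[!is_stop]; c2 <- c2[!is_stop]
  }
  if (!length(c1)) stop("no comparable codons after filtering")

  st <- site_table()
  S <- sum((st[c1, "S"] + st[c2, "S"]) / 2)
  N <- sum((st[c1, "N"] + st[c2, "N"]) / 2)
  diffs <- mapply(count_diffs, c1, c2)
  used <- !is.na(diffs[1, ])
  Sd <- sum(diffs[1, used]); Nd <- sum(diffs[2, used])

  pS <- Sd / S; pN <- Nd / N
  jc_s <- jukes_cantor(pS); jc_n <- jukes_cantor(pN)
  undef <- is.na(jc_s$d) || jc_s$d == 0
  data.frame(pair_id = pair_id, n_codons_used = sum(used),
             S_sites = S, N_sites = N, S_diffs = Sd, N_diffs = Nd,
             pS = pS, pN = pN, dS = jc_s$d, dN = jc_n$d,
             omega = if (!undef && !is.na(jc_n$d)) jc_n$d / jc_s$d else NA_real_,
             identical = Sd + Nd == 0,
             saturated_dS = jc_s$saturated, saturated_dN = jc_n$saturated,
             undefined_omega = undef, stringsAsFactors = FALSE)
}

#' dN/dS over a set of aligned pairs
#'
#' @param alignments named list of two-sequence character vectors, e.g. from
#'   [read_codon_alignments()].
#' @return data.frame with one [dnds()] row per pair.
#' @export
dnds_table <- function(alignments) {
  rows <- lapply(names(alignments), function(id)
    dnds(alignments[[id]][1], alignments[[id]][2], pair_id = id))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
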