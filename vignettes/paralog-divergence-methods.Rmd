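---
title: "Methods: expression and sequence divergence of ancient WGD paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression and sequence divergence of ancient WGD paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

After a whole-genome duplication (WGD), every gene exists in (at least) two
copies. Most duplicates are lost; the interesting question is what keeps the
survivors. Two regulatory routes are commonly invoked: subfunctionalization,
where the ancestral expression domain is partitioned between the copies
(each copy becomes necessary somewhere), and neofunctionalization, where one
copy acquires a new expression domain. Both leave a measurable footprint in
RNA-seq data: the two paralogs of a pair stop being expressed at the same
level, in a way that can depend on tissue.

`paleodup` implements a complete desk-scale version of such an analysis for
paralog pairs retained from an ancient (~60 My) polyploidy event in a diploid
cotton relative, measured in three tissues (petal, leaf, seed) with three
biological replicates each, plus the comparative-genomics step that defines
the pair set and the molecular-evolution step (dN/dS) that asks whether
expression divergence tracks protein-level selection.

Because the original read data live in external archives, the package ships a
first-class synthetic-data module that emulates the statistical structure of
the study and plants known truth. Every stage of the pipeline is exercised
and tested against that truth or against closed-form/brute-force oracles.

## Strictly duplicated pairs from synteny

The pair set is defined comparatively. The focal genome carries duplicated
syntenic regions; two outgroup genomes that do not share the WGD carry each
region once. A pair is *strictly duplicated* when

1. its two members are anchors of a focal-genome collinear block spanning two
   duplicated regions,
2. both members map to one and the same single syntenic region in outgroup 1,
   and
3. likewise in outgroup 2.

`call_strict_duplicates()` consumes precomputed collinearity anchor tables
(block detection is upstream tooling) and applies this 2:1:1 filter. "Single
region" is operationalized as block-ID equality, the only machine-checkable
reading. Genes occurring in more than two focal-genome copies (triplicates),
genes whose outgroup ortholog occupies two regions, and tandem anchors inside
one block are excluded. Pairs are canonically ordered (`gene1 < gene2`), and
the caller is deterministic. On fixtures from `simulate_synteny_fixture()` —
which plants strict pairs among exactly these decoy classes — recovery is
exact (precision = recall = 1), which is the designed behaviour, not a
statistical achievement: the filter is a set operation.

## Normalization

Two normalizations are implemented:

* **RPKM**: `count * 1e9 / (length_bp * total_mapped_reads)` — comparisons
  between the members of a pair additionally benefit from length effects
  cancelling when the two gene models have similar length.
* **Upper quartile (UQ)**: each sample is scaled by the 75th percentile of
  its nonzero counts. The free global constant is fixed as the geometric
  mean of the per-sample factors, so normalized values keep a count-like
  magnitude and are stable under taking sample subsets.

The per-pair GLM does not consume normalized values: negative-binomial
likelihoods need counts, so the UQ size factors enter as log offsets, which
is the model-based equivalent of dividing by them.

## Per-pair, per-tissue differential expression

Both paralogs are quantified in the same libraries, so within a replicate
the log ratio

    r = log2((x1 + c) / (x2 + c))

cancels library-wide effects; a pseudocount `c = 0.5` keeps ratios finite
while preserving antisymmetry under paralog swap. A one-sample two-sided
Student t-test of the replicate ratios against 0 (df = n - 1 = 2 at three
replicates) tests equal expression, assuming the ancestral state of equal
expression after duplication. Benjamini–Hochberg correction is applied per
tissue across pairs, since tissues are reported separately. Pairs in which
both members fall below a floor of mean normalized expression 1 in a tissue
are not tested there (ratios of noise around zero are meaningless); log base
2 is used throughout so fold thresholds (1.5/2/5) convert cleanly.

Two small-sample properties matter for interpretation and are worth stating
explicitly because the test suite exercises both:

* A zero-variance ratio vector is degenerate. All-zero ratios give `t = 0,
  p = 1`; a nonzero constant is flagged (`degenerate_variance`) and reported
  with `p = 0`.
* At df = 2 the attainable p-value has a heavy floor (`p ~ 1/t^2`), so the
  BH step-up threshold depends strongly on the composition of the family:
  in a family dense with strong effects the staircase catches and most true
  effects are declared; in a sparser family it can collapse and reject very
  little, even at identical per-pair power. This is correct behaviour of BH
  with few replicates, and it is the reason the per-pair GLM below — whose
  chi-square p-values have no such floor — is the primary classification
  engine.

## Reciprocal silencing and complementary expression

*Reciprocal silencing* is the extreme subfunctionalization pattern: among
pairs differentially expressed in both compared conditions, one member
carries at least 95% of the pair total (replicate-mean normalized
expression) in one condition and at most 5% in the other, boundaries
inclusive. The threshold is exposed (`detect_reciprocal_silencing()`), and
call counts are monotone non-increasing in it.

The differential-expression precondition makes the detector's positive set
conditional: a planted silenced pair that does not clear BH significance in
both conditions (common at three replicates, see the p-value floor above) is
not eligible. Within the eligible set, detection of the planted pattern is
exact, and null pairs are never called — the test suite and acceptance
script measure exactly these two quantities plus the eligible fraction.

*Complementary expression* relaxes silencing: the pair must be
differentially expressed within both tissues of a comparison (per-tissue
GLM contrasts, below) with the dominant member (estimated expression share
> 0.5) reversed between them. A share of exactly 0.5 names no dominant
member and blocks the call. Because the detector consumes estimated
significance, a null pair that happens to be a false positive in both
tissues (expected at the per-family FDR, about one pair per several hundred)
is called with reversed estimated dominance; exact agreement with planted
truth holds up to that irreducible set.

## The per-pair negative-binomial GLM

For one pair, counts of both genes across tissues and replicates are
modelled as

    y ~ NB(mu, phi),   log mu = b0 + gene + tissue + gene:tissue + offset

with reference coding (gene 1, alphabetically first tissue), variance
`mu + phi * mu^2`, and offsets `log(UQ size factor)`. The dispersion `phi`
is estimated per pair by maximum likelihood with a floor at `1e-8`; when the
MLE sits at the equidispersion boundary or the NB fit fails, the fit falls
back to Poisson (`phi = 0`) and is flagged (`boundary_dispersion`). No
information is shared across pairs — with ~12,000 observations behind each
family-wise decision the plain per-pair estimate is adequate, at the cost of
mildly liberal raw p-values that the per-family BH correction absorbs (the
complete-null simulation keeps each effect family at or below the nominal
level after correction).

Four hypotheses are tested per pair:

* **G** (1 df): the gene contrast averaged over tissues — do the paralogs
  differ in mean expression combined across tissues?
* **T** (T−1 df): does the pooled-paralog mean differ between any two
  tissues? (tissue main effects evaluated at the midpoint of the two genes)
* **G×T** (T−1 df): all interaction terms jointly — is the paralog
  difference tissue-dependent? This is the signature of regulatory sub-/
  neofunctionalization.
* **G|T** (1 df each): the gene difference within each tissue.

**Test statistic.** The default is a likelihood-ratio test at the full-model
dispersion: for an arbitrary contrast matrix `C`, the design is
reparameterized so the rows of `C` become coordinates, the constrained model
drops those columns, and twice the deviance difference is referred to a
chi-square. The Wald statistic (`type = "wald"`) is also provided and is the
one cross-checked against a hand-rolled Poisson IRLS oracle in the tests —
but it is *not* the default, because with three replicates a gene can be
entirely unobserved in a tissue (separation), the fitted coefficient runs to
the boundary, its standard error diverges, and the Wald statistic collapses
towards zero precisely where the effect is strongest (the Hauck–Donner
effect; in the all-effects simulation it cost a third of the category-viii
assignments). The LRT is immune to this failure mode and costs only a few
extra IRLS fits per pair.

BH correction is applied within each effect family across pairs (the G|T
family per tissue). Every pair then falls in exactly one of eight exclusive
categories given by its significant effects: i = none, ii = G, iii = T,
iv = G×T, v = G+T, vi = G+G×T, vii = T+G×T, viii = G+T+G×T. Categories are
invariant to paralog relabelling and partition the pair set.

The pooled two-way ANOVA over all pairs (gene with 2×P levels, tissue,
interaction) is a classical fixed-effects Gaussian ANOVA of log2 UQ
normalized values, computed by direct mean decomposition — with ~4,000 gene
levels a dense `lm()` design matrix is needlessly expensive, and the direct
decomposition is exact for the balanced designs this analysis uses (missing
cells are an error). `aov()` on a small layout is the oracle in the tests.

## dN/dS

Site and difference counting follows the Nei–Gojobori (1986) scheme under
the standard genetic code:

* **Sites**: per codon position, the synonymous fraction is the share of
  single-nucleotide neighbours preserving the amino acid, computed over
  non-stop neighbours (mutations to stops are excluded and the fraction
  renormalized over the rest), so every sense codon carries exactly 3 sites.
  Site totals are averaged over the two sequences.
* **Differences**: averaged over all minimal mutational pathways between two
  codons (1, 2, or 6 orderings), classifying each step as synonymous or not;
  pathways through stop codons are dropped and the average renormalized.
* **Correction**: `d = -(3/4) ln(1 - 4p/3)` (Jukes–Cantor) applied to
  `pN = Nd/N` and `pS = Sd/S`; `p >= 0.75` sets a saturation flag rather
  than producing infinities, `dS = 0` flags omega as undefined.

Codons containing a gap or N in either sequence are excluded pairwise, which
is deterministic and leaves all other codons' contributions unchanged.
`simulate_codon_pair()` builds alignments from fourfold-degenerate codon
families with a pyrimidine third base, so the planted synonymous (third
position) and nonsynonymous (second position) single-nucleotide changes are
unambiguous and NG86 recovers them exactly — the generator/counter
cross-check in the tests is exact over a thousand random fixtures.

## Downstream comparisons

Omega distributions between categories are compared with the two-sample
Wilcoxon rank-sum test (`W` = rank sum of the first group; exact null via
the Mann–Whitney distribution when the smaller group has at most 10 values
and no ties, otherwise normal approximation with tie and continuity
correction). A paired signed-rank test would be undefined here: the category
groups contain different pairs and differ in size. Pairs with undefined
omega (`dS = 0`) are excluded and counted.

Positional bias — whether duplicates in a chromosomal region tend to be
over- or under-expressed relative to their partners — is tested per tissue
in sliding windows of 20 consecutive pair-member genes with 50% overlap
(window size configurable; "region" is not otherwise defined), two-sided
exact binomial tests against 0.5 on the members with a significant
direction, BH-corrected across windows within a tissue.

## The synthetic-data generator

`simulate_counts()` draws NB counts with mean
`baseline * 2^(planted effects) * (length/1e3) * (lib_size/1e6)`; the two
members of a pair split a common pair total so planted log2 ratios are
exact, and share one gene length so length never mimics expression
divergence. Defaults follow the study design where stated — three tissues,
three replicates — and otherwise use values a practitioner would call
realistic for bulk RNA-seq, fixed once:

* dispersion `phi = 0.05` (typical for biological replicates);
* library sizes 200k–400k, a 100× scale-down of 20–40 M mapped reads that
  keeps test runtimes in seconds while preserving counting noise at the
  per-gene level relevant here;
* per-pair baseline expression log-normal (`meanlog = log 100`,
  `sdlog = 1`), gene lengths uniform on 300–3000 bp;
* planted gene and interaction effects of 2 on the log2 scale ("strong" but
  not silencing-scale);
* the silencing scenario plants a 99%/1% split (safely beyond the 95% rule),
  the complementary scenario 80%/20% (reversal without silencing).

Scenario labels are drawn multinomially from a configurable mix. Two
generator choices deserve a note. First, scenarios with reversed dominance
between the first two tissues (G×T, silencing, complementary) are all
recorded as planted-complementary, since the detector's definition does not
require silencing. Second, the tissue-shift pattern of the all-effects
scenario is permuted per pair: if every pair carried the same tissue shift,
the planted "tissue effect" would move the whole transcriptome and be
absorbed — correctly — by normalization, making the truth unrecoverable by
any valid method.

What the generator does **not** emulate: mapping bias and multireads, the
SNP-index correction used for cross-species read assignment, GC/length
biases within a pair, correlated dispersion across tissues,
allopolyploid homeolog expression, or any coupling between expression
category and substitution load (so downstream category comparisons of omega
are expected null unless the user plants otherwise). Passing tests on
synthetic data therefore validate the statistical machinery and its
bookkeeping, not the upstream read processing of a real experiment.

## Problem sizes and numerical choices

The test suite and acceptance script run at: 10,000 pairs for the type-I
error of the log-ratio test (the rejection rate at alpha = 0.05 must lie in
0.05 ± 0.01); 500–1,000 pairs for GLM category power and null calibration
(at least 90% of all-effects pairs in category viii; at least ~93% of null
pairs in category i); 400 pairs for the silencing/complementary checks; ten
pairs at 50 replicates for parameter recovery (planted ln 2 gene effect
within ±0.1); 1,000 random codon fixtures for exact substitution-class
recovery. The analysis scripts under `analysis/` use 1,971 pairs, matching
the scale of the pair set the design emulates. All generators restore the
caller's RNG state and are byte-reproducible under a fixed seed, as are
both full pipeline runs compared in the determinism check.

## Known limitations

* Per-pair ML dispersion at three replicates is biased low, making raw GLM
  p-values liberal; per-family BH absorbs this at the 5% level but raw
  p-values should not be interpreted singly.
* The df = 2 t-test's p-value floor makes per-tissue BH outcomes sensitive
  to family composition (see above); fold-change tables inherit this.
* The silencing detector is conditional on DE eligibility by definition;
  its unconditional sensitivity at three replicates is far below 1 and is
  reported as such.
* The strictness filter trusts the anchor tables; internal rearrangements
  within duplicated blocks are handled by dropping ambiguous genes, not by
  resolving them.
* Time-point series are treated as conditions, exactly like tissues; no
  longitudinal model is attempted.
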