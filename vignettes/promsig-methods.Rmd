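---
title: "Methods: promoter regulatory signatures with promsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter regulatory signatures with promsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promsig)
```

## The analysis

`promsig` asks whether treatment-defined gene expression programmes carry a
transcription-factor binding-site (TFBS) signature in their promoters. The
motivating design is a cultured-cell experiment with four states — control,
two growth-factor treatments (call them A and B, e.g. TGF&beta; and CCN2)
and the co-treatment AB — profiled on expression arrays with three
replicates per state. The pipeline runs in five stages.

**1. Treatment-defined gene sets.** Each treatment is contrasted against
control per gene with a two-sample t-test on log2 expression and
Benjamini–Hochberg (BH) control at `alpha = 0.05` across the genes of the
contrast. The "modified" t-statistic used by small-replicate array studies
is under-determined; `differential_expression()` therefore defaults to the
Welch test and exposes a `moderated` mode in which each gene's pooled
variance is shrunk toward the global mean pooled variance with a fixed
prior weight (`prior_df`, default 4 pseudo-observations). We make no claim
that either mode reproduces any particular published gene list — the
underlying array data are not public — only that both are defensible
instances of the same testing role. The three significant sets feed
`venn_partition()`, whose seven disjoint regions include the key
"regulated by the combination but by neither factor alone" set.

**2. Promoter scanning.** Binding models are position frequency matrices
(PFMs) normalized by `normalize_pfm()` with a background-weighted
pseudocount (default 0.8, the conventional small-sample correction; split
by the background so columns stay proper distributions). A window of width
$W$ scores $\sum_{j=1}^{W} \log_2 f_j(b_j)/\pi(b_j)$, and the *relative*
score rescales this between the worst and best attainable scores into
$[0,1]$. The scan threshold of **0.85 relative score** is the canonical
matrix-similarity cut-off of the promoter-scanning literature, and is the
only reading under which a unitless "0.85" matrix threshold makes sense;
it is exposed as `threshold` everywhere. Both strands are scanned by
default (strandedness of the original analysis is unknowable; a
`both_strands` flag is provided), all overlapping hits are counted (no
collapsing rule is assumed), `N` bases score zero log-odds, and a
degenerate matrix whose best and worst scores coincide is defined to score
1 (such motifs never enter generated libraries). Hits against the short
(500 bp) upstream window, binarized to presence/absence, form the
genes &times; motifs **motif/gene matrix**.

**3. Co-inertia analysis (CIA).** The motif/gene matrix $X$ is coupled to
a gene-set membership table $Y$ (indicator columns for the up- and
down-regulated co-treatment sets) over the regulated genes. Both tables
are column-centered under uniform row weights $D = \mathrm{diag}(1/n)$ and
the cross-product $Z = X^\top D Y$ is decomposed by SVD; singular values
are the covariances achievable by paired axes and $\sum_i \lambda_i^2$ is
the total co-inertia. We deliberately use plain centered tables
(PCA-style duality) rather than correspondence analysis: a binary
presence/absence matrix has no profile interpretation for CA to exploit.
Global association is summarized by the RV coefficient
$\mathrm{tr}(C_{xy}C_{yx}) / \sqrt{\mathrm{tr}(C_{xx}^2)\,
\mathrm{tr}(C_{yy}^2)}$ and tested by permuting the rows of $Y$
(`permutation_test_global()`).

**4. Representation calls.** Which motifs drive the coupling is decided
per motif by `motif_representation()`: the statistic is the difference in
presence rate between a query set and the rest of a universe, with a
membership-relabelling permutation p-value (two-sided, add-one smoothed,
ties counted toward the null) and an exact hypergeometric tail p-value as
a cross-check; BH is applied across the motif library and both raw and
adjusted significance are reported. The universe is a free argument; in
the packaged end-to-end analysis (`analyze_study()`) the query is the
up-regulated co-treatment set against the universe of all regulated
(up &cup; down) genes, i.e. over-representation is judged against the
regulated background rather than the whole array. This choice targets the
scientific question — which sites distinguish induced from repressed
genes within the responsive programme — and gives the statistic usable
power at realistic set sizes.

**5. Focal-TFBS stratification.** `subset_by_go()` selects genes whose
annotation text contains a query term (default `"actin"`,
case-insensitive substring match, mirroring a free-text GO search; an
exact-match mode exists). For that subset, CREB-like and E2F1-like site
counts in the long (5000 bp) window are laid against the co-treatment
log2 fold change. The original observation was graphical; to make it
assertable `stratify()` computes, per motif, the Spearman correlation
between counts and fold change (fold-change-shuffling permutation p) and
the up-minus-down mean count difference (label-permutation p; genes with
fold change exactly 0 are excluded from the two-group test, having no
direction).

## The synthetic-study generator

No array data or motif library accompany the motivating study, so
validation rests on `generate_study()`, which plants known structure:

* **Design:** 4 conditions &times; 3 replicate arrays, 1000 genes — the
  stated study design. Expression is simulated at the gene level on the
  log2 scale (per-gene baseline $\mathcal N(8, 1.5^2)$, replicate noise
  sd 0.25); probe-level effects and normalization artefacts are out of
  scope.
* **Effects:** 100 genes up- and 100 down-regulated by ±2 log2 units in
  the co-treatment only. The size/effect values are the package's fixed
  reference scenario: ±2 at sd 0.25 with n = 3 puts per-gene power high
  but not saturated, so recovery is informative.
* **Promoters:** i.i.d. bases with a GC parameter (default 0.45, a
  typical promoter-region figure). The simplest null consistent with
  PWM log-odds scoring; real promoters have CpG islands, repeats and
  dinucleotide structure that this model deliberately omits.
* **Planting:** an E2F1-like motif in the up group and a CREB-like motif
  in the down group, each at rate 0.8 inside the group and 0.1 outside,
  plus 50 unplanted decoy motifs (widths 6–12, per-column information
  0.8–1.6 bits). Planting *replaces* bases at a uniform position inside
  the TSS-proximal 500 bp — so both window classes carry the signal and
  the coordinate frame stays fixed — and each selected gene receives one
  site per call. The focal models are synthetic 12-bp consensus-dominated
  matrices embedding the CRE palindrome (TGACGTCA) and the E2F core
  (TTTCGCGC); they are stand-ins, not database matrices, and real PFMs
  can be supplied through `read_pfm()`.
* **Annotation:** a fifth of genes, drawn from every effect group, carry
  an "actin cytoskeleton organization" term; all other terms avoid the
  substring "actin" so the subset is exactly recoverable.

Everything is a deterministic function of one integer seed (verified by
byte-identity tests); the `truth` component is consumed only by tests,
never by analysis code. Passing recovery tests on this generator shows
the machinery detects signals of the planted kind at the planted
strength; it does not certify performance on real promoters, whose
background composition, motif co-occurrence and annotation noise are all
richer.

## Numerical choices

* Window scores accumulate in extended precision in the compiled scanner,
  matching R's `sum()`, so scan results are bit-reproducible against a
  naive re-scorer.
* Hit retention uses `relative >= threshold - 1e-9`, so exact-consensus
  windows survive a threshold of 1.0 despite floating-point summation.
* All permutation p-values are add-one smoothed, $(1 + \#\{T^* \ge T\}) /
  (B + 1)$, never 0; two-sided p-values double the smaller tail and cap
  at 1; ties count toward the null (conservative).
* Degenerate cases are defined, not errors: identical groups give
  $t = 0, p = 1$; noiseless separated groups fall back to an epsilon
  variance and come out significant; all-identical site counts report
  $\rho = 0, p = 1$ with a degenerate flag; fold-change ties order
  lexicographically by gene id; a fold change of exactly 0 classifies as
  "up" where a direction is forced (probability 0 under continuous
  noise).
* `coinertia()` truncates the requested axes to the rank of $Z$ with a
  message. Genes lacking a promoter sequence are dropped with a warning,
  never imputed as zero rows, which would bias representation statistics.

## Default problem sizes

The shipped tests exercise the scanner against a naive per-position
oracle on 100 random 1 kb sequences &times; 10 random matrices (exact
agreement), the CIA decomposition against a dense eigendecomposition on
20 small table pairs (tolerance 1e-8), permutation calibration on 500
null runs at 199 permutations (rejection rate required within
[0.03, 0.08] at &alpha; = 0.05), and the full planted scenario over 20
seeds at 1999 permutations. These sizes were chosen to make the binomial
error of each check small relative to its acceptance band while keeping
the default suite fast on one core.

## Limitations

* The motif library, promoter source (genome build, TSS definitions) and
  exact test flavour of the motivating study are unrecorded; the package
  treats all three as inputs and makes no claim of reproducing its
  printed TFBS counts or gene lists.
* Substring GO matching is a text search, not ontology traversal; no
  is-a closure is computed.
* CIA is reported descriptively (loadings, RV, global permutation p);
  per-motif inference rests on the set-vs-background permutation test,
  whose calibration is verified, rather than on axis loadings.
* The two-group stratification test conditions on the observed up/down
  split; with very unbalanced splits the Spearman statistic is the more
  stable of the two.
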