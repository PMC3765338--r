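# promsig

Promoter regulatory-signature analysis: which transcription-factor
binding sites (TFBSs) distinguish the genes a treatment switches on from
the genes it switches off?

`promsig` is built for the common design in growth-factor biology where
cells are profiled under a control, two single treatments and their
combination (e.g. TGFβ, CCN2 and both together), and the co-treatment
induces an expression programme that neither factor produces alone. The
package turns that design into a tested pipeline:

1. **Gene sets** — per-treatment differential expression versus control
   (Welch or moderated t-test, Benjamini–Hochberg control at *p* < 0.05)
   and the three-set Venn partition, including the co-treatment-unique
   region.
2. **Promoter scanning** — position weight matrices scored over 500 bp
   upstream windows on both strands; a window of width *W* scores
   ∑ⱼ log₂ *f*ⱼ(*b*ⱼ)/π(*b*ⱼ), min–max normalized to a relative score in
   [0, 1] and thresholded at the conventional 0.85, giving the binary
   genes × motifs **motif/gene matrix**.
3. **Co-inertia analysis (CIA)** — the motif/gene matrix *X* is coupled
   to gene-set membership *Y* by SVD of *Z* = *X*ᵀ*DY* (uniform row
   weights *D*); global association is the RV coefficient
   tr(*C*ₓᵧ*C*ᵧₓ)/√(tr(*C*ₓₓ²)·tr(*C*ᵧᵧ²)) with a row-permutation test,
   and per-motif over/under-representation is called by a set-membership
   permutation test with an exact hypergeometric cross-check.
4. **Stratification** — for a GO-defined subset (default: genes whose
   annotation contains "actin"), CREB-like and E2F1-like site counts in
   the 5000 bp upstream window are tested against co-treatment log2 fold
   change (Spearman ρ and an up-vs-down mean-count difference, both with
   permutation p-values).

Because studies of this kind often leave no public arrays or motif
library, the package ships a seeded synthetic-study generator
(`generate_study()`) that plants motif occurrences and expression effects
at known rates, so every stage is validated against ground truth.

## Worked example

```r
library(promsig)

study <- generate_study(study_config(seed = 1))
study
#> Synthetic promoter/expression study
#>   1000 genes, conditions control/A/B/AB x 3 replicates (seed 1)
#>   promoter windows: 500 bp and 5000 bp; 52 motifs (2 focal)
#>   planted occurrences: 346; actin-tagged genes: 200

analysis <- analyze_study(study, seed = 1)
analysis
#> Promoter regulatory-signature analysis
#>   A vs control: 0 significant genes (BH < 0.05)
#>   B vs control: 0 significant genes (BH < 0.05)
#>   AB vs control: 194 significant genes (BH < 0.05)
#>   unique to co-treatment: 194 genes
#>   motif/gene matrix: 1000 genes x 52 motifs (threshold 0.85)
#>   co-inertia RV = 0.1948 (global permutation p = 0.002)
#>   representation calls (up vs down universe): 2 over, 2 under at p < 0.05
#>   stratification creb_like: rho = -0.292 (p = 0.001)
#>   stratification e2f1_like: rho = +0.271 (p = 0.001)

head(analysis$representation[order(analysis$representation$p_perm), ], 2)
#>       motif       stat direction p_perm      p_hyper  p_bh significant
#> 1 creb_like -0.5702286     under  0.001 1.718168e-16 0.026        TRUE
#> 2 e2f1_like  0.6455077      over  0.001 1.148070e-21 0.026        TRUE
```

Reading the output: only the co-treatment regulates genes (194 at BH
< 0.05, all unique to the combination, recovering the planted 100 up +
100 down within noise); among the regulated genes the planted E2F1-like
site is over-represented in the up set and the CREB-like site
under-represented (both permutation *p* = 0.001, surviving BH across the
52-motif library), while the 50 decoys behave like null motifs; and
within the actin-annotated subset, E2F1-like counts rise and CREB-like
counts fall with expression fold change — repressed genes carry more
CREB-like sites, induced genes more E2F1-like sites.

`plot(analysis$cia)` draws motif loadings on the co-inertia axes and
`plot(analysis$stratification)` the site-count bars ordered by fold
change. A thin command-line wrapper with `simulate` / `run-all`
subcommands lives at `inst/cli/promsig.R`; `run_pipeline()` is the same
entry point from R and writes every stage output plus an MD5-hashed
manifest.

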