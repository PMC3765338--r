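Package: promsig
Title: Promoter Regulatory Signatures by Motif Scanning and Co-Inertia Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription-factor binding-site (TFBS) signatures
    associated with treatment-defined gene expression programmes. Builds
    differential-expression gene sets from a multi-condition expression matrix
    (t-tests with Benjamini-Hochberg control), scans upstream promoter windows
    with position weight matrices at a relative-score threshold to form a
    motif/gene matrix, couples that matrix to gene-set membership by
    co-inertia analysis with RV-coefficient permutation inference, calls
    over- and under-represented TFBSs per gene set, and tests whether counts
    of focal binding sites (CREB-like, E2F1-like) in long upstream windows
    stratify with expression fold change within a GO-defined gene subset.
    Includes a seeded synthetic-study generator that plants motif occurrences
    and expression effects at known rates for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
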