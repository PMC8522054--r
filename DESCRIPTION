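Package: twohit
Title: Family-Based Two-Hit Integration of Rare Variants and Transcriptome Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a family-based "two-hit" analysis for recurrent
    pathogenic copy-number variants such as the 16p12.1 deletion. Rare
    deleterious "second-hit" variants are filtered and classified into a
    25-class taxonomy (coding, non-coding regulatory, structural, and short
    tandem repeat classes) with parent-of-origin inheritance; expression
    changes are called by negative-binomial differential expression
    (leave-one-out intersection and trio modes), latent-factor-corrected
    outlier z-scores, isoform-level splicing calls, and binomial
    allele-specific expression tests; variant classes are related to
    expression changes by stratified Fisher-exact enrichment, burden tests,
    and synergy-gene detection; and proximity between second-hit genes and
    dysregulated genes is tested in a weighted brain-specific interaction
    network by node-relabelling permutations. A fully labelled synthetic
    family-cohort generator makes every stage testable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
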