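Package: acewas
Title: Epigenome-Wide Association Pipeline for Maternal Adversity and Newborn
    Cord-Blood DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, simulation-driven reimplementation of an analysis
    pipeline linking maternal preconception adversity scores (ACEs) to newborn
    cord-blood DNA methylation. Provides synthetic cohort and methylome
    generators with planted effects, moderated logit-scale epigenome-wide
    association testing under three exposure specifications, Monte-Carlo
    reference-individual contrasts converting logit coefficients to percent
    methylation, autocorrelation-adjusted Stouffer-Liptak region calling with
    Sidak correction, unsigned co-methylation network modules with eigengene
    trait tests, Storey and Grenander-based q-values, genomic inflation
    diagnostics, reference-based cell-type deconvolution, and probe-count-bias
    corrected gene-set enrichment via the Wallenius noncentral hypergeometric
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
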