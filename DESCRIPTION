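Package: rifdc
Title: Differential Connectivity and Regulatory Impact Factor Analysis for
    Two-Group RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for contrasting bulk RNA-seq transcriptomes
    between two treatment groups when per-gene hypothesis testing is
    underpowered. Implements the normalisation chain (completeness filter,
    reads-per-million, log2, quantile normalisation) with a PCA group-separation
    check; MA-style differential expression and the Phenotypic Impact Factor
    (PIF, abundance times differential expression) gene ranking; an exact
    binomial test for direction-of-change skew of a designated gene set such as
    the mitoproteome; Regulatory Impact Factor (RIF1/RIF2) scores that detect
    regulators rewired between conditions through differential co-expression to
    extreme-PIF targets, even when the regulator itself is not differentially
    expressed; and hierarchical clustering of samples on the extreme-PIF panel.
    A negative-binomial simulator plants differential expression, gene-set
    direction skew and differentially wired regulators, with truth tables for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    MASS,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
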