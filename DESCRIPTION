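Package: ssgrn
Title: Single-Step Genomic Reaction-Norm GWAS for
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage genome-wide association analysis for
    genotype-by-environment interaction in livestock. Stage one derives a
    continuous environmental gradient from contemporary-group effects on a
    descriptor trait estimated under single-step GBLUP; stage two fits a
    random-regression reaction-norm model on Legendre polynomials of that
    gradient, with a blended pedigree-genomic (H) relationship matrix,
    heterogeneous residual classes and REML variance components. SNP effects
    are back-solved from the fitted intercept and slope breeding values,
    projected to chosen environment levels, tested with genome-wide
    standardized z-scores, and annotated against local gene, QTL and
    gene-set files. Includes a pedigree/genotype/phenotype simulator with
    truth tables for calibration and recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
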