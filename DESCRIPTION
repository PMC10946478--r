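Package: demsel
Title: Two-Population Demographic Model Selection from the Joint Site
    Frequency Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds folded joint site frequency spectra (jSFS) from
    biallelic SNP data, with hypergeometric downprojection to absorb
    missing genotypes, and fits a registry of two-population
    diversification models (vicariance, founder event, old founder
    event, secondary contact) by maximizing a Poisson composite
    likelihood. Expected spectra are computed by Monte-Carlo
    structured-coalescent simulation of piecewise demographies with
    migration, size changes and exponential growth. Model selection
    uses multi-round randomized restarts, AIC and Akaike weights, with
    a hierarchical harness for pairwise population comparisons. A
    synthetic-data module generates jSFS counts and RAD-style VCFs for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
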