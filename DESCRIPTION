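Package: poolfx
Title: SNP Effects on Quantitative Traits from Pooled DNA Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-allele SNP effects on quantitative traits from
    pooled DNA samples.  Allele counts derived from pool allele-frequency
    estimates are regressed on pooled mean phenotypes by binomial logistic
    regression, and the fitted slope is converted to an effect in trait
    units through a closed-form identity involving the allele frequency and
    the phenotypic variance.  Includes rank-based pool construction within
    contemporary groups, correction for population stratification using
    principal components of a genomic correlation matrix built from pool
    allele frequencies, the individual-genotype least-squares reference
    analysis, simulation tools for evaluating pooling designs, and a
    synthetic stratified-cohort generator for two diverged populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
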