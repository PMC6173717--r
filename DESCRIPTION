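Package: sexturn
Title: Sex-Linked Marker Discovery and Sex-Chromosome Turnover Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and validation of sex-linked markers from population
    RADseq genotypes, identification of sex chromosomes, and analysis of
    sex-chromosome turnover on dated phylogenies. Implements three rule-based
    screens for XY- and ZW-type sex linkage (allele-frequency, heterozygosity
    and sex-limited-tag criteria), sex-permutation empirical nulls for
    validating marker sets, alignment-based chromosome assignment tested
    against random-subset nulls, Mk-model ancestral-state inference with
    stochastic character mapping, turnover counting and rate estimation,
    exact binomial tests of heterogamety preservation, and a gene-resampling
    null for chromosome recruitment. A synthetic-data module simulates
    genotypes, sex-limited tags, alignment hits and character histories on
    trees, with truth labels, so the full pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
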