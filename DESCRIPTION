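Package: pedexome
Title: Family-Based Exome Variant Prioritization with Parametric Linkage
    and IBD Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rare-variant discovery in multiplex
    pedigrees sequenced by whole-exome sequencing. Reads multi-sample VCF,
    pedigree (PED) and annotation tables; applies genotype-, site-, sample-
    and marker-level quality filters; computes exact two-point parametric
    affecteds-only LOD scores by Elston-Stewart peeling; delineates
    identity-by-descent sharing segments among affected relatives with a
    sliding-window rule; and prioritizes variants into three tiers
    (known-gene, linkage-region segregating, cross-family clustered) using
    population frequency and CADD deleteriousness thresholds. Includes a
    gene-dropping simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
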