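Package: strainvar
Title: Multi-Strain Variation Analysis for Inbred Mouse Panels
Version: 0.1.0
Authors@R:
    person("Strain", "Variation Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream variation analysis across a panel of inbred strains:
    classification of multi-sample VCF genotypes, identification of variants
    private to a single strain under a configurable high-quality
    homozygous-reference rule, pairwise sharing summaries, damage scoring of
    missense variants (Grantham physicochemical distances and SIFT classes),
    reciprocal-overlap merging and privacy calling of structural-variant call
    sets, genotype concordance against an external panel, strain-subtraction
    candidate-gene discovery, and hypergeometric pathway over-representation
    with Benjamini-Hochberg correction. Includes seeded synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
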