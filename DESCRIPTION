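Package: splicefve
Title: Regressing Alternative Splicing Variation on DNA Methylation and Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for asking how much of cassette-exon splicing
    variation is explained by DNA methylation, MeCP2 binding and sequence
    features. Provides formula-defined methylation features (region mean
    methylation and methylation density in CG and CA dinucleotide contexts)
    over five exon-centred region categories, log2 ChIP/Input features,
    probit-domain transforms of splicing ratios, repeated train/test-split
    fraction-of-variance-explained (FVE) regression with evidence-maximized
    ridge and random forests, a beta-binomial Bayes factor for differential
    splicing, and a synthetic-data generator with an exact, user-specified
    decomposition of splicing-variation variance into sequence, methylation
    and noise fractions, so power and null behaviour of the whole framework
    are verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
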