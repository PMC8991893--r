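Package: ctlong
Title: Longitudinal Circulating Tumour DNA Analysis from Serial Plasma
    Exome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising and tracking patient-specific somatic
    variants in circulating tumour DNA (ctDNA) from serial plasma exome
    sequencing. Implements a multi-stage plasma variant filtering cascade
    (strand-aware calling, germline and benign-control exclusion, blacklist
    and strand-bias artifact removal), detection of localized hypermutation
    (kataegis) from inter-mutational distances, mutational signature
    refitting against a 96-channel trinucleotide catalogue, copy-number
    segmentation and tumour-fraction estimation from binned read depth,
    longitudinal clonal deconvolution of variant allele fractions under a
    sum-condition phylogeny, and longitudinal summaries (mean mutant allele
    fraction series, tumour-plasma concordance, fragment-size profiles,
    pathway enrichment, actionability annotation). A synthetic serial-plasma
    generator with full truth tables supports end-to-end evaluation of every
    component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
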