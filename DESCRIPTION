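Package: centsat
Title: Centromeric Satellite Quantification and CENH3 Enrichment Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing centromeric satellite DNA and CENH3 (CENP-A)
    ChIP-seq data in species with large tandem-repeat arrays, modelled on the
    maize CentC system. Quantifies satellite abundance and per-copy sequence
    polymorphism by junction-aware local alignment of short reads to a circular
    monomer consensus (via its dimer), computes k-mer copy-number spectra with
    an analytic homogeneous-array baseline, profiles ChIP/input enrichment in
    genomic bins with zero-coverage and satellite masking, calls "complex"
    (unique-sequence) centromeres by a minimum-span rule with a per-chromosome
    merge, and quantifies positional drift of CENH3 profiles between samples.
    Includes a synthetic genome and read simulator with truth files for
    parameter-recovery testing, and a pipeline runner tying the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    XVector,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
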