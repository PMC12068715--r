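Package: cendyn
Title: Centromere Dynamics from CENH3 ChIP-Seq, Chromatin Marks, Non-B
    DNA and Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise centromere contraction after
    intergenomic transfer of chromosomes. Calls CENH3-binding domains
    from binned ChIP/Input coverage with a fold-change rule, compares
    parental and derived centromeres and partitions them into variable
    (R1) and stable (R2) regions; computes region-level and window-level
    differential statistics for histone modifications and chromatin
    accessibility (Fisher region tests, differential modification
    windows, pericentromere profiles, arm-symmetry tests, change
    correlations); scans genome sequence for seven non-B-form DNA motif
    classes and tests centromeric enrichment by permutation; balances
    Hi-C contact matrices (Knight-Ruiz), calls A/B compartments from
    PC1 and TADs from insulation scores, and compares boundaries
    between samples. A synthetic-data module generates genomes, paired
    ChIP/Input tracks and contact matrices with planted ground truth so
    that every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
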