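Package: capDMR
Title: Window-Based Differential Methylation Analysis for MBD-Capture Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) from
    methyl-CpG-binding-domain (MBD) capture sequencing by counting
    fragments in sliding 200-bp windows, testing each window with a
    negative-binomial generalized linear model, merging nearby windows
    into regions, combining window p-values with the Simes method and
    controlling the false discovery rate with Benjamini-Hochberg.
    Includes genomic annotation layers (regulatory/gene-body/3'UTR and
    CpG island/shore/shelf composites), observed-to-expected CpG density
    classification, a cross-platform concordance procedure against
    targeted bisulfite sequencing based on per-CpG beta regression, and
    a synthetic-data generator that plants DMRs with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    edgeR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Sequencing, Coverage
RoxygenNote: 7.3.3
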