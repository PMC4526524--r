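Package: mbddmr
Title: Differential Methylation Analysis of MBD-Seq Capture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for calling differentially methylated regions
    (DMRs) from methyl-CpG binding domain sequencing (MBD-Seq) of two mouse
    strains under a prenatal exposure design. Provides genome tiling and
    promoter probe construction, strain-aware CpG enumeration from variant
    calls, concordance/uniqueness/CpG read-pair filtration, fragment counting
    onto probes, trimmed-mean (TMM) normalization, negative-binomial
    dispersion estimation and per-probe likelihood-ratio and exact tests,
    threshold-based DMR calling, a strain-by-treatment interaction contrast,
    gene-class and genomic-feature summaries, phenotype-level power and Welch
    t-test statistics, and a synthetic MBD-capture data generator with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
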