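Package: paralogCNV
Title: Copy-Number Variation of Two-Unit Segmental Duplications via
    Paralog Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of copy-number variation at a two-unit
    segmental duplication such as the low-affinity Fc-gamma receptor locus.
    Generates paralog reference pairs with a paralog sequence variant (PSV)
    catalog, structural alleles formed by nonallelic homologous recombination
    (NAHR) and gene conversion, fosmid-like contigs, and array-CGH log2-ratio
    matrices with paralog-specific cross-hybridization. Provides contig
    paralog assignment by sequence identity, PSV-profile switch detection for
    NAHR-breakpoint and gene-conversion-tract mapping, copy-number calling by
    a cohort-adjusted three-component Gaussian mixture on the first principal
    component, discrimination of which paralog is deleted among heterozygous
    deletion carriers, and exact case-control association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
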