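Package: chromotif
Title: Chromatin Motif Discovery from Allele-Resolved FAIRE-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers DNA motifs associated with allele-specific chromatin
    accessibility. Calls differential chromatin-state region (DCSR) pairs
    from allele-resolved FAIRE-seq read depth at phased heterozygous SNPs,
    exhaustively tests all 6-10mer sequences for differential occurrence
    between the accessible and inaccessible alleles with a paired t-test,
    annotates significant k-mers against transcription-factor binding site
    collections, and validates calls against allele-specific peak sets.
    Includes a fully synthetic data generator so the whole pipeline can be
    exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    tools,
    stats,
    utils,
    methods
Suggests:
    knitr,
    rmarkdown,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
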