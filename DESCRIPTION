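Package: admixscan
Title: Local Ancestry Painting, Selection Scans and Admixture Dating for
    Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting recently admixed populations from phased
    SNP data: reference-panel local-ancestry painting by dynamic-programming
    haplotype copying with ancestry-excess segment testing, single-pulse
    admixture dating from weighted linkage-disequilibrium decay with
    jackknife uncertainty, composite selection scans (Weir-Cockerham FST,
    nucleotide-diversity log-ratio, Tajima's D, integrated haplotype score,
    composite likelihood ratio) with empirical top-quantile intersection,
    runs-of-homozygosity, LD-decay and KING-robust kinship diagnostics,
    plus a Balding-Nichols admixed-cohort simulator that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
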