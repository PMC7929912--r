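Package: kelpscan
Title: Population-Genomic Landscape and Selection Scans for Cultivated and
    Introduced Kelp
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, expected/observed heterozygosity, F_IS,
    Weir-Cockerham F_ST, reduction of diversity, delta Tajima's D), linkage
    disequilibrium decay profiles with half-maximum decay distances, runs of
    homozygosity, and a decorrelated composite of multiple signals (DCMS)
    selection scan, together with a forward Wright-Fisher simulator (selfing,
    bottlenecks, founder introductions, pooled-gamete breeding, hard sweeps)
    that generates genotype data with known ground truth for end-to-end
    validation. Designed around the study design of domesticated and invasive
    kelp populations: natural beds, pool-bred cultivars and founder-effect
    introductions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
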