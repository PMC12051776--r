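Package: sweepscan
Title: Selective-Sweep Scans and QTL-Seq Mapping for Herbicide-Resistance Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic inference of recent positive selection and
    bulked-segregant trait mapping, built around the analyses used to localise
    non-target-site herbicide resistance in outcrossing weeds. Implements
    per-site and windowed Weir-Cockerham F_ST scans with a multi-pair top-1%
    parallel-divergence tally, extended haplotype homozygosity (EHH) curves,
    Garud H1/H12/H2 soft-sweep statistics, within-group diversity and
    allele-frequency summaries, and QTL-seq delta-SNP-index mapping with a
    simulated null confidence envelope. A forward Wright-Fisher simulator of
    multi-deme hard and soft sweeps and of F2 bulked-segregant read counts
    makes every stage verifiable without access to the original resequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
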