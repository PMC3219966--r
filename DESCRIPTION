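Package: DNaseDynamics
Title: Developmental Dynamics of Chromatin Accessibility from DNaseI Cleavage Tags
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping and analysing developmentally dynamic chromatin
    accessibility from DNaseI cleavage tag data across embryonic stages.
    Implements binned cleavage-density tracks, binomial scan-statistic calling
    of FDR-controlled accessible regions, 150-bp DNaseI hypersensitive site
    (DHS) peak detection with replicate concordance and cross-stage consensus,
    a rank-expectation statistic for differential accessibility between
    stages with replicate-consistency voting and temporal classification of
    developmentally dynamic elements (DDEs), bootstrap-calibrated calling of
    developmentally dynamic domains (DDDs), and downstream annotation
    statistics (genomic category assignment, interval-overlap binomial tests,
    conservation comparison, hypergeometric term enrichment, core-promoter and
    peri-exonic accessibility clustering). A synthetic-data module generates
    multi-stage, multi-replicate tag data with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), GenomicRanges
Imports: methods, stats, utils, IRanges, S4Vectors, GenomeInfoDb,
    Biostrings, rtracklayer, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), mclust, jsonlite, optparse, withr
Config/testthat/edition: 3
biocViews: Epigenetics, ChromatinAccessibility, PeakDetection, Sequencing
RoxygenNote: 7.3.3
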