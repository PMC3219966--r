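#' @import methods GenomicRanges
#' @importFrom stats kmeans mad median p.adjust pbinom phyper pnorm quantile
#'   rbinom rnorm rpois runif setNames cor dist sd ave
#' @importFrom utils read.table write.table head tail
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom IRanges IRanges findOverlaps overlapsAny reduce width start end
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqlevels
#' @importFrom Rcpp evalCpp
#' @useDynLib DNaseDynamics, .registration = TRUE
NULL

DEV_STAGES <- c("5", "9", "10", "11", "14")

#' TagSet: one stage/replicate's DNaseI cleavage positions
#'
#' A `TagSet` holds the raw observable of the assay: the genomic positions of
#' individual DNaseI cleavage events for one developmental stage and one
#' replicate. Cleavage events are strandless single-base points; positions are
#' stored 0-based (the convention of the 4-column tag BED interchange format)
#' and kept sorted per chromosome.
#'
#' @slot stage character scalar, one of "5", "9", "10", "11", "14".
#' @slot replicate integer replicate index (1-based).
#' @slot positions named list of sorted integer vectors (0-based positions),
#'   one per chromosome.
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] describing the genome.
#' @exportClass TagSet
setClass("TagSet",
  representation(
    stage = "character",
    replicate = "integer",
    positions = "list",
    seqinfo = "Seqinfo"
  )
)

setValidity("TagSet", function(object) {
  msgs <- character()
  if (length(object@stage) != 1L)
    msgs <- c(msgs, "'stage' must be a single identifier")
  sl <- seqlengths(object@seqinfo)
  if (!all(names(object@positions) %in% names(sl)))
    msgs <- c(msgs, "positions on chromosomes absent from seqinfo")
  for (chr in names(object@positions)) {
    p <- object@positions[[chr]]
    if (length(p)) {
      if (is.unsorted(p)) msgs <- c(msgs, sprintf("positions on %s not sorted", chr))
      if (min(p) < 0 || max(p) >= sl[[chr]])
        msgs <- c(msgs, sprintf("positions on %s outside [0, seqlength)", chr))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DensityTrack: binned sliding-window cleavage density
#'
#' Per-chromosome tag counts on a fixed 20-bp binning: the score of each bin is
#' the number of cleavage tags within a `window` (default 150 bp) centred on
#' the bin midpoint. This track is the substrate for DHS peak calling, the
#' rank-expectation statistic, promoter profiles and peri-exonic profiles.
#'
#' @slot binSize bin width in bp (default 20).
#' @slot window smoothing window in bp (default 150).
#' @slot scores named list of numeric vectors, one count per bin.
#' @slot seqinfo a [GenomeInfoDb::Seqinfo].
#' @slot stage,replicate provenance of the underlying TagSet.
#' @exportClass DensityTrack
setClass("DensityTrack",
  representation(
    binSize = "integer",
    window = "integer",
    scores = "list",
    seqinfo = "Seqinfo",
    stage = "character",
    replicate = "integer"
  )
)

setValidity("DensityTrack", function(object) {
  msgs <- character()
  if (object@binSize < 1L) msgs <- c(msgs, "binSize must be positive")
  if (object@window < object@binSize)
    msgs <- c(msgs, "window must be >= binSize")
  sl <- seqlengths(object@seqinfo)
  for (chr in names(object@scores)) {
    nb <- ceiling(sl[[chr]] / object@binSize)
    if (length(object@scores[[chr]]) != nb)
      msgs <- c(msgs, sprintf("score vector length on %s != bin count", chr))
    if (any(object@scores[[chr]] < 0))
      msgs <- c(msgs, sprintf("negative scores on %s", chr))
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic tag generator
#'
#' Describes an inhomogeneous-Poisson cleavage model: a uniform background rate
#' everywhere plus shaped intensity bumps at planted sites, modulated per
#' developmental stage by each site's stage profile. All randomness derives
#' from the single integer `seed` through a documented splitting scheme
#' ([splitSeed]).
#'
#' @slot genome a [GenomeInfoDb::Seqinfo].
#' @slot backgroundRate expected background tags per bp.
#' @slot sites a [GenomicRanges::GRanges] of planted sites; metadata columns
#'   `profile` (numeric matrix, one column per stage), `truth_class`, `shape`
#'   ("unimodal" or "camelback").
#' @slot siteEnrichment fold enrichment over background at the peak of a
#'   planted site with unit profile.
#' @slot replicatesPerStage integer, default 2.
#' @slot seed integer master seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    genome = "Seqinfo",
    backgroundRate = "numeric",
    sites = "GRanges",
    siteEnrichment = "numeric",
    replicatesPerStage = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@backgroundRate < 0) msgs <- c(msgs, "backgroundRate must be >= 0")
  if (object@siteEnrichment < 0) msgs <- c(msgs, "siteEnrichment must be >= 0")
  if (object@replicatesPerStage < 1L)
    msgs <- c(msgs, "replicatesPerStage must be >= 1")
  if (length(object@sites)) {
    prof <- mcols(object@sites)$profile
    if (is.null(prof) || !is.matrix(prof) || ncol(prof) != 5L)
      msgs <- c(msgs, "sites must carry a 5-column stage profile matrix")
    else if (any(!is.finite(prof)) || any(prof < 0))
      msgs <- c(msgs, "stage profiles must be finite and non-negative")
    if (any(width(object@sites) < 150L))
      msgs <- c(msgs, "planted sites must be at least 150 bp wide")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenomeAnnotation: toy gene models with promoter motifs and exon expression
#'
#' Container for the gene annotation the downstream analyses consume: gene
#' bodies with strand and TSS, per-gene features (5'UTR, CDS exons, introns,
#' 3'UTR), a promoter motif-presence matrix over ten named core-promoter
#' motifs, and per-exon early-embryo expression values.
#'
#' @slot genes GRanges of gene bodies with `gene_id`, `tss` (0-based position)
#'   and `regulator` (logical) metadata.
#' @slot features GRanges of gene parts with `type` in
#'   {five_prime_UTR, CDS, intron, three_prime_UTR} and `gene_id`.
#' @slot promoterMotifs logical matrix, genes x motifs.
#' @slot exonExpression numeric vector named by exon id (early expression
#'   signal for CDS exons).
#' @slot seqinfo a Seqinfo.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(
    genes = "GRanges",
    features = "GRanges",
    promoterMotifs = "matrix",
    exonExpression = "numeric",
    seqinfo = "Seqinfo"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msgs <- character()
  if (length(object@genes)) {
    if (is.null(mcols(object@genes)$gene_id))
      msgs <- c(msgs, "genes must carry gene_id")
    sl <- seqlengths(object@seqinfo)
    if (any(end(object@genes) > sl[as.character(seqnames(object@genes))]))
      msgs <- c(msgs, "gene intervals extend beyond chromosome bounds")
    if (nrow(object@promoterMotifs) != length(object@genes))
      msgs <- c(msgs, "promoterMotifs rows != number of genes")
  }
  if (length(msgs)) msgs else TRUE
})
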