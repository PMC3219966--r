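#' Construct a genome description
#'
#' Thin wrapper around [GenomeInfoDb::Seqinfo] used throughout the package to
#' describe the (toy) genome: unique chromosome names with positive lengths.
#'
#' @param chromNames character vector of unique chromosome names.
#' @param chromLengths integer vector of chromosome lengths (bp, > 0).
#' @return a [GenomeInfoDb::Seqinfo].
#' @examples
#' gn <- makeGenome("chr2L", 2e6)
#' @export
makeGenome <- function(chromNames, chromLengths) {
  if (anyDuplicated(chromNames)) stop("chromosome names must be unique")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = as.character(chromNames),
          seqlengths = as.integer(chromLengths))
}

genomeSize <- function(genome) sum(as.numeric(seqlengths(genome)))

#' Deterministic seed splitting
#'
#' All randomness in the package flows from one master integer seed. Substream
#' seeds are derived as
#' `(seed * 1000003 + code(purpose) * 10007 + index) mod 2147483629`
#' where `code()` maps the purpose string to a fixed small integer. The same
#' (seed, purpose, index) always yields the same substream seed.
#'
#' @param seed master integer seed.
#' @param purpose one of "tags", "annotation", "conservation", "fdr",
#'   "null", "cluster", "random".
#' @param index non-negative integer distinguishing substreams of one purpose.
#' @return an integer seed below 2^31.
#' @export
splitSeed <- function(seed, purpose, index = 0L) {
  codes <- c(tags = 1, annotation = 2, conservation = 3, fdr = 4,
             null = 5, cluster = 6, random = 7)
  if (!purpose %in% names(codes)) stop("unknown seed purpose: ", purpose)
  as.integer((as.numeric(seed) * 1000003 + codes[[purpose]] * 10007 +
                as.numeric(index)) %% 2147483629)
}

#' Construct a TagSet
#'
#' @param positions named list of integer vectors of 0-based cleavage
#'   positions (one element per chromosome), or a single unnamed vector for a
#'   one-chromosome genome.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param stage stage identifier ("5", "9", "10", "11", "14").
#' @param replicate replicate index.
#' @return a [TagSet].
#' @examples
#' gn <- makeGenome("chr2L", 1000)
#' ts <- TagSet(list(chr2L = c(100L, 110L, 500L)), gn)
#' nTags(ts)
#' @export
TagSet <- function(positions, genome, stage = "5", replicate = 1L) {
  if (!is.list(positions)) {
    if (length(seqlevels(genome)) != 1L)
      stop("unnamed positions need a one-chromosome genome")
    positions <- setNames(list(positions), seqlevels(genome))
  }
  full <- setNames(vector("list", length(seqlevels(genome))), seqlevels(genome))
  for (chr in names(full))
    full[[chr]] <- sort(as.integer(positions[[chr]]))
  new("TagSet", stage = as.character(stage), replicate = as.integer(replicate),
      positions = full, seqinfo = genome)
}

#' @rdname TagSet-class
#' @export
setMethod("stageId", "TagSet", function(x) x@stage)
#' @rdname TagSet-class
#' @export
setMethod("replicateId", "TagSet", function(x) x@replicate)
#' @rdname TagSet-class
#' @export
setMethod("tagPositions", "TagSet", function(x) x@positions)
#' @rdname TagSet-class
#' @export
setMethod("nTags", "TagSet", function(x) sum(lengths(x@positions)))
#' @rdname TagSet-class
#' @export
setMethod("seqinfo", "TagSet", function(x) x@seqinfo)

setMethod("show", "TagSet", function(object) {
  cat(sprintf("TagSet: stage %s replicate %d, %d tags on %d chromosome(s)\n",
              object@stage, object@replicate, nTags(object),
              length(seqlevels(object@seqinfo))))
})

#' @rdname DensityTrack-class
#' @export
setMethod("binSize", "DensityTrack", function(x) x@binSize)
#' @rdname DensityTrack-class
#' @export
setMethod("windowSize", "DensityTrack", function(x) x@window)
#' @rdname DensityTrack-class
#' @export
setMethod("trackScores", "DensityTrack", function(x) x@scores)
#' @rdname DensityTrack-class
#' @export
setMethod("seqinfo", "DensityTrack", function(x) x@seqinfo)
#' @rdname DensityTrack-class
#' @export
setMethod("stageId", "DensityTrack", function(x) x@stage)
#' @rdname DensityTrack-class
#' @export
setMethod("replicateId", "DensityTrack", function(x) x@replicate)

setMethod("show", "DensityTrack", function(object) {
  cat(sprintf(
    "DensityTrack: %d-bp bins, %d-bp window, stage %s rep %d, %d bins total\n",
    object@binSize, object@window, object@stage, object@replicate,
    sum(lengths(object@scores))))
})

#' Construct a SimulationConfig
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param backgroundRate expected background cleavage tags per bp (default
#'   0.025, i.e. 50,000 tags on a 2-Mb genome per sample).
#' @param sites planted sites from [plantedSites()] (may be empty).
#' @param siteEnrichment peak fold-enrichment over background for a site with
#'   unit stage profile; default 10.
#' @param replicatesPerStage default 2.
#' @param seed master integer seed.
#' @return a [SimulationConfig].
#' @export
SimulationConfig <- function(genome, backgroundRate = 0.025,
                             sites = GRanges(seqinfo = genome),
                             siteEnrichment = 10, replicatesPerStage = 2L,
                             seed = 1L) {
  if (backgroundRate < 0) stop("backgroundRate must be >= 0")
  if (siteEnrichment < 0) stop("siteEnrichment must be >= 0")
  new("SimulationConfig", genome = genome,
      backgroundRate = as.numeric(backgroundRate), sites = sites,
      siteEnrichment = as.numeric(siteEnrichment),
      replicatesPerStage = as.integer(replicatesPerStage),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %.3g-Mb genome, background %.3g tags/bp, ",
    "%d planted sites, enrichment %.3gx, %d replicates/stage, seed %d\n"),
    genomeSize(object@genome) / 1e6, object@backgroundRate,
    length(object@sites), object@siteEnrichment,
    object@replicatesPerStage, object@seed))
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf(
    "GenomeAnnotation: %d genes, %d features, %d promoter motifs\n",
    length(object@genes), length(object@features),
    ncol(object@promoterMotifs)))
})

#' @rdname GenomeAnnotation-class
#' @param x a GenomeAnnotation.
#' @export
annotGenes <- function(x) x@genes
#' @rdname GenomeAnnotation-class
#' @export
annotFeatures <- function(x) x@features
#' @rdname GenomeAnnotation-class
#' @export
promoterMotifs <- function(x) x@promoterMotifs
#' @rdname GenomeAnnotation-class
#' @export
exonExpression <- function(x) x@exonExpression

## count tags t with a <= t < b on a sorted 0-based integer vector
countInRange <- function(pos, a, b) {
  findInterval(b - 0.5, pos) - findInterval(a - 0.5, pos)
}
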