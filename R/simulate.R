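## Synthetic multi-stage DNaseI cleavage data with planted truth.
##
## The generator emulates the observable structure of an embryo DNase-seq
## experiment at desk scale: a uniform Poisson background of cleavage tags,
## 150-bp-scale enriched sites whose intensity is modulated across the five
## developmental stages (5, 9, 10, 11, 14), and two independent replicates per
## stage drawn from the same intensity function.

STAGE_PROFILES <- list(
  stage5  = c(1, 0, 0, 0, 0),
  stage9  = c(0, 1, 0, 0, 0),
  stage10 = c(0, 0, 1, 0, 0),
  stage11 = c(0, 0, 0, 1, 0),
  stage14 = c(0, 0, 0, 0, 1),
  early   = c(1, 0.9, 0.7, 0.45, 0.2),
  late    = c(0.2, 0.45, 0.7, 0.9, 1),
  mixed   = c(1, 0.4, 0.1, 0.4, 1),
  constitutive = c(1, 1, 1, 1, 1)
)

#' Planted accessibility sites with known temporal truth
#'
#' Builds a GRanges of planted sites for [SimulationConfig()]. Each site gets
#' a 5-stage relative-intensity profile determined by its truth class:
#' stage-specific classes have intensity only at that stage, "early" declines
#' monotonically, "late" rises monotonically, "mixed" is U-shaped
#' (high-low-high) and "constitutive" is flat. Shapes are "unimodal" (one
#' 150-bp triangular bump) or "camelback" (two 150-bp bumps whose centres are
#' 150 bp apart, giving a double peak with a central trough).
#'
#' @param genome a Seqinfo.
#' @param classes character vector of truth classes, one per site; recycled
#'   against `starts`.
#' @param starts integer vector of 0-based site start positions.
#' @param width site width, >= 150 (default 150).
#' @param shape "unimodal" or "camelback", recycled.
#' @param chrom chromosome name, recycled (default first chromosome).
#' @return GRanges with metadata columns `profile` (matrix, columns are the
#'   five stages), `truth_class` and `shape`.
#' @export
plantedSites <- function(genome, classes, starts, width = 150L,
                         shape = "unimodal", chrom = seqlevels(genome)[1]) {
  n <- max(length(classes), length(starts))
  classes <- rep_len(classes, n)
  starts <- rep_len(as.integer(starts), n)
  shape <- rep_len(shape, n)
  chrom <- rep_len(chrom, n)
  width <- rep_len(as.integer(width), n)
  bad <- setdiff(classes, names(STAGE_PROFILES))
  if (length(bad)) stop("unknown truth class: ", paste(bad, collapse = ", "))
  prof <- do.call(rbind, STAGE_PROFILES[classes])
  colnames(prof) <- DEV_STAGES
  gr <- GRanges(chrom, IRanges(start = starts + 1L, width = width),
                seqinfo = genome)
  mcols(gr)$profile <- prof
  mcols(gr)$truth_class <- classes
  mcols(gr)$shape <- shape
  gr
}

## Draw n positions from a unit-peak triangular bump centred at `centre`
## (0-based) with total half-width `halfw`: sum of two uniforms.
rtriangle <- function(n, centre, halfw) {
  centre + halfw * (runif(n) + runif(n) - 1)
}

#' Simulate one stage/replicate of cleavage tags
#'
#' Tags are drawn from an inhomogeneous Poisson process: a uniform background
#' of `backgroundRate` tags/bp plus, at every planted site, a shaped intensity
#' bump whose peak height is `backgroundRate * siteEnrichment *
#' profile[stage]`. Replicates are independent draws from the same intensity
#' (mirroring separate DNaseI digestions of pooled nuclei). The same
#' (config, stage, replicate) triple always produces an identical TagSet.
#'
#' @param config a [SimulationConfig].
#' @param stage one of "5", "9", "10", "11", "14".
#' @param replicate replicate index, 1 .. replicatesPerStage.
#' @return a [TagSet].
#' @examples
#' gn <- makeGenome("chr2L", 1e5)
#' cfg <- SimulationConfig(gn, backgroundRate = 0.01, seed = 1)
#' ts <- simulateTags(cfg, "5", 1)
#' @export
simulateTags <- function(config, stage, replicate = 1L) {
  stage <- as.character(stage)
  if (!stage %in% DEV_STAGES)
    stop("unknown stage id: ", stage, " (expected one of ",
         paste(DEV_STAGES, collapse = ", "), ")")
  replicate <- as.integer(replicate)
  if (replicate < 1L || replicate > config@replicatesPerStage)
    stop("replicate index out of range")
  sidx <- match(stage, DEV_STAGES)
  set.seed(splitSeed(config@seed, "tags", sidx * 100L + replicate))
  sl <- seqlengths(config@genome)
  positions <- setNames(vector("list", length(sl)), names(sl))
  sites <- config@sites
  for (chr in names(sl)) {
    len <- sl[[chr]]
    nbg <- rpois(1L, config@backgroundRate * len)
    pos <- floor(runif(nbg) * len)
    cs <- sites[as.character(seqnames(sites)) == chr]
    if (length(cs)) {
      prof <- mcols(cs)$profile[, stage]
      shp <- mcols(cs)$shape
      ctr0 <- (start(cs) - 1L + end(cs)) / 2  # 0-based midpoint
      peak <- config@backgroundRate * config@siteEnrichment * prof
      for (i in seq_along(cs)) {
        if (peak[i] <= 0) next
        if (shp[i] == "camelback") {
          ## two triangular bumps, centres 150 bp apart
          lam <- peak[i] * 75  # area of one unit-height 150-bp triangle
          n1 <- rpois(1L, lam); n2 <- rpois(1L, lam)
          p <- c(rtriangle(n1, ctr0[i] - 75, 75),
                 rtriangle(n2, ctr0[i] + 75, 75))
        } else {
          halfw <- width(cs)[i] / 2
          lam <- peak[i] * halfw  # triangle area = peak * halfw
          p <- rtriangle(rpois(1L, lam), ctr0[i], halfw)
        }
        pos <- c(pos, p)
      }
    }
    pos <- floor(pos)
    pos <- pos[pos >= 0 & pos < len]
    positions[[chr]] <- sort(as.integer(pos))
  }
  new("TagSet", stage = stage, replicate = replicate,
      positions = positions, seqinfo = config@genome)
}

#' Generate a toy gene annotation with planted truth
#'
#' Places `nGenes` non-overlapping gene models on the genome, alternating
#' strands, each with a 5'UTR, 2-3 CDS exons separated by introns, and a
#' 3'UTR. A configurable fraction of promoters carries each of the ten core
#' promoter motif labels, a configurable fraction of genes is labelled as a
#' regulator (transcription factor), and a fraction of CDS exons receives an
#' elevated early-expression signal. The truth of every assignment is
#' returned alongside the annotation.
#'
#' @param config a [SimulationConfig] (supplies the genome and the seed).
#' @param nGenes number of genes to place.
#' @param motifFraction named numeric vector of per-motif promoter fractions;
#'   names default to the ten core promoter motifs (TATA, INR, DPE, DRE, MTE,
#'   r1, r2, r6, r7, DPEv), value default 0.2 each.
#' @param regulatorFraction fraction of genes labelled regulator (default 0.1).
#' @param elevatedExonFraction fraction of CDS exons with elevated early
#'   expression (default 0.3).
#' @param elevatedSignal,baselineSignal expression values for elevated /
#'   baseline exons (defaults 60 and 5; the elevated-expression threshold used
#'   downstream is 25).
#' @return list with elements `annotation` (a [GenomeAnnotation]) and `truth`
#'   (list of data frames: genes, motifs, exons).
#' @export
makeAnnotation <- function(config, nGenes = 40L,
                           motifFraction = NULL,
                           regulatorFraction = 0.1,
                           elevatedExonFraction = 0.3,
                           elevatedSignal = 60, baselineSignal = 5) {
  motifs <- c("TATA", "INR", "DPE", "DRE", "MTE", "r1", "r2", "r6", "r7",
              "DPEv")
  if (is.null(motifFraction)) motifFraction <- setNames(rep(0.2, 10), motifs)
  if (is.null(names(motifFraction)))
    names(motifFraction) <- motifs[seq_along(motifFraction)]
  frac <- setNames(rep(0, 10), motifs)
  frac[names(motifFraction)] <- motifFraction
  nGenes <- as.integer(nGenes)
  gn <- config@genome
  set.seed(splitSeed(config@seed, "annotation"))
  if (nGenes == 0L) {
    ann <- new("GenomeAnnotation", genes = GRanges(seqinfo = gn),
               features = GRanges(seqinfo = gn),
               promoterMotifs = matrix(FALSE, 0, 10,
                                       dimnames = list(NULL, motifs)),
               exonExpression = numeric(), seqinfo = gn)
    return(list(annotation = ann,
                truth = list(genes = data.frame(), motifs = data.frame(),
                             exons = data.frame())))
  }
  sl <- seqlengths(gn)
  ## share genes across chromosomes proportionally to length
  perChrom <- diff(round(cumsum(c(0, as.numeric(sl))) / sum(as.numeric(sl)) *
                           nGenes))
  geneRows <- list(); featRows <- list()
  gid <- 0L
  for (ci in seq_along(sl)) {
    ng <- perChrom[ci]
    if (ng == 0) next
    chr <- names(sl)[ci]
    len <- sl[[ci]]
    slot <- floor(len / ng)
    for (g in seq_len(ng)) {
      gid <- gid + 1L
      strand <- if (gid %% 2L) "+" else "-"
      ## structural parts, 5' -> 3' in transcription order
      utr5 <- sample(150:250, 1)
      nex <- sample(2:3, 1)
      exLens <- sample(c(180:260, 340:420), nex, replace = TRUE)
      inLens <- sample(320:700, nex - 1, replace = TRUE)
      utr3 <- sample(150:250, 1)
      glen <- utr5 + sum(exLens) + sum(inLens) + utr3
      margin <- 400L  # keep promoters and flanks inside the slot
      lo <- (g - 1) * slot + margin
      hi <- g * slot - margin - glen
      if (hi <= lo) stop("genome too small to place requested genes")
      gstart <- lo + sample.int(hi - lo, 1)  # 0-based
      mid <- integer(0); midT <- character(0)
      for (e in seq_len(nex)) {
        mid <- c(mid, exLens[e]); midT <- c(midT, "CDS")
        if (e < nex) { mid <- c(mid, inLens[e]); midT <- c(midT, "intron") }
      }
      partLens <- c(utr5, mid, utr3)
      partTypes <- c("five_prime_UTR", midT, "three_prime_UTR")
      offs <- cumsum(c(0, partLens))
      if (strand == "+") {
        s0 <- gstart + offs[-length(offs)]
        e0 <- gstart + offs[-1]
        tss <- gstart
      } else {
        gend <- gstart + glen
        s0 <- gend - offs[-1]
        e0 <- gend - offs[-length(offs)]
        tss <- gend - 1L
      }
      id <- sprintf("gene%03d", gid)
      geneRows[[gid]] <- data.frame(chrom = chr, start0 = gstart,
                                    end0 = gstart + glen, strand = strand,
                                    gene_id = id, tss = tss)
      featRows[[gid]] <- data.frame(chrom = chr, start0 = s0, end0 = e0,
                                    strand = strand, type = partTypes,
                                    gene_id = id)
    }
  }
  gdf <- do.call(rbind, geneRows)
  fdf <- do.call(rbind, featRows)
  genes <- GRanges(gdf$chrom, IRanges(gdf$start0 + 1L, gdf$end0),
                   strand = gdf$strand, seqinfo = gn)
  mcols(genes)$gene_id <- gdf$gene_id
  mcols(genes)$tss <- gdf$tss
  features <- GRanges(fdf$chrom, IRanges(fdf$start0 + 1L, fdf$end0),
                      strand = fdf$strand, seqinfo = gn)
  mcols(features)$type <- fdf$type
  mcols(features)$gene_id <- fdf$gene_id
  ## regulator labels: exact count
  nReg <- round(regulatorFraction * nGenes)
  reg <- rep(FALSE, nGenes)
  reg[sample.int(nGenes, nReg)] <- TRUE
  mcols(genes)$regulator <- reg
  ## motif truth: exact per-motif counts
  pm <- matrix(FALSE, nGenes, 10, dimnames = list(gdf$gene_id, motifs))
  for (m in motifs) {
    k <- round(frac[[m]] * nGenes)
    if (k > 0) pm[sample.int(nGenes, k), m] <- TRUE
  }
  ## exon early-expression truth
  ex <- features[mcols(features)$type == "CDS"]
  exid <- sprintf("%s_ex%d", mcols(ex)$gene_id,
                  ave(seq_along(ex), mcols(ex)$gene_id, FUN = seq_along))
  nEl <- round(elevatedExonFraction * length(ex))
  expr <- rep(baselineSignal, length(ex))
  if (nEl > 0) expr[sample.int(length(ex), nEl)] <- elevatedSignal
  names(expr) <- exid
  ann <- new("GenomeAnnotation", genes = genes, features = features,
             promoterMotifs = pm, exonExpression = expr, seqinfo = gn)
  truth <- list(
    genes = data.frame(gene_id = gdf$gene_id, chrom = gdf$chrom,
                       tss = gdf$tss, strand = gdf$strand, regulator = reg),
    motifs = data.frame(gene_id = rep(gdf$gene_id, 10),
                        motif = rep(motifs, each = nGenes),
                        present = as.vector(pm)),
    exons = data.frame(exon_id = exid, gene_id = mcols(ex)$gene_id,
                       expression = unname(expr),
                       elevated = unname(expr) > 25))
  list(annotation = ann, truth = truth)
}

#' Simulate a per-base conservation score track
#'
#' Produces a phastCons-style per-base score in [0, 1]: `backgroundMean`
#' everywhere, `elevatedMean` over the supplied truth intervals, plus optional
#' Gaussian noise (clamped to [0, 1]).
#'
#' @param genome a Seqinfo.
#' @param truth GRanges of intervals with elevated conservation (e.g. planted
#'   DDE truth).
#' @param elevatedMean,backgroundMean means inside / outside truth intervals;
#'   `elevatedMean >= backgroundMean` required.
#' @param noiseSd standard deviation of additive Gaussian noise (default 0).
#' @param seed integer seed.
#' @return named list of per-base numeric vectors, one per chromosome
#'   (position i of a vector is 0-based base i-1).
#' @export
simulateConservation <- function(genome, truth, elevatedMean = 0.8,
                                 backgroundMean = 0.2, noiseSd = 0,
                                 seed = 1L) {
  stopifnot(is.finite(elevatedMean), is.finite(backgroundMean))
  if (elevatedMean < backgroundMean)
    stop("elevatedMean must be >= backgroundMean")
  set.seed(splitSeed(seed, "conservation"))
  sl <- seqlengths(genome)
  out <- setNames(vector("list", length(sl)), names(sl))
  for (chr in names(sl)) {
    v <- rep(backgroundMean, sl[[chr]])
    tr <- truth[as.character(seqnames(truth)) == chr]
    for (i in seq_along(tr))
      v[start(tr)[i]:end(tr)[i]] <- elevatedMean
    if (noiseSd > 0) v <- pmin(1, pmax(0, v + rnorm(length(v), 0, noiseSd)))
    out[[chr]] <- v
  }
  out
}
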