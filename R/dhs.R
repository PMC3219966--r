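## 150-bp DHS peaks within accessible regions, replicate concordance,
## cross-stage consensus and stage of temporal origin.

DHS_WIDTH <- 150L

#' Call 150-bp DHS peaks within accessible regions
#'
#' Within each region, local maxima of the binned density are selected
#' greedily by descending density (ties: leftmost wins). Each accepted peak
#' spawns a 150-bp DHS centred on the peak bin's midpoint; subsequent peaks
#' whose 150-bp windows would overlap an already accepted DHS are skipped.
#' Multiple DHSs per region are allowed; a region with all-zero density
#' yields none. A DHS centre always lies inside its region, but the 150-bp
#' window may extend past the region edge by up to 75 bp.
#'
#' @param track a [DensityTrack] of the same stage/replicate as `regions`.
#' @param regions GRanges of accessible regions ([callAccessibleRegions]).
#' @return GRanges of DHSs (width 150) with metadata `stage`, `peak_density`
#'   and `source_region`.
#' @export
callDHSPeaks <- function(track, regions) {
  bs <- track@binSize
  sl <- seqlengths(track@seqinfo)
  out <- list()
  for (ri in seq_along(regions)) {
    chr <- as.character(seqnames(regions)[ri])
    s0 <- start(regions)[ri] - 1L; e0 <- end(regions)[ri]
    i1 <- s0 %/% bs + 1L
    i2 <- (e0 - 1L) %/% bs + 1L
    d <- track@scores[[chr]][i1:i2]
    if (all(d == 0)) next
    ## plateau-compressed local maxima, leftmost bin of each maximal run
    r <- rle(as.numeric(d))
    nr <- length(r$values)
    prev <- c(-Inf, r$values[-nr]); nxt <- c(r$values[-1L], -Inf)
    isMax <- r$values > prev & r$values > nxt & r$values > 0
    runStart <- cumsum(c(1L, r$lengths[-nr]))
    cand <- runStart[isMax]            # index within region bins
    if (!length(cand)) next
    dens <- r$values[isMax]
    ord <- order(-dens, cand)
    accepted <- integer(0)
    for (ci in ord) {
      mid <- (i1 + cand[ci] - 2L) * bs + bs / 2  # 0-based bin midpoint
      if (length(accepted) && any(abs(accepted - mid) < DHS_WIDTH)) next
      accepted <- c(accepted, mid)
    }
    accepted <- sort(accepted)
    ds0 <- pmax(as.integer(accepted - DHS_WIDTH / 2), 0L)
    de0 <- pmin(as.integer(accepted + DHS_WIDTH / 2), sl[[chr]])
    gr <- GRanges(chr, IRanges(ds0 + 1L, de0), seqinfo = track@seqinfo)
    binIdx <- as.integer(accepted %/% bs + 1L)
    mcols(gr)$peak_density <- track@scores[[chr]][binIdx]
    mcols(gr)$source_region <- if (!is.null(mcols(regions)$region_id))
      mcols(regions)$region_id[ri] else ri
    out[[length(out) + 1L]] <- gr
  }
  if (!length(out))
    return(GRanges(seqinfo = track@seqinfo, peak_density = numeric(),
                   source_region = integer(), stage = character()))
  res <- do.call(c, out)
  mcols(res)$stage <- track@stage
  sort(res)
}

#' Replicate concordance filter for DHSs
#'
#' A DHS from either replicate is retained iff it overlaps some DHS of the
#' other replicate by at least `minOverlap` bp (default 75); retained,
#' mutually supporting DHSs are merged to their interval union. The operation
#' is symmetric in the two replicates.
#'
#' @param dhsA,dhsB GRanges of DHSs from the two replicates of one stage.
#' @param minOverlap minimum overlap in bp, default 75.
#' @param stage stage label for the output (default taken from `dhsA`).
#' @return GRanges of merged concordant DHSs with metadata `stage`.
#' @export
replicateConcordant <- function(dhsA, dhsB, minOverlap = 75L,
                                stage = NULL) {
  if (is.null(stage))
    stage <- if (length(dhsA)) mcols(dhsA)$stage[1] else NA_character_
  hits <- findOverlaps(dhsA, dhsB, minoverlap = minOverlap)
  keep <- c(granges(dhsA[unique(queryHits(hits))]),
            granges(dhsB[unique(subjectHits(hits))]))
  merged <- reduce(keep)
  if (length(merged)) mcols(merged)$stage <- stage
  else mcols(merged)$stage <- character(0)
  merged
}

#' Cross-stage union consensus of DHSs
#'
#' Overlapping DHSs across stages are merged (transitively) into a single
#' consensus record carrying a presence flag per stage; non-overlapping DHSs
#' pass through unchanged. The result is a non-overlapping ("non-
#' intersecting") final DHS list.
#'
#' @param perStage named list (stage id -> GRanges of replicate-concordant
#'   DHSs).
#' @return GRanges with a logical metadata column per stage
#'   (`present.5`, ..., `present.14`).
#' @export
unionConsensus <- function(perStage) {
  stages <- names(perStage)
  all <- do.call(c, lapply(unname(perStage), granges))
  merged <- reduce(all)
  pres <- sapply(perStage, function(g) overlapsAny(merged, g))
  if (length(merged) == 1L) pres <- matrix(pres, nrow = 1)
  colnames(pres) <- paste0("present.", stages)
  mcols(merged) <- DataFrame(pres)
  merged
}

#' Assign stage of temporal origin to consensus DHSs
#'
#' The origin of a consensus DHS is the earliest developmental stage at which
#' it is present. Errors on a record with no presence flag.
#'
#' @param consensus GRanges from [unionConsensus()].
#' @return the same GRanges with an `origin_stage` metadata column.
#' @export
stageOfOrigin <- function(consensus) {
  pres <- as.matrix(mcols(consensus)[, grep("^present\\.",
                                            colnames(mcols(consensus)))])
  stages <- sub("^present\\.", "", colnames(pres))
  if (any(rowSums(pres) == 0)) stop("consensus record with no presence flag")
  first <- apply(pres, 1L, function(r) which(r)[1L])
  mcols(consensus)$origin_stage <- stages[first]
  consensus
}

#' Stage-of-origin composition table
#'
#' For every stage, among the consensus DHSs present at that stage, the
#' fraction originating at each (earlier or same) stage -- the per-stage
#' origin composition of the DHS landscape.
#'
#' @param consensus GRanges from [stageOfOrigin()].
#' @return numeric matrix, rows = stage of presence, columns = origin stage,
#'   each row summing to 1.
#' @export
originComposition <- function(consensus) {
  pres <- as.matrix(mcols(consensus)[, grep("^present\\.",
                                            colnames(mcols(consensus)))])
  stages <- sub("^present\\.", "", colnames(pres))
  origin <- mcols(consensus)$origin_stage
  out <- matrix(0, length(stages), length(stages),
                dimnames = list(present = stages, origin = stages))
  for (si in seq_along(stages)) {
    sel <- pres[, si]
    if (!any(sel)) next
    tab <- table(factor(origin[sel], levels = stages))
    out[si, ] <- as.numeric(tab) / sum(sel)
  }
  out
}
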