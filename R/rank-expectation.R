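## The rank-expectation differential statistic on 20-bp bins, replicate
## consistency voting, DDE merging, temporal classification and profile
## clustering.

#' Ordered stage pairs "s>t" in the fixed signature column order
#' @return character vector of the 20 ordered stage-pair labels.
#' @export
orderedStagePairs <- function() {
  pairs <- expand.grid(t = DEV_STAGES, s = DEV_STAGES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, c("s", "t")]
  paste0(pairs$s, ">", pairs$t)
}

#' Rolling median with truncated end windows
#'
#' Exact median over a centred window of `2*halfwidth + 1` values, truncated
#' (not reflected or shrunk symmetrically) at the sequence ends. Backed by a
#' C++ dual-multiset sliding window.
#'
#' @param x numeric vector.
#' @param halfwidth integer half-window.
#' @return numeric vector of windowed medians, same length as `x`.
#' @export
rollingMedian <- function(x, halfwidth) {
  rolling_median_trunc(as.numeric(x), as.integer(halfwidth))
}

#' Rank-expectation differential statistic
#'
#' Identifies genomic bins where signal `a` is enriched over signal `b`. The
#' bin scores of B are ranked from low to high (ties broken by genomic
#' order), and A is reordered by that ranking to give A'. In A', a bin whose
#' A-score is out of keeping with its rank neighbourhood stands out: for each
#' position the local median `m` and a robust scale
#' `s = 1.4826 * rolling-median of |A' - m|` are computed over a centred
#' window of `localWindow` rank positions (truncated at the ends), giving a
#' Gaussian z-score `(A' - m)/s` (0 where `s = 0`) and a one-sided upper-tail
#' normal p-value, which is mapped back to genomic bin order.
#'
#' Bins where both signals are zero are excluded from the ranking by default
#' (the genome is mostly empty; massed zero ties would swamp the rank
#' neighbourhoods) and receive `NA` p-values.
#'
#' @param a,b numeric vectors of per-bin density scores on the same binning
#'   (genome-wide concatenation), or [DensityTrack] objects.
#' @param localWindow odd window length in rank positions, default 10001.
#' @param includeZero include bins with `a == 0 & b == 0` (default FALSE).
#' @return numeric vector of per-bin p-values for "a enriched over b" (NA for
#'   excluded bins).
#' @export
rankExpectation <- function(a, b, localWindow = 10001L, includeZero = FALSE) {
  if (is(a, "DensityTrack")) a <- unlist(trackScores(a), use.names = FALSE)
  if (is(b, "DensityTrack")) b <- unlist(trackScores(b), use.names = FALSE)
  if (length(a) != length(b)) stop("length mismatch between signals")
  localWindow <- as.integer(localWindow)
  if (localWindow %% 2L == 0L) stop("localWindow must be odd")
  keep <- if (includeZero) seq_along(a) else which(a != 0 | b != 0)
  p <- rep(NA_real_, length(a))
  if (!length(keep)) return(p)
  ak <- a[keep]; bk <- b[keep]
  ord <- order(bk, seq_along(bk))  # ascending B, ties by genomic order
  ap <- ak[ord]
  h <- (localWindow - 1L) %/% 2L
  m <- rollingMedian(ap, h)
  s <- 1.4826 * rollingMedian(abs(ap - m), h)
  z <- ifelse(s > 0, (ap - m) / s, 0)
  p[keep[ord]] <- pnorm(z, lower.tail = FALSE)
  p
}

#' Replicate-consistency voting over the four cross-comparisons
#'
#' For one ordered stage pair there are four rank-expectation measurements
#' (2 x 2 replicate cross-comparisons). Each is BH-adjusted genome-wide and a
#' bin is flagged as consistently enriched iff at least 3 of the 4
#' comparisons are significant at `qThreshold`.
#'
#' @param pvals list of exactly 4 per-bin p-value vectors.
#' @param qThreshold BH q-value cutoff, default 0.05.
#' @return logical per-bin flag vector.
#' @export
consistentEnrichment <- function(pvals, qThreshold = 0.05) {
  if (length(pvals) != 4L) stop("need exactly 4 p-value sets")
  qs <- lapply(pvals, p.adjust, method = "BH")
  sig <- vapply(qs, function(q) !is.na(q) & q <= qThreshold,
                logical(length(qs[[1L]])))
  rowSums(sig) >= 3L
}

#' Merge flagged bins into developmentally dynamic elements
#'
#' Bins that exhibit change (at least one flagged ordered stage pair) and are
#' genomically adjacent with an identical enrichment signature are merged
#' into one DDE. Per-stage mean densities (averaged over replicates and the
#' merged bins) are attached.
#'
#' @param flags logical matrix, bins x 20 ordered stage pairs (columns named
#'   as [orderedStagePairs()]).
#' @param binInfo data.frame with columns `chrom` and `bin` (1-based bin
#'   index within chromosome) aligned with the rows of `flags`; if NULL a
#'   single chromosome with consecutive bins is assumed.
#' @param densities numeric matrix, bins x 5 stages, of per-stage mean bin
#'   densities.
#' @param binSize bp per bin, default 20.
#' @param genome optional Seqinfo for the output GRanges.
#' @return GRanges of DDEs with metadata: `signature` (character), per-stage
#'   mean densities `d5 ... d14`, `n_bins`.
#' @export
mergeDDEBins <- function(flags, densities, binInfo = NULL, binSize = 20L,
                         genome = NULL) {
  pairs <- orderedStagePairs()
  if (is.null(colnames(flags))) colnames(flags) <- pairs
  nb <- nrow(flags)
  if (is.null(binInfo)) {
    chr1 <- if (!is.null(genome)) seqlevels(genome)[1] else "chr"
    binInfo <- data.frame(chrom = chr1, bin = seq_len(nb))
  }
  changed <- rowSums(flags) > 0
  sigStr <- apply(flags, 1L, function(r) paste(as.integer(r), collapse = ""))
  idx <- which(changed)
  if (!length(idx)) {
    gr <- if (is.null(genome)) GRanges() else GRanges(seqinfo = genome)
    mcols(gr) <- DataFrame(signature = character(),
                           n_bins = integer())
    return(gr)
  }
  adj <- c(FALSE, diff(idx) == 1L &
             binInfo$chrom[idx[-1L]] == binInfo$chrom[idx[-length(idx)]] &
             sigStr[idx[-1L]] == sigStr[idx[-length(idx)]])
  runId <- cumsum(!adj)
  firsts <- tapply(idx, runId, min)
  lasts <- tapply(idx, runId, max)
  chroms <- binInfo$chrom[firsts]
  s0 <- (binInfo$bin[firsts] - 1L) * binSize
  e0 <- binInfo$bin[lasts] * binSize
  gr <- if (is.null(genome)) GRanges(chroms, IRanges(s0 + 1L, e0))
        else GRanges(chroms, IRanges(s0 + 1L, e0), seqinfo = genome)
  mcols(gr)$signature <- sigStr[firsts]
  dmat <- t(vapply(seq_along(firsts), function(k) {
    rows <- seq(firsts[k], lasts[k])
    colMeans(densities[rows, , drop = FALSE])
  }, numeric(5L)))
  colnames(dmat) <- paste0("d", DEV_STAGES)
  mcols(gr) <- cbind(mcols(gr), DataFrame(dmat))
  mcols(gr)$n_bins <- as.integer(lasts - firsts + 1L)
  gr
}

## signature string -> 5x5 logical enrichment matrix E[s, t]
signatureToMatrix <- function(sig) {
  bits <- as.integer(strsplit(sig, "")[[1L]]) == 1L
  pairs <- orderedStagePairs()
  E <- matrix(FALSE, 5, 5, dimnames = list(DEV_STAGES, DEV_STAGES))
  st <- strsplit(pairs, ">")
  for (i in seq_along(pairs)) E[st[[i]][1L], st[[i]][2L]] <- bits[i]
  E
}

#' Temporal class of a developmentally dynamic element
#'
#' Classification rules, applied in order:
#' * stage-s-specific iff `E[s, t]` holds for every other stage t;
#' * else early iff the density peak is at stage 5, 9 or 10 and no later
#'   stage is enriched over an earlier one;
#' * else late iff the density peak is at stage 11 or 14 and no earlier
#'   stage is enriched over a later one;
#' * else mixed.
#'
#' @param signature 20-character 0/1 enrichment signature (column order of
#'   [orderedStagePairs()]), or a 5x5 logical matrix.
#' @param densities numeric length-5 per-stage densities.
#' @return character scalar: one of "stage5", "stage9", "stage10", "stage11",
#'   "stage14", "early", "late", "mixed".
#' @export
classifyTemporal <- function(signature, densities) {
  E <- if (is.matrix(signature)) signature else signatureToMatrix(signature)
  if (!any(E)) stop("empty enrichment matrix: element shows no change")
  for (s in seq_along(DEV_STAGES)) {
    if (all(E[s, -s])) return(paste0("stage", DEV_STAGES[s]))
  }
  peak <- which.max(densities)
  laterOverEarlier <- any(E[lower.tri(E)])
  earlierOverLater <- any(E[upper.tri(E)])
  if (peak %in% 1:3 && !laterOverEarlier) return("early")
  if (peak %in% 4:5 && !earlierOverLater) return("late")
  "mixed"
}

#' Classify every DDE in a set
#'
#' @param ddes GRanges from [mergeDDEBins()].
#' @return the same GRanges with a `temporal_class` metadata column.
#' @export
classifyDDEs <- function(ddes) {
  dmat <- as.matrix(mcols(ddes)[, paste0("d", DEV_STAGES)])
  cls <- vapply(seq_along(ddes), function(i)
    classifyTemporal(mcols(ddes)$signature[i], dmat[i, ]), character(1L))
  mcols(ddes)$temporal_class <- cls
  ddes
}

#' Tabulate temporal classes
#'
#' Per-class counts and percentages of total, rounded to two decimals.
#'
#' @param x either a GRanges of classified DDEs (metadata `temporal_class`)
#'   or a named integer vector of class counts.
#' @param total denominator for the percentages; defaults to the sum of the
#'   counts. (The class list need not be exhaustive of the total, so listed
#'   percentages sum to at most 100.)
#' @return data.frame with columns `class`, `count`, `percent`.
#' @export
tabulateClasses <- function(x, total = NULL) {
  counts <- if (is.numeric(x)) x
            else {
              if (!length(x)) stop("empty DDE input")
              tab <- table(mcols(x)$temporal_class)
              setNames(as.integer(tab), names(tab))
            }
  if (!length(counts)) stop("empty class counts")
  if (is.null(total)) total <- sum(counts)
  data.frame(class = names(counts), count = as.integer(counts),
             percent = round(100 * as.numeric(counts) / total, 2L),
             row.names = NULL)
}

#' Cluster DDE temporal profiles
#'
#' k-means on per-DDE 5-stage profiles normalized to unit maximum, with
#' fixed-seed initialization; clusters are relabelled in order of the stage
#' (then stage value) at which their mean profile peaks. If the profiles
#' contain fewer distinct rows than `k` the assignment degenerates
#' deterministically to one cluster per distinct profile (clusters beyond the
#' number of distinct profiles are empty).
#'
#' @param ddes GRanges with `d5 ... d14` metadata, or a numeric matrix of
#'   profiles (rows = elements, 5 columns).
#' @param k number of clusters.
#' @param seed integer seed.
#' @return list with `cluster` (integer assignment per element), `centers`
#'   (k x 5 matrix of cluster mean profiles) and `sizes`.
#' @export
clusterProfiles <- function(ddes, k, seed = 1L) {
  prof <- if (is.matrix(ddes)) ddes
          else as.matrix(mcols(ddes)[, paste0("d", DEV_STAGES)])
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(prof)) stop("k exceeds the number of elements")
  mx <- apply(prof, 1L, max)
  norm <- prof / ifelse(mx > 0, mx, 1)
  uniq <- unique(norm)
  if (nrow(uniq) <= k) {
    cl <- match(apply(norm, 1L, paste, collapse = ","),
                apply(uniq, 1L, paste, collapse = ","))
    centers <- matrix(NA_real_, k, ncol(norm))
    centers[seq_len(nrow(uniq)), ] <- uniq
  } else {
    set.seed(splitSeed(seed, "cluster"))
    km <- kmeans(norm, centers = k, nstart = 5L, iter.max = 50L)
    cl <- km$cluster
    centers <- km$centers
  }
  ## order clusters by stage of peak mean accessibility
  peakStage <- apply(centers, 1L, function(r)
    if (all(is.na(r))) Inf else which.max(r))
  ord <- order(peakStage, seq_len(k))
  relabel <- match(seq_len(k), ord)
  cl <- relabel[cl]
  centers <- centers[ord, , drop = FALSE]
  colnames(centers) <- DEV_STAGES
  list(cluster = cl, centers = centers,
       sizes = tabulate(cl, nbins = k))
}
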