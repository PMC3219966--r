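## Binned density tracks and FDR-controlled accessible-region calling via the
## 250-bp scan-window binomial z-score against a 50-kb local background.

#' @describeIn binDensity method for TagSet
#' @export
setMethod("binDensity", "TagSet", function(tags, binSize = 20L,
                                           window = 150L) {
  binSize <- as.integer(binSize); window <- as.integer(window)
  if (binSize < 1L || window < 1L) stop("binSize and window must be positive")
  if (window < binSize) stop("window must be >= binSize")
  sl <- seqlengths(tags@seqinfo)
  scores <- setNames(vector("list", length(sl)), names(sl))
  for (chr in names(sl)) {
    nb <- ceiling(sl[[chr]] / binSize)
    mids <- (seq_len(nb) - 1) * binSize + binSize / 2
    p <- tags@positions[[chr]]
    scores[[chr]] <- findInterval(mids + window / 2 - 0.5, p) -
      findInterval(mids - window / 2 - 0.5, p)
  }
  new("DensityTrack", binSize = binSize, window = window, scores = scores,
      seqinfo = tags@seqinfo, stage = tags@stage, replicate = tags@replicate)
})

#' Hotspot scan parameters
#'
#' @param scanWindow W, the scanning window in bp (default 250).
#' @param backgroundSpan L, the local background span in bp (default 50,000);
#'   must exceed `scanWindow`.
#' @param fdr target false discovery rate for the region threshold (default
#'   0.01).
#' @param mergeGap maximal gap between qualifying tags merged into one region
#'   (default = scanWindow).
#' @return list of validated parameters.
#' @export
hotspotParams <- function(scanWindow = 250L, backgroundSpan = 50000L,
                          fdr = 0.01, mergeGap = scanWindow) {
  scanWindow <- as.integer(scanWindow)
  backgroundSpan <- as.integer(backgroundSpan)
  if (scanWindow >= backgroundSpan) stop("scanWindow must be < backgroundSpan")
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  list(scanWindow = scanWindow, backgroundSpan = backgroundSpan,
       fdr = fdr, mergeGap = as.integer(mergeGap))
}

#' Binomial enrichment z-score of the scanning window
#'
#' For each query position, counts the tags in the W-bp scanning window and in
#' the L-bp local background, both centred on the position, and computes the
#' binomial z-score `z = (n_w - n_L p) / sqrt(n_L p (1 - p))` with
#' `p = W / L_effective`. The background window is truncated (not shifted) at
#' chromosome ends and `p` recomputed against its realized span. Positions
#' with an empty background (or degenerate variance) get `NA` (skip signal).
#'
#' @param tags a [TagSet].
#' @param params from [hotspotParams()].
#' @param at 0-based positions to evaluate; either a numeric vector (single
#'   chromosome genome) or a named list per chromosome. Default: all tag
#'   positions.
#' @return numeric vector (or named list) of z-scores aligned with `at`.
#' @export
scanZ <- function(tags, params = hotspotParams(), at = NULL) {
  sl <- seqlengths(tags@seqinfo)
  single <- FALSE
  if (is.null(at)) {
    at <- tags@positions
  } else if (!is.list(at)) {
    if (length(sl) != 1L) stop("unnamed 'at' needs a one-chromosome genome")
    at <- setNames(list(at), names(sl))
    single <- TRUE
  }
  W <- params$scanWindow; L <- params$backgroundSpan
  out <- setNames(vector("list", length(at)), names(at))
  for (chr in names(at)) {
    pos <- tags@positions[[chr]]
    a <- at[[chr]]
    len <- sl[[chr]]
    nw <- countInRange(pos, a - W / 2, a + W / 2)
    lo <- pmax(a - L / 2, 0); hi <- pmin(a + L / 2, len)
    leff <- hi - lo
    nl <- countInRange(pos, lo, hi)
    p <- W / leff
    v <- nl * p * (1 - p)
    z <- ifelse(nl > 0 & v > 0, (nw - nl * p) / sqrt(v), NA_real_)
    out[[chr]] <- z
  }
  if (single) out[[1L]] else out
}

#' FDR threshold from observed and random z-score lists
#'
#' Returns the smallest candidate threshold T (candidates are the observed z
#' values) such that the number of random-set values >= T is at most `fdr`
#' times the number of observed values >= T. If no candidate qualifies the
#' threshold is `+Inf` (no calls).
#'
#' @param observedZ numeric vector of z-scores from the experimental tag set
#'   (NAs dropped).
#' @param randomZ numeric vector of z-scores from an equal-size uniform-random
#'   tag set on the same genome.
#' @param fdr target ratio, default 0.01.
#' @return numeric scalar threshold T.
#' @export
fdrThreshold <- function(observedZ, randomZ, fdr = 0.01) {
  if (is.list(observedZ)) observedZ <- unlist(observedZ, use.names = FALSE)
  if (is.list(randomZ)) randomZ <- unlist(randomZ, use.names = FALSE)
  observedZ <- observedZ[!is.na(observedZ)]
  randomZ <- randomZ[!is.na(randomZ)]
  if (!length(observedZ)) stop("empty observed z list")
  so <- sort(observedZ); sr <- sort(randomZ)
  cand <- unique(so)
  nObsGE <- length(so) - findInterval(cand - 1e-12, so)
  nRndGE <- length(sr) - findInterval(cand - 1e-12, sr)
  ok <- nRndGE <= fdr * nObsGE
  if (!any(ok)) return(Inf)
  cand[which(ok)[1L]]
}

## uniform tag set with the same per-chromosome totals (FDR null)
randomTagSet <- function(tags, seed) {
  set.seed(seed)
  sl <- seqlengths(tags@seqinfo)
  pos <- setNames(vector("list", length(sl)), names(sl))
  for (chr in names(sl)) {
    n <- length(tags@positions[[chr]])
    pos[[chr]] <- sort(as.integer(floor(runif(n) * sl[[chr]])))
  }
  new("TagSet", stage = tags@stage, replicate = tags@replicate,
      positions = pos, seqinfo = tags@seqinfo)
}

#' Call FDR-controlled accessible regions
#'
#' Each tag is assigned the z-score of the scanning window centred on it
#' ([scanZ]); tags with `z >= T` qualify, qualifying tags within `mergeGap` bp
#' of each other are merged, and each merged run becomes an accessible region
#' spanning from the first to the last qualifying tag expanded by W/2 on each
#' side (clamped at chromosome bounds).
#'
#' @param tags a [TagSet].
#' @param params from [hotspotParams()].
#' @param T z-score threshold, normally from [fdrThreshold()].
#' @param z optional precomputed per-tag z list (as returned by
#'   `scanZ(tags, params)`); recomputed if missing.
#' @return GRanges of regions with metadata `max_z` and `tag_count`.
#' @export
callAccessibleRegions <- function(tags, params = hotspotParams(), T,
                                  z = NULL) {
  if (is.null(z)) z <- scanZ(tags, params)
  if (!is.list(z)) z <- setNames(list(z), seqlevels(tags@seqinfo)[1])
  W <- params$scanWindow
  sl <- seqlengths(tags@seqinfo)
  res <- list()
  for (chr in names(tags@positions)) {
    pos <- tags@positions[[chr]]
    zc <- z[[chr]]
    qi <- which(!is.na(zc) & zc >= T)
    if (!length(qi)) next
    qp <- pos[qi]; qz <- zc[qi]
    newRun <- c(TRUE, diff(qp) > params$mergeGap)
    runId <- cumsum(newRun)
    first <- tapply(qp, runId, min)
    last <- tapply(qp, runId, max)
    maxz <- tapply(qz, runId, max)
    s0 <- pmax(first - W %/% 2L, 0)
    e0 <- pmin(last + W %/% 2L, sl[[chr]])
    cnt <- countInRange(pos, s0, e0)
    gr <- GRanges(chr, IRanges(s0 + 1L, e0), seqinfo = tags@seqinfo)
    mcols(gr)$max_z <- as.numeric(maxz)
    mcols(gr)$tag_count <- as.integer(cnt)
    res[[chr]] <- gr
  }
  if (!length(res))
    return(GRanges(seqinfo = tags@seqinfo,
                   max_z = numeric(), tag_count = integer()))
  out <- do.call(c, unname(res))
  mcols(out)$region_id <- seq_along(out)
  out
}

#' One-stop hotspot calling for a TagSet
#'
#' Convenience wrapper: computes per-tag z-scores, builds the uniform-random
#' null tag set (same per-chromosome totals), picks the FDR threshold, and
#' calls accessible regions. The threshold and the realized random/observed
#' ratios are attached as attributes.
#'
#' @param tags a [TagSet].
#' @param params from [hotspotParams()].
#' @param seed seed for the random null tag set.
#' @param dedupe collapse tags at identical positions before scanning
#'   (default FALSE).
#' @return GRanges of accessible regions; attributes `threshold`, `z`
#'   (per-tag z list) and `nullRegions` (count of regions the random set
#'   yields at the same threshold).
#' @export
callHotspots <- function(tags, params = hotspotParams(), seed = 1L,
                         dedupe = FALSE) {
  if (dedupe)
    tags <- new("TagSet", stage = tags@stage, replicate = tags@replicate,
                positions = lapply(tags@positions, unique),
                seqinfo = tags@seqinfo)
  zObs <- scanZ(tags, params)
  rnd <- randomTagSet(tags, splitSeed(seed, "fdr", tags@replicate))
  zRnd <- scanZ(rnd, params)
  T <- fdrThreshold(zObs, zRnd, params$fdr)
  regions <- callAccessibleRegions(tags, params, T, z = zObs)
  nullRegions <- length(callAccessibleRegions(rnd, params, T, z = zRnd))
  attr(regions, "threshold") <- T
  attr(regions, "z") <- zObs
  attr(regions, "nullRegions") <- nullRegions
  regions
}
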