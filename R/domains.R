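## Developmentally dynamic domains: DDE density track, binomial-placement
## bootstrap null, BH-controlled domain calling, the rho temporal score, the
## neighbour-pattern binomial test, and the TSS DDE-density ranking.

#' DDE density track
#'
#' For each 20-bp genomic bin, the number of base pairs covered by DDEs
#' within `radius` bp of the bin midpoint (window `[mid - radius,
#' mid + radius)`, truncated at chromosome ends).
#'
#' @param ddes GRanges of DDEs.
#' @param genome a Seqinfo.
#' @param radius window radius in bp, default 10,000.
#' @param binSize bp per bin, default 20.
#' @return named list of numeric per-bin vectors, one per chromosome.
#' @export
ddeDensity <- function(ddes, genome, radius = 10000L, binSize = 20L) {
  sl <- seqlengths(genome)
  red <- reduce(granges(ddes))
  out <- setNames(vector("list", length(sl)), names(sl))
  for (chr in names(sl)) {
    len <- sl[[chr]]
    nb <- ceiling(len / binSize)
    ## cumulative covered-bp: C[k] = covered bp in [0, k)
    cov <- numeric(len)
    cr <- red[as.character(seqnames(red)) == chr]
    for (i in seq_along(cr)) cov[start(cr)[i]:end(cr)[i]] <- 1
    C <- c(0, cumsum(cov))
    mids <- (seq_len(nb) - 1) * binSize + binSize / 2
    lo <- pmax(floor(mids - radius), 0)
    hi <- pmin(floor(mids + radius), len)
    out[[chr]] <- C[hi + 1] - C[lo + 1]
  }
  out
}

## total union length of intervals [s, e)
unionLength <- function(s, e) {
  if (!length(s)) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  hi <- cummax(e)
  prevHi <- c(0, hi[-length(hi)])
  sum(pmax(0, e - pmax(s, prevHi)))
}

#' Bootstrap null distribution of window DDE density
#'
#' Each bootstrap draws the number of DDEs mapping by chance into a window of
#' `span = 2 * radius` bp as `k ~ Binomial(n_DDE, (span + s - 1) /
#' genome_size)` where `s` is the mean DDE size (a DDE overlaps the window
#' whenever its start falls within `span + size - 1` bp), samples `k` sizes
#' with replacement from the empirical DDE size distribution, places each
#' uniformly among the start positions that intersect the window (so partial
#' overlaps at both window edges are represented), and records the covered
#' base pairs (union within the window). The sorted null sample is returned.
#'
#' @param ddes GRanges of DDEs (non-empty).
#' @param genome a Seqinfo.
#' @param radius window radius, default 10,000 (20-kb window).
#' @param nBoot number of bootstraps; 1e4 is desk scale, 1e7 reproduces
#'   full-precision tail estimates.
#' @param seed integer seed.
#' @return sorted numeric vector of length `nBoot`.
#' @export
dddNull <- function(ddes, genome, radius = 10000L, nBoot = 10000L,
                    seed = 1L) {
  n <- length(ddes)
  if (n == 0L) stop("empty DDE list")
  span <- 2 * as.numeric(radius)
  sizes <- width(ddes)
  p <- (span + mean(sizes) - 1) / genomeSize(genome)
  set.seed(splitSeed(seed, "null"))
  ks <- rbinom(nBoot, n, p)
  out <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    k <- ks[b]
    if (k == 0L) next
    sz <- sizes[sample.int(n, k, replace = TRUE)]
    ## any start in [-(size-1), span-1] intersects the window
    st <- floor(runif(k) * (span + sz - 1)) - (sz - 1)
    out[b] <- unionLength(pmax(st, 0), pmin(st + sz, span))
  }
  sort(out)
}

#' Call developmentally dynamic domains
#'
#' Every bin of the DDE density track is assigned an empirical upper-tail
#' p-value against the bootstrap null (add-one estimator,
#' `(r + 1) / (n_boot + 1)`), and Benjamini-Hochberg control at level
#' `alpha` is applied genome-wide across bins. Local peaks of the track
#' whose bin passes are the domain seeds; each is extended to the
#' surrounding run of bins whose density exceeds the null's `1 - alpha`
#' quantile, overlapping domains are merged, and the nearest gene is
#' annotated when gene models are supplied. Testing the whole track (rather
#' than only the selected maxima) keeps the empirical p-values calibrated:
#' a sliding maximum is always in the extreme tail of a fixed-window null.
#'
#' @param track from [ddeDensity()].
#' @param null sorted null sample from [dddNull()].
#' @param alpha BH level, default 0.05.
#' @param genome a Seqinfo.
#' @param genes optional GRanges of genes with `gene_id` metadata.
#' @param binSize bp per bin, default 20.
#' @return GRanges of domains with metadata `peak_density`, `p_value`,
#'   `q_value` and (if genes given) `nearest_gene`.
#' @export
callDDDs <- function(track, null, alpha = 0.05, genome, genes = NULL,
                     binSize = 20L) {
  if (length(unique(null)) < 2L) stop("degenerate null distribution")
  nb <- length(null)
  qthr <- quantile(null, 1 - alpha, names = FALSE)
  ## per-bin empirical p, BH across the whole track
  pAll <- lapply(track, function(v) {
    rGE <- nb - findInterval(v - 1e-9, null)
    (rGE + 1) / (nb + 1)
  })
  qAll <- p.adjust(unlist(pAll, use.names = FALSE), method = "BH")
  offs <- cumsum(c(0, lengths(pAll)))
  peaks <- list()
  for (ci in seq_along(track)) {
    chr <- names(track)[ci]
    v <- track[[chr]]
    if (!length(v) || all(v == 0)) next
    r <- rle(v)
    nr <- length(r$values)
    prev <- c(-Inf, r$values[-nr]); nxt <- c(r$values[-1L], -Inf)
    isMax <- r$values > prev & r$values > nxt & r$values > 0
    runStart <- cumsum(c(1L, r$lengths[-nr]))
    if (!any(isMax)) next
    bins <- runStart[isMax]
    peaks[[chr]] <- data.frame(chrom = chr, bin = bins,
                               density = r$values[isMax],
                               p = pAll[[chr]][bins],
                               q = qAll[offs[ci] + bins])
  }
  if (!length(peaks))
    return(GRanges(seqinfo = genome, peak_density = numeric(),
                   p_value = numeric(), q_value = numeric()))
  pk <- do.call(rbind, peaks)
  sig <- pk[pk$q <= alpha, , drop = FALSE]
  if (!nrow(sig))
    return(GRanges(seqinfo = genome, peak_density = numeric(),
                   p_value = numeric(), q_value = numeric()))
  doms <- list()
  for (i in seq_len(nrow(sig))) {
    chr <- sig$chrom[i]
    v <- track[[chr]]
    above <- v > qthr
    j <- sig$bin[i]
    lo <- j; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- j; while (hi < length(v) && above[hi + 1L]) hi <- hi + 1L
    doms[[i]] <- data.frame(chrom = chr, s0 = (lo - 1L) * binSize,
                            e0 = hi * binSize, peak = sig$density[i],
                            p = sig$p[i], q = sig$q[i])
  }
  dd <- do.call(rbind, doms)
  gr <- GRanges(dd$chrom, IRanges(dd$s0 + 1L, dd$e0), seqinfo = genome)
  mcols(gr)$peak_density <- dd$peak
  mcols(gr)$p_value <- dd$p
  mcols(gr)$q_value <- dd$q
  ## merge overlapping domains, keeping the strongest peak's statistics
  red <- reduce(gr)
  hits <- findOverlaps(red, gr)
  best <- tapply(subjectHits(hits), queryHits(hits), function(ix)
    ix[which.max(mcols(gr)$peak_density[ix])])
  mcols(red)$peak_density <- mcols(gr)$peak_density[unlist(best)]
  mcols(red)$p_value <- mcols(gr)$p_value[unlist(best)]
  mcols(red)$q_value <- mcols(gr)$q_value[unlist(best)]
  if (!is.null(genes) && length(genes)) {
    nearest <- GenomicRanges::nearest(red, genes)
    mcols(red)$nearest_gene <- mcols(genes)$gene_id[nearest]
  }
  red
}

#' Temporal asymmetry score rho
#'
#' Weighted temporal asymmetry of a 5-stage density profile:
#' `rho = sum(w_s * d_s) / sum(d_s)` with stage weights summing to zero
#' (default `+2, +1, 0, -1, -2` for stages 5, 9, 10, 11, 14). A pure stage-5
#' profile scores the maximum weight (+2); a constitutive (flat) profile
#' scores 0. The score is invariant to rescaling of the densities.
#'
#' @param d numeric length-5 per-stage densities (sum > 0), or a matrix with
#'   5 columns (one score per row).
#' @param w numeric length-5 weights summing to 0.
#' @return numeric score(s).
#' @export
rhoScore <- function(d, w = c(2, 1, 0, -1, -2)) {
  if (abs(sum(w)) > 1e-9) stop("weights must sum to 0")
  if (is.matrix(d)) {
    tot <- rowSums(d)
    if (any(tot <= 0)) stop("all-zero density profile")
    return(as.numeric(d %*% w) / tot)
  }
  if (sum(d) <= 0) stop("all-zero density profile")
  sum(w * d) / sum(d)
}

#' Neighbour-pattern binomial test
#'
#' Tests whether genomically neighbouring DDEs share temporal polarity. Over
#' all pairs `(i, i + lag)` in genomic order where both elements lean
#' temporally (`|rho| > tau`), agreement of the rho signs is a Bernoulli
#' success; the p-value is the upper binomial tail at success probability
#' 1/2. With no eligible pairs the test is vacuous (p = 1).
#'
#' @param rhos numeric vector of DDE rho scores in genomic order.
#' @param lag neighbour offset (1 = adjacent, 2 = neighbour's neighbour, ...).
#' @param tau eligibility threshold on |rho|, default 0.5.
#' @return list with `p_value`, `successes`, `pairs`.
#' @export
neighborPatternTest <- function(rhos, lag = 1L, tau = 0.5) {
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  n <- length(rhos)
  if (n <= lag) return(list(p_value = 1, successes = 0L, pairs = 0L))
  a <- rhos[seq_len(n - lag)]
  b <- rhos[seq_len(n - lag) + lag]
  elig <- abs(a) > tau & abs(b) > tau
  np <- sum(elig)
  if (np == 0L) return(list(p_value = 1, successes = 0L, pairs = 0L))
  succ <- sum(sign(a[elig]) == sign(b[elig]))
  p <- pbinom(succ - 1L, np, 0.5, lower.tail = FALSE)
  list(p_value = p, successes = as.integer(succ), pairs = as.integer(np))
}

#' Regulator fraction across DDE-density-ranked gene bins
#'
#' Genes are ranked by their TSS DDE-density score (descending) and broken
#' into consecutive bins of `binGenes` genes (the last bin may be short); the
#' fraction of regulator-labelled genes in each bin is returned.
#'
#' @param tssDensity numeric DDE density at each gene's TSS.
#' @param regulator logical per-gene regulator label.
#' @param binGenes genes per bin, default 200.
#' @return data.frame with `bin`, `n`, `fraction`, `mean_density`.
#' @export
tssDensityRanking <- function(tssDensity, regulator, binGenes = 200L) {
  stopifnot(length(tssDensity) == length(regulator))
  ord <- order(-tssDensity, seq_along(tssDensity))
  reg <- regulator[ord]
  dens <- tssDensity[ord]
  bin <- (seq_along(reg) - 1L) %/% binGenes + 1L
  data.frame(bin = unique(bin),
             n = as.integer(tabulate(bin)),
             fraction = as.numeric(tapply(reg, bin, mean)),
             mean_density = as.numeric(tapply(dens, bin, mean)))
}
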