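## Genomic category assignment, interval-overlap binomial significance,
## conservation comparison, hypergeometric term enrichment, core-promoter
## clustering with motif enrichment, and peri-exonic accessibility profiles.

#' Genomic category of DHSs
#'
#' Assigns each DHS to exactly one category by the position of its central
#' nucleotide (left-rounded), with precedence
#' TSS (within 100 bp) > 5'UTR > CDS > intron > 3'UTR > intergenic.
#'
#' @param dhs GRanges of DHSs.
#' @param annot a [GenomeAnnotation].
#' @param tssWindow distance from a TSS counted as promoter-proximal,
#'   default 100 bp.
#' @return character vector of categories, one per DHS.
#' @export
assignCategory <- function(dhs, annot, tssWindow = 100L) {
  if (!length(dhs)) return(character(0))
  centers0 <- start(dhs) - 1L + width(dhs) %/% 2L
  cgr <- GRanges(seqnames(dhs), IRanges(centers0 + 1L, width = 1L))
  genes <- annot@genes
  out <- rep("intergenic", length(dhs))
  feats <- annot@features
  for (type in c("three_prime_UTR", "intron", "CDS", "five_prime_UTR")) {
    f <- feats[mcols(feats)$type == type]
    lab <- switch(type, five_prime_UTR = "5'UTR", CDS = "CDS",
                  intron = "intron", three_prime_UTR = "3'UTR")
    out[overlapsAny(cgr, f, ignore.strand = TRUE)] <- lab
  }
  if (length(genes)) {
    tss <- GRanges(seqnames(genes),
                   IRanges(mcols(genes)$tss + 1L - tssWindow,
                           mcols(genes)$tss + 1L + tssWindow))
    out[overlapsAny(cgr, tss, ignore.strand = TRUE)] <- "TSS"
  }
  out
}

#' Binomial interval-overlap test
#'
#' Fraction of query intervals overlapping any subject interval by at least
#' 1 bp, with an upper-tail binomial p-value under a uniform-placement null:
#' the per-query success probability is the fraction of the genome covered by
#' the (self-merged) subject set.
#'
#' @param query,subject GRanges on the same genome.
#' @param genome a Seqinfo.
#' @return list with `fraction`, `overlapping`, `n`, `coverage` (the null
#'   success probability) and `p_value`.
#' @export
overlapBinomial <- function(query, subject, genome) {
  gsz <- genomeSize(genome)
  if (gsz <= 0) stop("zero-length genome")
  merged <- reduce(granges(subject))
  q <- sum(as.numeric(width(merged))) / gsz
  n <- length(query)
  b <- sum(overlapsAny(query, merged, ignore.strand = TRUE))
  p <- if (b == 0L) 1 else pbinom(b - 1L, n, q, lower.tail = FALSE)
  list(fraction = if (n) b / n else NA_real_, overlapping = as.integer(b),
       n = as.integer(n), coverage = q, p_value = p)
}

## mean of a per-base score list over GRanges intervals
intervalMeans <- function(gr, track) {
  vapply(seq_along(gr), function(i) {
    v <- track[[as.character(seqnames(gr)[i])]]
    mean(v[start(gr)[i]:end(gr)[i]])
  }, numeric(1L))
}

#' Conservation of DDEs versus matched random locations
#'
#' Computes the per-element mean conservation score for the (non-coding) DDE
#' set and for a matched random set (equal count, equal sizes, uniformly
#' placed in non-coding sequence), and summarizes each as the median with a
#' 95 percent percentile-bootstrap confidence interval.
#'
#' @param ddes GRanges of non-coding DDE intervals.
#' @param track per-base score list ([simulateConservation] or
#'   [readConservation]).
#' @param genome a Seqinfo.
#' @param coding optional GRanges of coding sequence to exclude when placing
#'   the random set.
#' @param nBoot bootstrap replicates for the CIs, default 1000.
#' @param seed integer seed.
#' @return data.frame with rows `dde` and `random`; columns `median`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
conservationCompare <- function(ddes, track, genome, coding = NULL,
                                nBoot = 1000L, seed = 1L) {
  if (!length(ddes)) stop("empty DDE list")
  set.seed(splitSeed(seed, "random"))
  ddeMeans <- intervalMeans(ddes, track)
  ## matched random placement in non-coding sequence
  sl <- seqlengths(genome)
  sizes <- width(ddes)
  chrs <- sample(names(sl), length(sizes), replace = TRUE,
                 prob = as.numeric(sl) / sum(as.numeric(sl)))
  starts <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    repeat {
      s <- sample.int(sl[[chrs[i]]] - sizes[i], 1L)
      cand <- GRanges(chrs[i], IRanges(s, width = sizes[i]))
      if (is.null(coding) || !overlapsAny(cand, coding,
                                          ignore.strand = TRUE)) break
    }
    starts[i] <- s
  }
  rnd <- GRanges(chrs, IRanges(starts, width = sizes), seqinfo = genome)
  rndMeans <- intervalMeans(rnd, track)
  bootCI <- function(x) {
    meds <- vapply(seq_len(nBoot), function(b)
      median(x[sample.int(length(x), replace = TRUE)]), numeric(1L))
    quantile(meds, c(0.025, 0.975), names = FALSE)
  }
  ciD <- bootCI(ddeMeans); ciR <- bootCI(rndMeans)
  data.frame(set = c("dde", "random"),
             median = c(median(ddeMeans), median(rndMeans)),
             ci_lo = c(ciD[1], ciR[1]), ci_hi = c(ciD[2], ciR[2]),
             n = length(ddeMeans), row.names = c("dde", "random"))
}

#' Hypergeometric enrichment p-value
#'
#' Probability of drawing at least `b` genes carrying an annotation term in a
#' draw of `n` genes without replacement, given `B` term-carrying genes among
#' `N` total.
#'
#' @param b observed term-positive genes in the draw.
#' @param B term-positive genes in the population.
#' @param n draw size.
#' @param N population size.
#' @return upper-tail p-value `P(X >= b)`.
#' @export
hypergeomEnrichment <- function(b, B, n, N) {
  if (b < 0 || B > N || n > N || b > min(B, n))
    stop("inconsistent hypergeometric counts")
  if (b == 0) return(1)
  phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

## per-gene oriented core-promoter window [-up, +down] as GRanges
promoterWindows <- function(annot, up = 60L, down = 40L) {
  genes <- annot@genes
  tss <- mcols(genes)$tss  # 0-based
  plus <- as.character(strand(genes)) != "-"
  s0 <- ifelse(plus, tss - up, tss - down)
  e0 <- ifelse(plus, tss + down, tss + up)
  sl <- seqlengths(annot@seqinfo)[as.character(seqnames(genes))]
  GRanges(seqnames(genes),
          IRanges(pmax(s0, 0) + 1L, pmin(e0 + 1L, sl)),
          strand = strand(genes), seqinfo = annot@seqinfo,
          gene_id = mcols(genes)$gene_id)
}

#' Per-stage peak promoter accessibility
#'
#' For every gene and stage, the maximum bin density within the
#' strand-oriented core promoter window (-60 to +40 around the TSS).
#'
#' @param tracks named list of 5 [DensityTrack]s (names "5" ... "14"); for
#'   replicated data, pass per-stage averaged tracks or one replicate.
#' @param annot a [GenomeAnnotation].
#' @param up,down window extent upstream/downstream of the TSS in oriented
#'   coordinates (defaults 60 and 40).
#' @return numeric matrix genes x stages of peak densities.
#' @export
promoterProfiles <- function(tracks, annot, up = 60L, down = 40L) {
  win <- promoterWindows(annot, up, down)
  out <- matrix(0, length(win), length(tracks),
                dimnames = list(mcols(win)$gene_id, names(tracks)))
  for (si in seq_along(tracks)) {
    tr <- tracks[[si]]
    bs <- tr@binSize
    for (i in seq_along(win)) {
      chr <- as.character(seqnames(win)[i])
      i1 <- (start(win)[i] - 1L) %/% bs + 1L
      i2 <- (end(win)[i] - 1L) %/% bs + 1L
      v <- tr@scores[[chr]]
      out[i, si] <- max(v[i1:min(i2, length(v))])
    }
  }
  out
}

#' Cluster core-promoter accessibility profiles
#'
#' Promoter profiles are row-normalized to unit maximum (all-zero rows
#' dropped) and k-means clustered with a fixed seed. Each cluster's mean
#' profile assigns it to a metacluster by temporal trend: "up" if the
#' stage-14 mean exceeds 1.5x the stage-5 mean, "down" in the reverse case,
#' else "constitutive". Per cluster and motif, the fraction of member
#' promoters carrying the motif and its ratio to the genome-wide fraction are
#' reported.
#'
#' @param profiles genes x 5 matrix from [promoterProfiles()].
#' @param motifs logical matrix genes x motifs ([promoterMotifs]).
#' @param k number of clusters, default 10.
#' @param seed integer seed.
#' @param trendRatio metacluster trend threshold, default 1.5.
#' @return list: `cluster` (named assignment over retained genes), `centers`,
#'   `metacluster` (per cluster), `motifFraction` (clusters x motifs),
#'   `motifEnrichment` (ratio to genome-wide fraction), `dropped` (all-zero
#'   gene ids).
#' @export
clusterPromoters <- function(profiles, motifs, k = 10L, seed = 1L,
                             trendRatio = 1.5) {
  mx <- apply(profiles, 1L, max)
  keep <- mx > 0
  if (sum(keep) < k) stop("k exceeds the number of non-zero profiles")
  norm <- profiles[keep, , drop = FALSE] / mx[keep]
  uniq <- unique(norm)
  if (nrow(uniq) <= k) {
    cl <- match(apply(norm, 1L, paste, collapse = ","),
                apply(uniq, 1L, paste, collapse = ","))
    centers <- rbind(uniq, matrix(NA_real_, k - nrow(uniq), ncol(norm)))
  } else {
    set.seed(splitSeed(seed, "cluster"))
    km <- kmeans(norm, centers = k, nstart = 5L, iter.max = 50L)
    cl <- km$cluster
    centers <- km$centers
  }
  names(cl) <- rownames(norm)
  meta <- apply(centers, 1L, function(m) {
    if (any(is.na(m))) return(NA_character_)
    if (m[length(m)] > trendRatio * m[1L]) "up"
    else if (m[1L] > trendRatio * m[length(m)]) "down"
    else "constitutive"
  })
  motifs <- motifs[keep, , drop = FALSE]
  genomeFrac <- colMeans(motifs)
  mf <- t(vapply(seq_len(k), function(ci) {
    members <- cl == ci
    if (!any(members)) return(rep(NA_real_, ncol(motifs)))
    colMeans(motifs[members, , drop = FALSE])
  }, numeric(ncol(motifs))))
  colnames(mf) <- colnames(motifs)
  enr <- sweep(mf, 2L, ifelse(genomeFrac > 0, genomeFrac, NA_real_), "/")
  list(cluster = cl, centers = centers, metacluster = meta,
       motifFraction = mf, motifEnrichment = enr,
       genomeFraction = genomeFrac,
       dropped = rownames(profiles)[!keep])
}

#' Peri-exonic accessibility clustering
#'
#' Filters CDS exons to those at least `minExonLen` bp long whose nearest
#' other exon is at least `minFlank` bp away on both sides, computes
#' strand-aligned density arrays at `binSize` steps across +/- `minFlank` bp
#' of the 5' and 3' exon boundaries, k-means clusters the 5'-boundary arrays,
#' and reports per cluster the fraction of exons with elevated early
#' expression.
#'
#' @param track a [DensityTrack] (the stage to profile; the blastoderm stage
#'   is the conventional choice).
#' @param annot a [GenomeAnnotation].
#' @param expr named numeric vector of per-exon expression
#'   ([exonExpression]).
#' @param minExonLen minimum exon length, default 320.
#' @param minFlank minimum clear flank and profile half-width, default 300.
#' @param k clusters, default 4.
#' @param exprThreshold elevated-expression cutoff, default 25.
#' @param seed integer seed.
#' @return list: `exons` (GRanges retained), `profiles5`, `profiles3`
#'   (matrices), `cluster`, `elevatedFraction` (per cluster), or NULL (with a
#'   warning) if no exon passes the filters.
#' @export
periexonicAnalysis <- function(track, annot, expr, minExonLen = 320L,
                               minFlank = 300L, k = 4L, exprThreshold = 25,
                               seed = 1L) {
  feats <- annot@features
  ex <- feats[mcols(feats)$type == "CDS"]
  if (!length(ex)) { warning("no exons in annotation"); return(NULL) }
  exid <- sprintf("%s_ex%d", mcols(ex)$gene_id,
                  ave(seq_along(ex), mcols(ex)$gene_id, FUN = seq_along))
  ## distance to nearest other exon on each side
  keep <- rep(FALSE, length(ex))
  sl <- seqlengths(annot@seqinfo)
  for (i in seq_along(ex)) {
    if (width(ex)[i] < minExonLen) next
    others <- ex[-i]
    sameChr <- others[as.character(seqnames(others)) ==
                        as.character(seqnames(ex)[i])]
    dUp <- start(ex)[i] - 1L
    dDn <- sl[[as.character(seqnames(ex)[i])]] - end(ex)[i]
    if (length(sameChr)) {
      before <- sameChr[end(sameChr) < start(ex)[i]]
      after <- sameChr[start(sameChr) > end(ex)[i]]
      if (length(before)) dUp <- start(ex)[i] - max(end(before)) - 1L
      if (length(after)) dDn <- min(start(after)) - end(ex)[i] - 1L
      if (any(overlapsAny(ex[i], sameChr, ignore.strand = TRUE))) next
    }
    keep[i] <- dUp >= minFlank && dDn >= minFlank
  }
  if (!any(keep)) { warning("no exon passes the filters"); return(NULL) }
  ex <- ex[keep]; exid <- exid[keep]
  bs <- track@binSize
  offs <- seq(-minFlank, minFlank, by = bs)
  profAt <- function(chr, pos0, flip) {
    v <- track@scores[[chr]]
    idx <- pmax(pmin((pos0 + offs) %/% bs + 1L, length(v)), 1L)
    p <- v[idx]
    if (flip) rev(p) else p
  }
  n <- length(ex)
  prof5 <- matrix(0, n, length(offs))
  prof3 <- matrix(0, n, length(offs))
  for (i in seq_len(n)) {
    chr <- as.character(seqnames(ex)[i])
    minus <- as.character(strand(ex)[i]) == "-"
    b5 <- if (minus) end(ex)[i] - 1L else start(ex)[i] - 1L
    b3 <- if (minus) start(ex)[i] - 1L else end(ex)[i] - 1L
    prof5[i, ] <- profAt(chr, b5, minus)
    prof3[i, ] <- profAt(chr, b3, minus)
  }
  rownames(prof5) <- rownames(prof3) <- exid
  kk <- min(k, nrow(unique(prof5)))
  set.seed(splitSeed(seed, "cluster"))
  cl <- if (kk < 2L) rep(1L, n)
        else kmeans(prof5, centers = kk, nstart = 5L, iter.max = 50L)$cluster
  ev <- expr[exid] > exprThreshold
  frac <- vapply(seq_len(max(cl)), function(ci) {
    m <- cl == ci
    if (!any(m)) NA_real_ else mean(ev[m], na.rm = TRUE)
  }, numeric(1L))
  list(exons = ex, profiles5 = prof5, profiles3 = prof3,
       cluster = setNames(cl, exid), elevatedFraction = frac)
}

IUPAC_RE <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
              B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
              N = "[ACGT]")

#' IUPAC consensus motif match
#'
#' Tests whether an IUPAC-coded consensus occurs in a promoter sequence
#' (plumbing stand-in for a full PWM scanner; presence/absence only).
#'
#' @param sequence character promoter sequence over A, C, G, T (the oriented
#'   -60..+40 window).
#' @param consensus IUPAC consensus, e.g. "TCAKTY".
#' @return logical presence flag.
#' @export
motifMatch <- function(sequence, consensus) {
  sequence <- toupper(sequence)
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("empty consensus")
  if (grepl("[^ACGT]", sequence)) stop("invalid characters in sequence")
  if (any(!strsplit(consensus, "")[[1L]] %in% names(IUPAC_RE)))
    stop("invalid IUPAC code in consensus")
  pat <- Biostrings::DNAString(consensus)
  subj <- Biostrings::DNAString(sequence)
  Biostrings::countPattern(pat, subj,
                           fixed = c(pattern = FALSE, subject = TRUE)) > 0L
}
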