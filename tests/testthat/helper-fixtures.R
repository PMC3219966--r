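## Shared fixture builders: everything is generated in code at test time.

tinyGenome <- function(len = 1e5, chrom = "chr2L") makeGenome(chrom, len)

## DensityTrack with scores set directly (20-bp bins)
manualTrack <- function(scores, genome, binSize = 20L, window = 150L,
                        stage = "5", replicate = 1L) {
  if (!is.list(scores))
    scores <- setNames(list(scores), GenomeInfoDb::seqlevels(genome)[1])
  new("DensityTrack", binSize = as.integer(binSize),
      window = as.integer(window), scores = scores, seqinfo = genome,
      stage = stage, replicate = as.integer(replicate))
}

## hand-built annotation: one plus-strand and one minus-strand gene with a
## known TSS, one CDS exon each, plus intergenic space
twoGeneAnnotation <- function(genome = tinyGenome(2e4)) {
  ## gene A (+): TSS at 0-based 2000, 5'UTR 2000-2200, CDS 2200-2600,
  ##            intron 2600-3000, CDS 3000-3400, 3'UTR 3400-3600
  ## gene B (-): TSS at 0-based 15999, gene body 14000-16000
  genes <- GRanges(c("chr2L", "chr2L"),
                   IRanges(c(2001, 14001), c(3600, 16000)),
                   strand = c("+", "-"), seqinfo = genome)
  S4Vectors::mcols(genes)$gene_id <- c("geneA", "geneB")
  S4Vectors::mcols(genes)$tss <- c(2000L, 15999L)
  S4Vectors::mcols(genes)$regulator <- c(TRUE, FALSE)
  feats <- GRanges("chr2L",
                   IRanges(c(2001, 2201, 2601, 3001, 3401,
                             15601, 15001, 14001),
                           c(2200, 2600, 3000, 3400, 3600,
                             16000, 15600, 15000)),
                   strand = c(rep("+", 5), rep("-", 3)),
                   seqinfo = genome)
  S4Vectors::mcols(feats)$type <- c("five_prime_UTR", "CDS", "intron",
                                    "CDS", "three_prime_UTR",
                                    "five_prime_UTR", "CDS",
                                    "three_prime_UTR")
  S4Vectors::mcols(feats)$gene_id <- c(rep("geneA", 5), rep("geneB", 3))
  pm <- matrix(FALSE, 2, 10,
               dimnames = list(c("geneA", "geneB"),
                               c("TATA", "INR", "DPE", "DRE", "MTE",
                                 "r1", "r2", "r6", "r7", "DPEv")))
  expr <- setNames(c(30, 10, 40), c("geneA_ex1", "geneA_ex2", "geneB_ex1"))
  new("GenomeAnnotation", genes = genes, features = feats,
      promoterMotifs = pm, exonExpression = expr, seqinfo = genome)
}

## independent brute-force rank-expectation pipeline (plain loops; the
## implementation under test uses a C++ sliding median)
bruteRankExpectation <- function(a, b, localWindow) {
  keep <- which(a != 0 | b != 0)
  p <- rep(NA_real_, length(a))
  if (!length(keep)) return(p)
  ord <- order(b[keep], seq_along(keep))
  ap <- a[keep][ord]
  h <- (localWindow - 1L) %/% 2L
  n <- length(ap)
  m <- vapply(seq_len(n), function(i)
    median(ap[max(1L, i - h):min(n, i + h)]), numeric(1L))
  r <- abs(ap - m)
  s <- 1.4826 * vapply(seq_len(n), function(i)
    median(r[max(1L, i - h):min(n, i + h)]), numeric(1L))
  z <- ifelse(s > 0, (ap - m) / s, 0)
  p[keep[ord]] <- pnorm(z, lower.tail = FALSE)
  p
}

## brute-force accessible-region caller: direct counting at every tag
bruteRegions <- function(pos, len, W = 250L, L = 50000L, T, mergeGap = 250L) {
  z <- vapply(pos, function(at) {
    nw <- sum(pos >= at - W / 2 & pos < at + W / 2)
    lo <- max(at - L / 2, 0); hi <- min(at + L / 2, len)
    nl <- sum(pos >= lo & pos < hi)
    p <- W / (hi - lo)
    v <- nl * p * (1 - p)
    if (nl == 0 || v <= 0) return(NA_real_)
    (nw - nl * p) / sqrt(v)
  }, numeric(1L))
  qp <- pos[!is.na(z) & z >= T]
  if (!length(qp)) return(data.frame(s0 = integer(), e0 = integer()))
  qp <- sort(qp)
  runs <- list(); cur <- c(qp[1L], qp[1L])
  for (p1 in qp[-1L]) {
    if (p1 - cur[2L] <= mergeGap) cur[2L] <- p1
    else { runs[[length(runs) + 1L]] <- cur; cur <- c(p1, p1) }
  }
  runs[[length(runs) + 1L]] <- cur
  data.frame(s0 = vapply(runs, function(r) max(r[1L] - W %/% 2L, 0),
                         numeric(1L)),
             e0 = vapply(runs, function(r) min(r[2L] + W %/% 2L, len),
                         numeric(1L)))
}
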