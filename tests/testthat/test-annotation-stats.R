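test_that("category assignment uses the centre nucleotide with precedence", {
  ann <- twoGeneAnnotation()
  gn <- ann@seqinfo
  mk <- function(center0)
    GRanges("chr2L", IRanges(center0 + 1L - 75L, width = 150),
            seqinfo = gn)
  ## centre 50 bp upstream of geneA's TSS (tss = 2000)
  expect_equal(assignCategory(mk(1950), ann), "TSS")
  ## centre inside geneA's second CDS exon, > 100 bp from the TSS
  expect_equal(assignCategory(mk(3200), ann), "CDS")
  ## centre in the intron
  expect_equal(assignCategory(mk(2800), ann), "intron")
  ## centre between the two genes
  expect_equal(assignCategory(mk(9000), ann), "intergenic")
  ## 5'UTR beyond the 100-bp TSS window
  expect_equal(assignCategory(mk(2150), ann), "5'UTR")
  ## minus-strand gene: 3'UTR at the low-coordinate end
  expect_equal(assignCategory(mk(14500), ann), "3'UTR")
  ## every DHS gets exactly one category; counts sum to the DHS count
  set.seed(6)
  centers <- sample(200:19500, 60)
  cats <- assignCategory(do.call(c, lapply(centers, mk)), ann)
  expect_length(cats, 60)
  expect_true(all(cats %in% c("TSS", "5'UTR", "CDS", "intron", "3'UTR",
                              "intergenic")))
  expect_equal(sum(table(cats)), 60)
})

test_that("overlap binomial reproduces exact tail probabilities", {
  gn <- tinyGenome(1000)
  ## subjects cover 10% of the genome; all 10 point queries inside
  subj <- GRanges("chr2L", IRanges(401, 500), seqinfo = gn)
  q10 <- GRanges("chr2L", IRanges(seq(410, 490, length.out = 10),
                                  width = 1), seqinfo = gn)
  res <- overlapBinomial(q10, subj, gn)
  expect_equal(res$fraction, 1)
  expect_equal(res$coverage, 0.1)
  expect_equal(res$p_value, 1e-10, tolerance = 1e-9)
  ## no overlaps
  q0 <- GRanges("chr2L", IRanges(seq(10, 100, length.out = 10), width = 1),
                seqinfo = gn)
  expect_equal(overlapBinomial(q0, subj, gn)$p_value, 1)
  ## 5 of 10 successes at coverage 1/2: P(X >= 5) = 638/1024
  subj2 <- GRanges("chr2L", IRanges(501, 1000), seqinfo = gn)
  q5 <- GRanges("chr2L", IRanges(c(100, 200, 300, 400, 450,
                                   600, 700, 800, 900, 950), width = 1),
                seqinfo = gn)
  res5 <- overlapBinomial(q5, subj2, gn)
  expect_equal(res5$overlapping, 5L)
  expect_equal(res5$p_value, 638 / 1024, tolerance = 1e-12)
})

test_that("binomial overlap p agrees with a Monte-Carlo placement null", {
  gn <- tinyGenome(1e5)
  set.seed(11)
  subj <- reduce(GRanges("chr2L",
                         IRanges(sort(sample.int(99000, 40)), width = 500),
                         seqinfo = gn))
  cov <- sum(width(subj)) / 1e5
  n <- 15
  query <- GRanges("chr2L", IRanges(sample.int(99000, n), width = 1),
                   seqinfo = gn)
  res <- overlapBinomial(query, subj, gn)
  nPerm <- 10000
  hits <- matrix(sample.int(1e5, nPerm * n, replace = TRUE), nPerm, n)
  covBase <- rep(FALSE, 1e5)
  for (i in seq_along(subj))
    covBase[start(subj)[i]:end(subj)[i]] <- TRUE
  succ <- rowSums(matrix(covBase[hits], nPerm, n))
  mcP <- mean(succ >= res$overlapping)
  se <- sqrt(mcP * (1 - mcP) / nPerm)
  expect_lt(abs(res$p_value - mcP), 3 * se + 1e-6)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(hypergeomEnrichment(0, 5, 4, 10), 1)
  expect_equal(hypergeomEnrichment(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeomEnrichment(3, 3, 3, 6), 1 / 20, tolerance = 1e-12)
  expect_error(hypergeomEnrichment(5, 4, 4, 10), "inconsistent")
  ## random cases vs direct enumeration for N <= 50
  set.seed(12)
  for (i in 1:25) {
    N <- sample(5:50, 1)
    B <- sample(1:N, 1)
    n <- sample(1:N, 1)
    b <- sample(0:min(B, n), 1)
    enum <- sum(vapply(b:min(B, n), function(j)
      choose(B, j) * choose(N - B, n - j), numeric(1L))) / choose(N, n)
    expect_equal(hypergeomEnrichment(b, B, n, N), enum, tolerance = 1e-12)
  }
})

test_that("promoter profiles take the oriented -60..+40 peak density", {
  ann <- twoGeneAnnotation()
  gn <- ann@seqinfo
  zero <- rep(0, 1000)
  zt <- function(v, stage) manualTrack(v, gn, stage = stage)
  ## all-zero tracks -> all-zero profiles
  tracks0 <- setNames(lapply(c("5", "9", "10", "11", "14"),
                             function(s) zt(zero, s)),
                      c("5", "9", "10", "11", "14"))
  expect_true(all(promoterProfiles(tracks0, ann) == 0))
  ## bump at geneA's promoter (tss 2000, + strand) in stage 5 only
  v5 <- zero; v5[(2000 - 30) %/% 20 + 1] <- 9
  tracks <- tracks0; tracks[["5"]] <- zt(v5, "5")
  prof <- promoterProfiles(tracks, ann)
  expect_equal(unname(prof["geneA", ]), c(9, 0, 0, 0, 0))
  expect_true(all(prof["geneB", ] == 0))
  ## minus-strand gene: oriented -60..+40 covers genomic [tss-40, tss+60];
  ## a bump at genomic tss+55 (oriented upstream) must be seen for geneB
  vB <- zero; vB[(15999 + 55) %/% 20 + 1] <- 7
  profB <- promoterProfiles(setNames(list(zt(vB, "5")), "5"), ann)
  expect_equal(unname(profB["geneB", 1]), 7)
  ## while a bump at genomic tss+90 is outside the oriented window
  vC <- zero; vC[(15999 + 90) %/% 20 + 1] <- 7
  profC <- promoterProfiles(setNames(list(zt(vC, "5")), "5"), ann)
  expect_equal(unname(profC["geneB", 1]), 0)
})

test_that("promoter clustering recovers metaclusters and motif fractions", {
  set.seed(13)
  up <- t(replicate(40, c(0.1, 0.25, 0.5, 0.75, 1) * runif(1, 3, 6) +
                      runif(5, 0, 0.1)))
  down <- t(replicate(40, c(1, 0.75, 0.5, 0.25, 0.1) * runif(1, 3, 6) +
                        runif(5, 0, 0.1)))
  flat <- t(replicate(40, rep(runif(1, 3, 6), 5) + runif(5, 0, 0.1)))
  prof <- rbind(up, down, flat)
  rownames(prof) <- sprintf("g%03d", seq_len(nrow(prof)))
  motifs <- matrix(FALSE, 120, 2, dimnames = list(rownames(prof),
                                                  c("DRE", "INR")))
  motifs[41:80, "DRE"] <- TRUE   # DRE in the down family
  motifs[1:40, "INR"] <- TRUE    # INR in the up family
  res <- clusterPromoters(prof, motifs, k = 6, seed = 14)
  truthMeta <- rep(c("up", "down", "constitutive"), each = 40)
  gotMeta <- res$metacluster[res$cluster]
  expect_gte(mean(gotMeta == truthMeta), 0.95)
  ## motif fraction arithmetic: 8 of 10 vs genome fraction 0.2 -> 4.0
  prof2 <- matrix(runif(50, 1, 2), 10, 5)
  m2 <- matrix(FALSE, 10, 1, dimnames = list(NULL, "DRE"))
  m2[1:2, 1] <- TRUE
  prof2 <- rbind(prof2, prof2)  # 20 promoters, two identical halves
  m2 <- rbind(m2, !m2)          # overall DRE fraction 0.5
  ## direct check of the arithmetic without clustering noise:
  frac <- colMeans(m2[1:10, , drop = FALSE])
  expect_equal(unname(frac), 0.2)
  res2 <- clusterPromoters(matrix(rep(c(1, 2, 3, 4, 5), 10), 10, 5,
                                  byrow = TRUE),
                           matrix(c(rep(TRUE, 8), FALSE, FALSE), 10, 1,
                                  dimnames = list(NULL, "DRE")),
                           k = 1, seed = 1)
  expect_equal(unname(res2$motifFraction[1, "DRE"]), 0.8)
  expect_equal(unname(res2$motifEnrichment[1, "DRE"]), 1)
  expect_error(clusterPromoters(prof[1:3, ], motifs[1:3, ], k = 10),
               "exceeds")
})

test_that("peri-exonic analysis filters exons and summarizes expression", {
  ann <- twoGeneAnnotation()
  gn <- ann@seqinfo
  ## geneA exons are 400 bp (2200-2600, 3000-3400) with a 400-bp intron
  ## between them (< 2 * 300 is fine: the rule is distance >= 300), and
  ## geneB's exon is 600 bp at 15000-15600. Distances: exon1 <-> exon2 400;
  ## exon2 <-> exonB ~11600.
  tr <- manualTrack(rep(1, 1000), gn)
  res <- periexonicAnalysis(tr, ann, exonExpression(ann), minExonLen = 320,
                            minFlank = 300, k = 1, exprThreshold = 25)
  expect_equal(length(res$exons), 3L)
  ## raising the flank requirement to 500 keeps only geneB's exon
  res2 <- periexonicAnalysis(tr, ann, exonExpression(ann), minExonLen = 320,
                             minFlank = 500, k = 1, exprThreshold = 25)
  expect_equal(length(res2$exons), 1L)
  expect_equal(S4Vectors::mcols(res2$exons)$gene_id, "geneB")
  ## expression fractions: exons (30, 10, 40) at threshold 25 -> 2/3
  expect_equal(res$elevatedFraction, 2 / 3)
  ## threshold 50: only the 40-signal exon fails too -> 0
  res50 <- periexonicAnalysis(tr, ann, exonExpression(ann), k = 1,
                              exprThreshold = 50)
  expect_equal(res50$elevatedFraction, 0)
  ## no exon passes an extreme filter
  expect_warning(
    out <- periexonicAnalysis(tr, ann, exonExpression(ann),
                              minExonLen = 5000),
    "filter")
  expect_null(out)
})

test_that("IUPAC consensus matching expands ambiguity codes", {
  expect_true(motifMatch("GGTATAAAGG", "TATAAA"))
  expect_false(motifMatch("GGCCGGCCGG", "TATAAA"))
  expect_true(motifMatch("AATCAGTTAA", "TCAKTY"))
  expect_false(motifMatch("AATCACTTAA", "TCAKTY"))  # K excludes C
  expect_error(motifMatch("ACGTN", "TATA"), "invalid")
  expect_error(motifMatch("ACGT", ""), "empty")
})

test_that("conservation comparison separates elevated DDEs from random", {
  gn <- tinyGenome(2e5)
  ddes <- GRanges("chr2L", IRanges(seq(10000, 180000, by = 10000) + 1,
                                   width = 400), seqinfo = gn)
  ## constant track: medians agree
  flat <- simulateConservation(gn, ddes, 0.3, 0.3, 0, seed = 1)
  resFlat <- conservationCompare(ddes, flat, gn, nBoot = 200, seed = 2)
  expect_equal(resFlat["dde", "median"], resFlat["random", "median"])
  ## elevated DDE scores: CIs separate
  tr <- simulateConservation(gn, ddes, 0.8, 0.2, 0.02, seed = 3)
  res <- conservationCompare(ddes, tr, gn, nBoot = 200, seed = 4)
  expect_gt(res["dde", "ci_lo"], res["random", "ci_hi"])
  ## deterministic under the seed
  res2 <- conservationCompare(ddes, tr, gn, nBoot = 200, seed = 4)
  expect_identical(res, res2)
  expect_error(conservationCompare(GRanges(seqinfo = gn), tr, gn), "empty")
})
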