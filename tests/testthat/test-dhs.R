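test_that("peak calling: one peak for monotone density, greedy for several", {
  gn <- tinyGenome(4000)
  ## monotone density within the region -> single DHS at the max bin
  sc <- rep(0, 200)
  sc[51:100] <- seq_len(50)  # rises to bin 100 (midpoint 1990)
  tr <- manualTrack(sc, gn)
  region <- GRanges("chr2L", IRanges(1001, 2000), seqinfo = gn)
  dhs <- callDHSPeaks(tr, region)
  expect_length(dhs, 1)
  expect_equal(width(dhs), 150)
  expect_equal(start(dhs) - 1L + 75L, 1990L)  # centred on max bin midpoint

  ## two equal maxima 400 bp apart -> two non-overlapping DHSs
  sc2 <- rep(0, 200)
  sc2[60] <- 10; sc2[80] <- 10   # midpoints 1190 and 1590
  sc2[c(59, 61, 79, 81)] <- 4
  tr2 <- manualTrack(sc2, gn)
  dhs2 <- callDHSPeaks(tr2, region)
  expect_length(dhs2, 2)
  expect_true(all(width(dhs2) == 150))
  expect_length(reduce(dhs2), 2)

  ## maxima only 100 bp apart -> the weaker one is suppressed
  sc3 <- rep(0, 200)
  sc3[60] <- 10; sc3[65] <- 9    # midpoints 1190 and 1290
  tr3 <- manualTrack(sc3, gn)
  dhs3 <- callDHSPeaks(tr3, region)
  expect_length(dhs3, 1)
  expect_equal(start(dhs3) - 1L + 75L, 1190L)

  ## all-zero density in the region -> no DHS, no error
  expect_length(callDHSPeaks(manualTrack(rep(0, 200), gn), region), 0)
})

test_that("equal-density ties resolve to the leftmost bin", {
  gn <- tinyGenome(4000)
  sc <- rep(0, 200)
  sc[70:73] <- 8  # plateau; leftmost bin midpoint 1390
  tr <- manualTrack(sc, gn)
  region <- GRanges("chr2L", IRanges(1001, 2000), seqinfo = gn)
  dhs <- callDHSPeaks(tr, region)
  expect_equal(start(dhs)[1] - 1L + 75L, 1390L)
})

test_that("replicate concordance enforces the 75-bp rule and is symmetric", {
  gn <- tinyGenome(5000)
  a <- GRanges("chr2L", IRanges(1001, 1150), seqinfo = gn)  # [1000,1150)
  S4Vectors::mcols(a)$stage <- "5"
  b75 <- GRanges("chr2L", IRanges(1076, 1225), seqinfo = gn) # overlap 75
  S4Vectors::mcols(b75)$stage <- "5"
  kept <- replicateConcordant(a, b75)
  expect_length(kept, 1)
  expect_equal(start(kept) - 1L, 1000L)
  expect_equal(end(kept), 1225L)  # union [1000, 1225)

  b74 <- GRanges("chr2L", IRanges(1077, 1226), seqinfo = gn) # overlap 74
  S4Vectors::mcols(b74)$stage <- "5"
  expect_length(replicateConcordant(a, b74), 0)

  ## identity: a list against itself is returned (self-merged)
  self <- replicateConcordant(a, a)
  expect_equal(start(self), start(a))
  expect_equal(end(self), end(a))

  ## symmetry in replicate labels
  s1 <- replicateConcordant(a, b75)
  s2 <- replicateConcordant(b75, a)
  expect_equal(start(s1), start(s2))
  expect_equal(end(s1), end(s2))
})

test_that("cross-stage union consensus merges transitively with flags", {
  gn <- tinyGenome(5000)
  mk <- function(s, e, stage) {
    g <- GRanges("chr2L", IRanges(s + 1L, e), seqinfo = gn)
    S4Vectors::mcols(g)$stage <- stage
    g
  }
  ## five disjoint lists pass through
  perStage <- list("5" = mk(0, 150, "5"), "9" = mk(1000, 1150, "9"),
                   "10" = mk(2000, 2150, "10"), "11" = mk(3000, 3150, "11"),
                   "14" = mk(4000, 4150, "14"))
  cons <- unionConsensus(perStage)
  expect_length(cons, 5)

  ## the same site at all 5 stages collapses to one record with 5 flags
  same <- lapply(c("5", "9", "10", "11", "14"), function(s) mk(500, 650, s))
  names(same) <- c("5", "9", "10", "11", "14")
  cons2 <- unionConsensus(same)
  expect_length(cons2, 1)
  expect_true(all(as.matrix(S4Vectors::mcols(cons2))))

  ## stage-5 [0,150) and stage-9 [100,250) merge to [0,250), flags {5,9}
  cons3 <- unionConsensus(list("5" = mk(0, 150, "5"),
                               "9" = mk(100, 250, "9")))
  expect_length(cons3, 1)
  expect_equal(start(cons3) - 1L, 0L)
  expect_equal(end(cons3), 250L)
  expect_true(S4Vectors::mcols(cons3)$present.5 &&
                S4Vectors::mcols(cons3)$present.9)
})

test_that("stage of origin is the earliest stage present", {
  gn <- tinyGenome(5000)
  g <- GRanges("chr2L", IRanges(c(1, 1001, 2001), width = 150),
               seqinfo = gn)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    present.5 = c(FALSE, TRUE, FALSE), present.9 = c(FALSE, TRUE, FALSE),
    present.10 = c(FALSE, FALSE, FALSE), present.11 = c(FALSE, FALSE, FALSE),
    present.14 = c(TRUE, TRUE, FALSE))
  expect_error(stageOfOrigin(g), "no presence")
  g <- g[1:2]
  out <- stageOfOrigin(g)
  expect_equal(S4Vectors::mcols(out)$origin_stage, c("14", "5"))
})

test_that("planted origin fractions are recovered from the consensus", {
  ## 55% of stage-14 sites planted as carried forward from stage 5
  gn <- makeGenome("chr2L", 1e6)
  starts <- seq(10000, 990000, length.out = 100)
  all14 <- GRanges("chr2L", IRanges(as.integer(starts) + 1L, width = 150),
                   seqinfo = gn)
  S4Vectors::mcols(all14)$stage <- "14"
  from5 <- all14[1:55]
  S4Vectors::mcols(from5)$stage <- "5"
  cons <- stageOfOrigin(unionConsensus(list("5" = from5, "14" = all14)))
  comp <- originComposition(cons)
  expect_equal(comp["14", "5"], 0.55)
  expect_equal(comp["14", "14"], 0.45)
})

test_that("planted DHSs are recovered accurately at 5x mean enrichment", {
  gn <- makeGenome("chr2L", 1e6)
  sites <- plantedSites(gn, "constitutive", seq(5e4, 95e4, by = 3e4))
  rec <- c(); cerr <- c()
  for (s in 1:2) {
    cfg <- SimulationConfig(gn, 0.05, sites, siteEnrichment = 2 * (5 - 1),
                            seed = 100 + s)
    tg <- simulateTags(cfg, "5", 1)
    reg <- callHotspots(tg, hotspotParams(), seed = s)
    dhs <- callDHSPeaks(binDensity(tg), reg)
    expect_true(all(width(dhs) == 150))
    ctrT <- (start(sites) - 1 + end(sites)) / 2
    ctrD <- (start(dhs) - 1 + end(dhs)) / 2
    hit <- overlapsAny(sites, dhs)
    rec <- c(rec, mean(hit))
    cerr <- c(cerr, vapply(ctrT[hit], function(x) min(abs(ctrD - x)),
                           numeric(1L)))
  }
  expect_gte(mean(rec), 0.9)
  expect_lte(median(cerr), 20)
})
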