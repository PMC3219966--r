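test_that("degenerate and null comparisons are controlled", {
  ## constant signals: s = 0 everywhere, z = 0, p = 0.5
  p <- rankExpectation(rep(3, 200), rep(3, 200), localWindow = 11)
  expect_true(all(p == 0.5))
  ## identical integer signals: nothing significant at BH q <= 0.05
  set.seed(1)
  a <- rpois(5000, 4)
  ps <- rankExpectation(a, a, localWindow = 1001)
  q <- p.adjust(ps, method = "BH")
  expect_lte(mean(q <= 0.05, na.rm = TRUE), 0.05)
  ## independent null replicates: significant fraction within the nominal
  set.seed(2)
  b <- rpois(5000, 4)
  q2 <- p.adjust(rankExpectation(a, b, localWindow = 1001), method = "BH")
  expect_lte(mean(q2 <= 0.05, na.rm = TRUE), 0.05)
  expect_error(rankExpectation(a, b[-1], 1001), "length")
  expect_error(rankExpectation(a, b, 1000), "odd")
})

test_that("an outlier bin attains the minimum p and matches brute force", {
  set.seed(7)
  b <- runif(3000, 1, 10)
  a <- b
  a[1234] <- b[1234] * 10
  p <- rankExpectation(a, b, localWindow = 301)
  expect_equal(which.min(p), 1234L)
  brute <- bruteRankExpectation(a, b, 301L)
  expect_equal(p, brute, tolerance = 1e-12)
  ## also on sparse integer data with zeros excluded
  set.seed(8)
  a2 <- rpois(2000, 2); b2 <- rpois(2000, 2)
  p2 <- rankExpectation(a2, b2, localWindow = 201)
  expect_equal(p2, bruteRankExpectation(a2, b2, 201L), tolerance = 1e-12)
  expect_true(all(is.na(p2[a2 == 0 & b2 == 0])))
})

test_that("the two polarities never flag the same bin", {
  set.seed(9)
  b <- rpois(4000, 5)
  a <- rpois(4000, 5)
  spikes <- sample(4000, 20)
  a[spikes[1:10]] <- a[spikes[1:10]] * 8 + 20
  b[spikes[11:20]] <- b[spikes[11:20]] * 8 + 20
  qa <- p.adjust(rankExpectation(a, b, 1001), "BH")
  qb <- p.adjust(rankExpectation(b, a, 1001), "BH")
  both <- !is.na(qa) & !is.na(qb) & qa <= 0.05 & qb <= 0.05
  expect_false(any(both))
})

test_that("consistency voting needs three of four significant calls", {
  n <- 400
  base <- matrix(runif(4 * n, 0.3, 1), ncol = 4)
  ## bin 1: 3 strong votes; bin 2: 2 votes; bin 3: 4 votes
  base[1, 1:3] <- 1e-12
  base[2, 1:2] <- 1e-12
  base[3, 1:4] <- 1e-12
  pv <- lapply(1:4, function(j) base[, j])
  fl <- consistentEnrichment(pv, qThreshold = 0.05)
  expect_true(fl[1])
  expect_false(fl[2])
  expect_true(fl[3])
  expect_error(consistentEnrichment(pv[1:3]), "4")
})

test_that("bins merge by adjacency and identical signature", {
  pairs <- orderedStagePairs()
  nb <- 30
  fl <- matrix(FALSE, nb, 20, dimnames = list(NULL, pairs))
  dens <- matrix(1, nb, 5)
  ## isolated flagged bin
  fl[5, "5>14"] <- TRUE
  ## five adjacent bins, same signature
  fl[10:14, "5>9"] <- TRUE
  ## two adjacent bins with different signatures
  fl[20, "5>14"] <- TRUE
  fl[21, "14>5"] <- TRUE
  ddes <- mergeDDEBins(fl, dens, genome = tinyGenome(600))
  expect_length(ddes, 4)
  w <- width(ddes)
  expect_equal(w[1], 20)    # isolated bin -> 20-bp DDE
  expect_equal(w[2], 100)   # run of five -> 100-bp DDE
  expect_equal(w[3], 20)
  expect_equal(w[4], 20)
  expect_equal(S4Vectors::mcols(ddes)$n_bins, c(1L, 5L, 1L, 1L))
})

test_that("temporal classification follows the enrichment rules", {
  pairs <- orderedStagePairs()
  sig <- function(on) paste(as.integer(pairs %in% on), collapse = "")
  ## enrichment of stage 5 over every other stage
  expect_equal(classifyTemporal(sig(c("5>9", "5>10", "5>11", "5>14")),
                                c(5, 1, 1, 1, 1)), "stage5")
  ## 5>14 and 9>14 only, peak at stage 5 -> early
  expect_equal(classifyTemporal(sig(c("5>14", "9>14")),
                                c(5, 4, 3, 2, 1)), "early")
  ## 5>10 and 14>10 (trough in the middle) -> mixed
  expect_equal(classifyTemporal(sig(c("5>10", "14>10")),
                                c(5, 2, 1, 2, 5)), "mixed")
  ## late: peak at 14, only later-over-earlier enrichments
  expect_equal(classifyTemporal(sig(c("14>5", "11>5")),
                                c(1, 2, 3, 4, 5)), "late")
  expect_error(classifyTemporal(sig(character(0)), c(1, 1, 1, 1, 1)),
               "empty")
})

test_that("class tabulation computes rounded percentages of the total", {
  counts <- c(stage5 = 193L, stage9 = 50L, stage10 = 21L, stage11 = 423L,
              stage14 = 1446L, early = 4431L, late = 4166L, mixed = 283L)
  tab <- tabulateClasses(counts, total = 11014)
  expect_equal(tab$percent[tab$class == "stage14"], 13.13)
  ## single element: 100.00
  one <- tabulateClasses(c(early = 1L))
  expect_equal(one$percent, 100)
  ## default total is the sum of counts; partition sums to ~100
  tab2 <- tabulateClasses(counts)
  expect_lt(abs(sum(tab2$percent) - 100), 0.05)
  expect_error(tabulateClasses(integer(0)), "empty")
})

test_that("profile clustering recovers planted families and degenerates safely", {
  set.seed(3)
  early <- t(replicate(40, c(1, 0.8, 0.6, 0.3, 0.1) + runif(5, 0, 0.02)))
  late <- t(replicate(40, c(0.1, 0.3, 0.6, 0.8, 1) + runif(5, 0, 0.02)))
  prof <- rbind(early, late)
  truth <- rep(1:2, each = 40)
  res <- clusterProfiles(prof, k = 2, seed = 5)
  expect_equal(mclust::adjustedRandIndex(res$cluster, truth), 1)
  ## clusters ordered by stage of peak: cluster 1 peaks earliest
  expect_lt(which.max(res$centers[1, ]), which.max(res$centers[2, ]))
  ## k = 1 puts everything together
  expect_true(all(clusterProfiles(prof, k = 1, seed = 5)$cluster == 1))
  ## identical profiles with k = 2: deterministic single non-empty cluster
  same <- matrix(rep(c(1, 1, 1, 1, 1), 10), ncol = 5, byrow = TRUE)
  deg <- clusterProfiles(same, k = 2, seed = 5)
  expect_true(all(deg$cluster == 1))
  expect_equal(deg$sizes, c(10L, 0L))
  expect_error(clusterProfiles(same, k = 20), "exceeds")
})
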