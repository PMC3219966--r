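## End-to-end pipeline: simulate -> density -> hotspots -> DHS -> DDE -> DDD
## -> annotate -> report. All stage outputs land in an output directory with
## deterministic formatting, so identical (config, seed) runs are
## byte-identical.

#' Demo planted-site layout
#'
#' Places blocks of same-class sites along the genome (one block per temporal
#' class, sites a few kb apart inside a block), so that similarly patterned
#' elements cluster as they do around developmental loci and domain calling
#' has planted structure to find.
#'
#' @param genome a Seqinfo.
#' @param nPerClass sites per temporal class, default 12.
#' @param spacing within-block site spacing in bp, default 3000.
#' @param classes temporal classes to plant.
#' @return GRanges from [plantedSites()].
#' @export
demoSiteLayout <- function(genome, nPerClass = 12L, spacing = 3000L,
                           classes = c("stage5", "stage9", "stage10",
                                       "stage11", "stage14", "early",
                                       "late", "mixed", "constitutive")) {
  sl <- seqlengths(genome)
  chr <- names(sl)[which.max(sl)]
  len <- sl[[chr]]
  nb <- length(classes)
  blockSpan <- len %/% (nb + 1L)
  starts <- integer(0); cls <- character(0)
  for (k in seq_len(nb)) {
    base <- (k - 1L) * blockSpan + blockSpan %/% 2L
    starts <- c(starts, base + (seq_len(nPerClass) - 1L) * spacing)
    cls <- c(cls, rep(classes[k], nPerClass))
  }
  plantedSites(genome, cls, starts, chrom = chr)
}

validateRunConfig <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$background_rate) || cfg$background_rate < 0)
    stop("config: background_rate must be a non-negative number")
  if (!num1(cfg$fdr) || cfg$fdr <= 0 || cfg$fdr >= 1)
    stop("config: fdr must be in (0, 1)")
  if (!num1(cfg$seed)) stop("config: seed must be a number")
  if (cfg$local_window %% 2 == 0) stop("config: local_window must be odd")
  if (any(cfg$chrom_lengths <= 0)) stop("config: chromosome lengths must be positive")
  invisible(TRUE)
}

averageTracks <- function(tracks) {
  t1 <- tracks[[1L]]
  scores <- t1@scores
  if (length(tracks) > 1L)
    for (chr in names(scores)) {
      for (j in 2:length(tracks))
        scores[[chr]] <- scores[[chr]] + tracks[[j]]@scores[[chr]]
      scores[[chr]] <- scores[[chr]] / length(tracks)
    }
  new("DensityTrack", binSize = t1@binSize, window = t1@window,
      scores = scores, seqinfo = t1@seqinfo, stage = t1@stage,
      replicate = 0L)
}

#' Chromosome/bin index table for a genome-wide bin concatenation
#' @param genome a Seqinfo.
#' @param binSize bp per bin, default 20.
#' @return data.frame with columns `chrom` and `bin` (1-based within
#'   chromosome), row order matching `unlist(trackScores(track))`.
#' @export
binInfoFromGenome <- function(genome, binSize = 20L) {
  sl <- seqlengths(genome)
  nb <- ceiling(sl / binSize)
  data.frame(chrom = rep(names(sl), nb),
             bin = unlist(lapply(nb, seq_len), use.names = FALSE))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates multi-stage, multi-replicate cleavage tags and annotations from
#' the configuration, then runs density calculation, FDR-controlled hotspot
#' calling, DHS peak calling with replicate concordance, the cross-stage
#' consensus with stage of origin, rank-expectation DDE detection with
#' temporal classification and clustering, bootstrap-calibrated DDD calling,
#' and the annotation statistics. Writes BED/bedGraph/TSV outputs plus a
#' summary report into `outDir` and returns the result objects invisibly.
#'
#' @param config from [readRunConfig()].
#' @param outDir output directory (created if needed); NULL is a
#'   configuration error.
#' @param seed overrides `config$seed` when non-NULL.
#' @param writeTagFiles also write the simulated tag BEDs (default FALSE;
#'   they are the largest outputs).
#' @return (invisibly) a list with all intermediate and final objects.
#' @export
runPipeline <- function(config = readRunConfig(), outDir, seed = NULL,
                        writeTagFiles = FALSE) {
  if (missing(outDir) || is.null(outDir) || !nzchar(outDir))
    stop("config: output directory is required")
  validateRunConfig(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  genome <- makeGenome(config$chrom_names, config$chrom_lengths)
  sites <- demoSiteLayout(genome, nPerClass = config$n_sites_per_class)
  simcfg <- SimulationConfig(genome,
                             backgroundRate = config$background_rate,
                             sites = sites,
                             siteEnrichment = config$site_enrichment,
                             replicatesPerStage = config$replicates_per_stage,
                             seed = as.integer(config$seed))
  ann <- makeAnnotation(simcfg, nGenes = config$n_genes)
  params <- hotspotParams(config$scan_window, config$background_span,
                          config$fdr, config$merge_gap)
  nrep <- config$replicates_per_stage
  tags <- list(); tracks <- list(); regions <- list(); dhs <- list()
  for (st in DEV_STAGES) {
    for (rp in seq_len(nrep)) {
      key <- paste0(st, ".", rp)
      tg <- simulateTags(simcfg, st, rp)
      tr <- binDensity(tg, config$bin_size, config$window)
      rg <- callHotspots(tg, params,
                         seed = splitSeed(config$seed, "fdr",
                                          match(st, DEV_STAGES) * 10L + rp))
      tags[[key]] <- tg; tracks[[key]] <- tr; regions[[key]] <- rg
      dhs[[key]] <- callDHSPeaks(tr, rg)
      if (writeTagFiles)
        writeTags(tg, file.path(outDir, sprintf("tags_stage%s_rep%d.bed",
                                                st, rp)))
      writeBedGraph(tr, file.path(outDir,
                                  sprintf("density_stage%s_rep%d.bedgraph",
                                          st, rp)))
      writeRegionsBed(rg, file.path(outDir,
                                    sprintf("regions_stage%s_rep%d.bed",
                                            st, rp)))
    }
  }
  ## replicate-concordant per-stage DHS lists and consensus
  perStage <- list()
  for (st in DEV_STAGES) {
    perStage[[st]] <- replicateConcordant(dhs[[paste0(st, ".1")]],
                                          dhs[[paste0(st, ".2")]],
                                          minOverlap = config$min_overlap,
                                          stage = st)
    writeBed(perStage[[st]],
             file.path(outDir, sprintf("dhs_stage%s.bed", st)))
  }
  consensus <- stageOfOrigin(unionConsensus(perStage))
  writeBed(granges(consensus), file.path(outDir, "dhs_consensus.bed"))
  presence <- data.frame(chrom = as.character(seqnames(consensus)),
                         start0 = start(consensus) - 1L,
                         end0 = end(consensus),
                         as.data.frame(mcols(consensus)))
  writeTsv(presence, file.path(outDir, "dhs_consensus_presence.tsv"))
  originTab <- originComposition(consensus)
  categories <- assignCategory(consensus, ann$annotation)
  ## rank-expectation DDEs over all ordered stage pairs
  binInfo <- binInfoFromGenome(genome, config$bin_size)
  sigVec <- function(key) unlist(trackScores(tracks[[key]]),
                                 use.names = FALSE)
  stageMeans <- vapply(DEV_STAGES, function(st)
    (sigVec(paste0(st, ".1")) + sigVec(paste0(st, ".2"))) / 2,
    numeric(nrow(binInfo)))
  pairs <- orderedStagePairs()
  flagMat <- matrix(FALSE, nrow(binInfo), length(pairs),
                    dimnames = list(NULL, pairs))
  for (pr in pairs) {
    st <- strsplit(pr, ">")[[1L]]
    pv <- list()
    for (i in seq_len(2L)) for (j in seq_len(2L))
      pv[[length(pv) + 1L]] <- rankExpectation(
        sigVec(paste0(st[1L], ".", i)), sigVec(paste0(st[2L], ".", j)),
        localWindow = config$local_window)
    flagMat[, pr] <- consistentEnrichment(pv, config$q_threshold)
  }
  ddes <- mergeDDEBins(flagMat, stageMeans, binInfo,
                       binSize = config$bin_size, genome = genome)
  ddes <- if (length(ddes)) classifyDDEs(ddes) else ddes
  classTab <- if (length(ddes)) tabulateClasses(ddes) else
    data.frame(class = character(), count = integer(), percent = numeric())
  ddeBed <- data.frame(chrom = as.character(seqnames(ddes)),
                       start0 = start(ddes) - 1L, end0 = end(ddes),
                       name = if (length(ddes)) mcols(ddes)$temporal_class
                              else character(),
                       as.data.frame(mcols(ddes)[, paste0("d", DEV_STAGES)]))
  writeTsv(ddeBed, file.path(outDir, "ddes.tsv"))
  clusters <- if (length(ddes) >= 2L)
    clusterProfiles(ddes, k = min(config$k_dde_clusters, length(ddes)),
                    seed = as.integer(config$seed)) else NULL
  ## dynamic domains
  ddd <- NULL; rho <- NULL; neighborTests <- NULL
  if (length(ddes)) {
    densTrack <- ddeDensity(ddes, genome, radius = config$radius,
                            binSize = config$bin_size)
    null <- dddNull(ddes, genome, radius = config$radius,
                    nBoot = config$n_boot, seed = as.integer(config$seed))
    ddd <- callDDDs(densTrack, null, alpha = config$alpha, genome = genome,
                    genes = annotGenes(ann$annotation),
                    binSize = config$bin_size)
    dddTab <- data.frame(chrom = as.character(seqnames(ddd)),
                         start0 = start(ddd) - 1L, end0 = end(ddd),
                         as.data.frame(mcols(ddd)))
    writeTsv(dddTab, file.path(outDir, "ddds.tsv"))
    ord <- order(as.character(seqnames(ddes)), start(ddes))
    rho <- rhoScore(as.matrix(mcols(ddes)[, paste0("d", DEV_STAGES)]))
    neighborTests <- lapply(1:3, function(l)
      neighborPatternTest(rho[ord], lag = l, tau = config$tau))
    names(neighborTests) <- paste0("lag", 1:3)
    ## TSS DDE-density ranking
    genes <- annotGenes(ann$annotation)
    tssDens <- vapply(seq_along(genes), function(i) {
      chr <- as.character(seqnames(genes)[i])
      bi <- mcols(genes)$tss[i] %/% config$bin_size + 1L
      densTrack[[chr]][min(bi, length(densTrack[[chr]]))]
    }, numeric(1L))
    tssRank <- tssDensityRanking(tssDens, mcols(genes)$regulator,
                                 binGenes = 200L)
  } else tssRank <- NULL
  ## annotation statistics
  stageTracks <- lapply(DEV_STAGES, function(st)
    averageTracks(list(tracks[[paste0(st, ".1")]],
                       tracks[[paste0(st, ".2")]])))
  names(stageTracks) <- DEV_STAGES
  promProf <- promoterProfiles(stageTracks, ann$annotation)
  promClust <- tryCatch(
    clusterPromoters(promProf, promoterMotifs(ann$annotation),
                     k = min(config$k_promoter_clusters,
                             max(2L, sum(apply(promProf, 1, max) > 0) - 1L)),
                     seed = as.integer(config$seed)),
    error = function(e) NULL)
  periex <- suppressWarnings(
    periexonicAnalysis(stageTracks[["5"]], ann$annotation,
                       exonExpression(ann$annotation),
                       k = config$k_exon_clusters,
                       exprThreshold = config$expr_threshold,
                       seed = as.integer(config$seed)))
  crmOverlap <- overlapBinomial(sites, Reduce(c, lapply(unname(regions),
                                                        granges)),
                                genome)
  ## summary report
  sumPath <- file.path(outDir, "summary.tsv")
  con <- file(sumPath, "w")
  writeLines(sprintf("# seed\t%d", as.integer(config$seed)), con)
  for (k in sort(names(config)))
    writeLines(sprintf("# param\t%s\t%s", k,
                       paste(config[[k]], collapse = ",")), con)
  gsz <- genomeSize(genome)
  writeLines("table\tstage\tvalue1\tvalue2", con)
  for (st in DEV_STAGES) {
    cov <- sum(as.numeric(width(perStage[[st]])))
    writeLines(sprintf("dhs_per_stage\t%s\t%d\t%.4f", st,
                       length(perStage[[st]]), 100 * cov / gsz), con)
  }
  writeLines(sprintf("dhs_consensus\tall\t%d\t%.4f", length(consensus),
                     100 * sum(as.numeric(width(consensus))) / gsz), con)
  for (i in seq_len(nrow(classTab)))
    writeLines(sprintf("dde_class\t%s\t%d\t%.2f", classTab$class[i],
                       classTab$count[i], classTab$percent[i]), con)
  for (si in rownames(originTab))
    writeLines(sprintf("origin\t%s\t%s\t-", si,
                       paste(sprintf("%.4f", originTab[si, ]),
                             collapse = ",")), con)
  catTab <- table(categories)
  for (nm in names(catTab))
    writeLines(sprintf("dhs_category\t%s\t%d\t%.2f", nm, catTab[[nm]],
                       100 * catTab[[nm]] / length(categories)), con)
  if (!is.null(ddd))
    writeLines(sprintf("ddd\tall\t%d\t%.1f", length(ddd),
                       if (length(ddd)) mean(width(ddd)) else 0), con)
  writeLines(sprintf("crm_overlap\tall\t%.4f\t%.3g", crmOverlap$fraction,
                     crmOverlap$p_value), con)
  close(con)
  invisible(list(config = config, genome = genome, sites = sites,
                 annotation = ann$annotation, truth = ann$truth,
                 tags = tags, tracks = tracks, regions = regions,
                 dhs = dhs, perStage = perStage, consensus = consensus,
                 originTable = originTab, categories = categories,
                 flagMat = flagMat, ddes = ddes, classTable = classTab,
                 clusters = clusters, ddd = ddd, rho = rho,
                 neighborTests = neighborTests, tssRank = tssRank,
                 promoterProfiles = promProf, promoterClusters = promClust,
                 periexonic = periex, crmOverlap = crmOverlap))
}
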