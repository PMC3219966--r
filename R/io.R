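## Readers/writers for the interchange formats the pipeline touches.
## Genomic coordinates are GRanges (1-based, closed) in memory; BED and
## bedGraph on disk are 0-based half-open, GFF3 1-based closed; conversion
## happens at this boundary (via rtracklayer).

## cheap pre-validation so parse failures name the offending line
checkCoordinateColumns <- function(path, cols = c(2L, 3L), nSkip = 0L) {
  lines <- readLines(path, warn = FALSE)
  for (ln in seq_along(lines)) {
    if (ln <= nSkip) next
    l <- lines[[ln]]
    if (!nzchar(l) || startsWith(l, "#") || startsWith(l, "track")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < max(cols))
      stop(sprintf("%s: line %d has %d fields (need %d)", path, ln,
                   length(f), max(cols)))
    for (cc in cols)
      if (is.na(suppressWarnings(as.integer(f[cc]))))
        stop(sprintf("%s: line %d, column %d: non-integer coordinate '%s'",
                     path, ln, cc, f[cc]))
  }
  invisible(TRUE)
}

#' Read / write BED interval files
#'
#' `readBed` returns a GRanges (BED 0-based half-open converted to 1-based
#' closed); `writeBed` writes one, emitting the `name` and `score` metadata
#' columns when present. Malformed coordinate fields are reported with their
#' line number.
#'
#' @param path file path.
#' @param genome optional Seqinfo to attach; intervals outside its bounds
#'   are an error.
#' @return `readBed`: a GRanges.
#' @export
readBed <- function(path, genome = NULL) {
  checkCoordinateColumns(path)
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) {
    sl <- seqlengths(genome)
    bad <- !(as.character(seqnames(gr)) %in% names(sl)) |
      end(gr) > sl[as.character(seqnames(gr))]
    if (any(bad))
      stop("interval outside chromosome bounds at record ", which(bad)[1L])
    gr <- GRanges(as.character(seqnames(gr)), ranges(gr),
                  strand = strand(gr), seqinfo = genome)
  }
  gr
}

#' @rdname readBed
#' @param gr GRanges to write.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write fixed-step bedGraph tracks
#'
#' `writeBedGraph` serializes a [DensityTrack] as fixed 20-bp-step bedGraph;
#' `readBedGraph` returns the GRanges of scored steps.
#'
#' @param track a [DensityTrack].
#' @param path file path.
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track@binSize
  sl <- seqlengths(track@seqinfo)
  for (chr in names(track@scores)) {
    v <- track@scores[[chr]]
    nz <- which(v != 0)
    if (!length(nz)) next
    s0 <- (nz - 1L) * bs
    e0 <- pmin(nz * bs, sl[[chr]])
    writeLines(sprintf("%s\t%d\t%d\t%g", chr, s0, e0, v[nz]), con)
  }
  invisible(path)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(path) {
  checkCoordinateColumns(path)
  rtracklayer::import(path, format = "bedGraph")
}

#' Read a GFF3-like gene annotation
#'
#' Parses gene, five_prime_UTR, CDS, intron and three_prime_UTR features into
#' a [GenomeAnnotation] (GFF 1-based closed coordinates become the in-memory
#' GRanges convention directly). The TSS of each gene is its strand-dependent
#' 5' end.
#'
#' @param path GFF3 file path.
#' @param genome a Seqinfo.
#' @return a [GenomeAnnotation] (motif matrix and expression empty).
#' @export
readGff <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gid <- if (!is.null(genes$ID)) as.character(genes$ID)
         else as.character(genes$gene_id)
  g <- GRanges(as.character(seqnames(genes)), ranges(genes),
               strand = strand(genes), seqinfo = genome)
  mcols(g)$gene_id <- gid
  mcols(g)$tss <- ifelse(as.character(strand(g)) == "-",
                         end(g) - 1L, start(g) - 1L)
  mcols(g)$regulator <- FALSE
  feats <- gr[type %in% c("five_prime_UTR", "CDS", "intron",
                          "three_prime_UTR")]
  f <- GRanges(as.character(seqnames(feats)), ranges(feats),
               strand = strand(feats), seqinfo = genome)
  mcols(f)$type <- as.character(feats$type)
  mcols(f)$gene_id <- if (!is.null(feats$Parent))
    as.character(unlist(feats$Parent)) else as.character(feats$gene_id)
  new("GenomeAnnotation", genes = g, features = f,
      promoterMotifs = matrix(FALSE, length(g), 10,
                              dimnames = list(mcols(g)$gene_id,
                                              c("TATA", "INR", "DPE", "DRE",
                                                "MTE", "r1", "r2", "r6",
                                                "r7", "DPEv"))),
      exonExpression = numeric(), seqinfo = genome)
}

#' Read / write cleavage tag files
#'
#' Tags travel as 4-column BED (chrom, pos, pos+1, "tag"), 0-based
#' half-open.
#'
#' @param path file path.
#' @param genome a Seqinfo.
#' @param stage,replicate provenance labels for the TagSet.
#' @return `readTags`: a [TagSet].
#' @export
readTags <- function(path, genome, stage = "5", replicate = 1L) {
  checkCoordinateColumns(path)
  gr <- rtracklayer::import(path, format = "BED")
  pos <- split(start(gr) - 1L, as.character(seqnames(gr)))
  TagSet(as.list(pos), genome, stage = stage, replicate = replicate)
}

#' @rdname readTags
#' @param tags a [TagSet] to write.
#' @export
writeTags <- function(tags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(tags@positions)) {
    p <- tags@positions[[chr]]
    if (length(p))
      writeLines(sprintf("%s\t%d\t%d\ttag", chr, p, p + 1L), con)
  }
  invisible(path)
}

#' Write accessible regions as BED5
#'
#' The z-score is stored in the BED score column scaled by 10 (so one
#' decimal survives the integer score field).
#'
#' @param regions GRanges from [callAccessibleRegions()].
#' @param path file path.
#' @export
writeRegionsBed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(regions)) {
    z10 <- as.integer(round(mcols(regions)$max_z * 10))
    writeLines(sprintf("%s\t%d\t%d\tregion%d\t%d",
                       as.character(seqnames(regions)),
                       start(regions) - 1L, end(regions),
                       seq_along(regions), z10), con)
  }
  invisible(path)
}

#' Read a run configuration (key: value text)
#'
#' Minimal structured text config: one `key: value` pair per line, `#`
#' comments allowed. Numeric-looking values are converted. Defaults are
#' filled for all pipeline parameters; every parameter default equals the
#' method's reference operating value where one exists.
#'
#' @param path config file, or NULL for all defaults.
#' @param overrides named list overriding file values.
#' @return named list of parameters.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    chrom_names = "chr2L", chrom_lengths = 2e6,
    background_rate = 0.025, site_enrichment = 10,
    replicates_per_stage = 2, seed = 1,
    bin_size = 20, window = 150,
    scan_window = 250, background_span = 50000, fdr = 0.01,
    merge_gap = 250, min_overlap = 75,
    q_threshold = 0.05, local_window = 10001,
    radius = 10000, n_boot = 10000, alpha = 0.05,
    k_dde_clusters = 8, k_promoter_clusters = 10, k_exon_clusters = 4,
    expr_threshold = 25, tau = 0.5, n_genes = 40,
    n_sites_per_class = 12
  )
  vals <- defaults
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    for (ln in seq_along(lines)) {
      l <- trimws(lines[[ln]])
      if (!nzchar(l) || startsWith(l, "#")) next
      if (!grepl(":", l, fixed = TRUE))
        stop(sprintf("%s: line %d is not 'key: value'", path, ln))
      key <- trimws(sub(":.*", "", l))
      val <- trimws(sub("^[^:]*:", "", l))
      if (!key %in% names(defaults))
        stop(sprintf("%s: line %d: unknown parameter '%s'", path, ln, key))
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
      num <- suppressWarnings(as.numeric(parts))
      vals[[key]] <- if (any(is.na(num))) parts else num
    }
  }
  for (k in names(overrides)) {
    if (!k %in% names(defaults)) stop("unknown parameter: ", k)
    vals[[k]] <- overrides[[k]]
  }
  if (length(vals$chrom_names) != length(vals$chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length")
  vals
}
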