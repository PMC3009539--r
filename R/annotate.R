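## Genome-wide promoter annotation: score the -300/+200 window around each
## Pol-II peak on both strands, merge both-strand calls, assign calls to
## genes by the -2 kb/+500 bp rule, and summarize alternative promoter
## usage across samples.

#' Score both-strand windows around every peak with a trained model
#'
#' For each peak summit two 500 bp windows are scored: the -300/+200 window
#' in '+' orientation and the strand-flipped window in '-' orientation (the
#' sequence is reverse-complemented by the feature extractor). Windows whose
#' score reaches the threshold become promoter calls; both-strand calls on
#' one peak are merged into a single call ([mergeStrandCalls()]).
#'
#' @param peaks GRanges from [callPeaks()] (metadata `summit`, `name`).
#' @param model a [PromoterModel-class].
#' @param genome DNAStringSet from [readGenomeFasta()].
#' @param tracks named list of TagTrack lists (`polII`, `h3k4me3`, `cage`).
#' @param scales list of 22 property scales.
#' @param threshold promoter probability cutoff (default 0.5).
#' @param sampleId sample label stored with each call.
#' @param upstream,downstream window offsets (default 300/200).
#' @param ... further arguments to [featureMatrix()] (pooling, mask,
#'   allowMissingTracks).
#' @return GRanges of merged promoter calls with metadata `score`,
#'   `strands`, `peak`, `summit`, `sampleId`.
#' @export
scanPeaks <- function(peaks, model, genome, tracks,
                      scales = defaultPropertyScales(), threshold = 0.5,
                      sampleId = "NA", upstream = 300L, downstream = 200L,
                      ...) {
  empty <- GenomicRanges::GRanges(
    score = numeric(), strands = character(), peak = character(),
    summit = integer(), sampleId = character())
  if (length(peaks) == 0L) return(empty)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  win <- c(.recordWindows(chrom, peaks$summit, "+", upstream, downstream),
           .recordWindows(chrom, peaks$summit, "-", upstream, downstream))
  peakId <- rep(peaks$name, 2L)
  summit <- rep(peaks$summit, 2L)
  fm <- featureMatrix(win, genome, scales = scales, tracks = tracks, ...)
  pr <- predictPromoter(model, fm, threshold = threshold)
  keep <- pr$score >= threshold
  if (!any(keep)) return(empty)
  calls <- win[keep]
  S4Vectors::mcols(calls) <- NULL
  S4Vectors::mcols(calls)$score <- pr$score[keep]
  S4Vectors::mcols(calls)$strands <-
    as.character(GenomicRanges::strand(win))[keep]
  S4Vectors::mcols(calls)$peak <- peakId[keep]
  S4Vectors::mcols(calls)$summit <- summit[keep]
  S4Vectors::mcols(calls)$sampleId <- sampleId
  mergeStrandCalls(calls)
}

#' Merge both-strand promoter calls of the same peak
#'
#' When the plus- and minus-orientation windows of one peak are both called,
#' they collapse to their union interval with the maximum score and strand
#' support "+-"; they are counted as one promoter.
#'
#' @param calls GRanges of per-orientation calls (metadata `score`,
#'   `strands`, `peak`, `summit`, `sampleId`).
#' @return GRanges with one row per called peak.
#' @export
mergeStrandCalls <- function(calls) {
  if (length(calls) <= 1L) {
    GenomicRanges::strand(calls) <- "*"
    return(calls)
  }
  idx <- split(seq_along(calls), calls$peak)
  rows <- lapply(idx, function(i) {
    if (length(i) == 1L) return(calls[i])
    merged <- range(GenomicRanges::granges(calls[i]), ignore.strand = TRUE)
    S4Vectors::mcols(merged)$score <- max(calls$score[i])
    S4Vectors::mcols(merged)$strands <-
      paste(sort(unique(calls$strands[i])), collapse = "")
    S4Vectors::mcols(merged)$peak <- calls$peak[i][1]
    S4Vectors::mcols(merged)$summit <- calls$summit[i][1]
    S4Vectors::mcols(merged)$sampleId <- calls$sampleId[i][1]
    merged
  })
  out <- do.call(c, unname(rows))
  GenomicRanges::strand(out) <- "*"
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Assign promoter calls to genes by the -2 kb/+500 bp rule
#'
#' A call is assigned to a gene when its source-peak summit lies in the
#' strand-aware window from 2000 bp upstream to 500 bp downstream of the
#' gene's TSS, both boundaries inclusive. With several candidate genes the
#' nearest TSS wins; exact distance ties go to the smaller TSS coordinate.
#' Calls with no candidate gene are returned as unassigned (potential novel
#' promoters).
#'
#' @param calls GRanges from [scanPeaks()].
#' @param tssCatalog width-1 GRanges from [buildNonredundantTss()].
#' @param upstream,downstream assignment window in bp (default 2000/500).
#' @return list with GRanges `assigned` (metadata gains `gene_id`,
#'   `biotype`, `tss`) and `unassigned`.
#' @export
assignToGenes <- function(calls, tssCatalog,
                          upstream = 2000L, downstream = 500L) {
  if (length(calls) == 0L)
    return(list(assigned = calls, unassigned = calls))
  # inclusive [TSS - upstream, TSS + downstream] along transcription:
  # promoters() gives [t - up, t + down - 1], so widen downstream by 1
  win <- .anchorWindows(tssCatalog, upstream, downstream + 1L)
  summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(calls),
                                    IRanges::IRanges(calls$summit,
                                                     calls$summit))
  hit <- GenomicRanges::findOverlaps(summits, win, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  assignedIdx <- integer(0); geneIdx <- integer(0)
  if (length(qh)) {
    tssPos <- GenomicRanges::start(tssCatalog)[sh]
    dist <- abs(calls$summit[qh] - tssPos)
    ord <- order(qh, dist, tssPos)
    keep <- ord[!duplicated(qh[ord])]
    assignedIdx <- qh[keep]; geneIdx <- sh[keep]
  }
  assigned <- calls[assignedIdx]
  if (length(assignedIdx)) {
    S4Vectors::mcols(assigned)$gene_id <- tssCatalog$gene_id[geneIdx]
    S4Vectors::mcols(assigned)$biotype <- tssCatalog$biotype[geneIdx]
    S4Vectors::mcols(assigned)$tss <- GenomicRanges::start(tssCatalog)[geneIdx]
  } else {
    S4Vectors::mcols(assigned)$gene_id <- character(0)
    S4Vectors::mcols(assigned)$biotype <- character(0)
    S4Vectors::mcols(assigned)$tss <- integer(0)
  }
  unassigned <- calls[setdiff(seq_along(calls), assignedIdx)]
  list(assigned = assigned, unassigned = unassigned)
}

#' Combine assigned calls across samples into distinct promoters per gene
#'
#' Assigned calls for one gene from any number of samples are clustered by
#' single-linkage interval overlap (>= 1 bp): overlapping call windows chain
#' into one cluster, and each cluster counts as one distinct promoter. The
#' result is invariant to the order of the input samples.
#'
#' @param assignedCalls list of GRanges (one per sample) from
#'   [assignToGenes()]`$assigned`, or a single concatenated GRanges.
#' @return list with `promoters` (GRanges of cluster intervals, metadata
#'   `gene_id`, `biotype`, `cluster`, `nCalls`) and `genes` (data.frame
#'   `gene_id`, `biotype`, `promoterCount`).
#' @export
combineSamples <- function(assignedCalls) {
  calls <- if (is(assignedCalls, "GRanges")) assignedCalls
           else do.call(c, unname(lapply(assignedCalls, identity)))
  if (length(calls) == 0L)
    return(list(promoters = calls,
                genes = data.frame(gene_id = character(),
                                   biotype = character(),
                                   promoterCount = integer())))
  idx <- split(seq_along(calls), calls$gene_id)
  promRows <- list()
  geneRows <- list()
  for (g in names(idx)) {
    i <- idx[[g]]
    clust <- GenomicRanges::reduce(GenomicRanges::granges(calls[i]),
                                   ignore.strand = TRUE, min.gapwidth = 0L)
    nC <- GenomicRanges::countOverlaps(clust, calls[i], ignore.strand = TRUE)
    S4Vectors::mcols(clust)$gene_id <- g
    S4Vectors::mcols(clust)$biotype <- calls$biotype[i][1]
    S4Vectors::mcols(clust)$cluster <- paste0(g, "_p", seq_along(clust))
    S4Vectors::mcols(clust)$nCalls <- nC
    promRows[[g]] <- clust
    geneRows[[g]] <- data.frame(gene_id = g,
                                biotype = calls$biotype[i][1],
                                promoterCount = length(clust),
                                stringsAsFactors = FALSE)
  }
  list(promoters = do.call(c, unname(promRows)),
       genes = do.call(rbind, unname(geneRows)))
}

#' Summarize alternative-promoter usage per biotype
#'
#' Counts, per biotype, the genes with exactly one, exactly two, and three
#' or more distinct promoters, and the fraction of genes with two or more
#' (alternative promoter usage).
#'
#' @param genes data.frame from [combineSamples()]`$genes`.
#' @return data.frame with columns `biotype`, `one`, `two`, `threePlus`,
#'   `genes`, `fractionMultiple`.
#' @export
summarizeAlternativePromoters <- function(genes) {
  stopifnot(all(c("gene_id", "biotype", "promoterCount") %in% names(genes)))
  out <- lapply(split(genes, genes$biotype), function(df) {
    data.frame(biotype = df$biotype[1],
               one = sum(df$promoterCount == 1),
               two = sum(df$promoterCount == 2),
               threePlus = sum(df$promoterCount >= 3),
               genes = nrow(df),
               fractionMultiple = mean(df$promoterCount >= 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(out))
  rownames(out) <- NULL
  out
}
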