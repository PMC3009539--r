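## Rule-based construction of labeled promoter / non-promoter 500 bp records
## from Pol-II peaks, a TSS catalog and exclusion tracks.

## strand-aware promoter region around width-1 anchors:
## '+': [pos - up, pos + down - 1]; '-': [pos - down + 1, pos + up].
## anchors with strand '*' are treated as '+'.
.anchorWindows <- function(anchors, up, down) {
  gr <- anchors
  s <- as.character(GenomicRanges::strand(gr))
  GenomicRanges::strand(gr) <- ifelse(s == "-", "-", "+")
  GenomicRanges::promoters(gr, upstream = up, downstream = down)
}

#' Strand-aware TSS promoter windows
#'
#' The window covers `upstream` bases before and `downstream` bases from the
#' TSS along the direction of transcription (default -300 bp to +200 bp, a
#' 500 bp window).
#'
#' @param tss width-1 GRanges of TSS positions (stranded).
#' @param upstream bases upstream of the TSS (default 300).
#' @param downstream bases from the TSS onward (default 200).
#' @return GRanges of windows of width `upstream + downstream`.
#' @export
tssWindows <- function(tss, upstream = 300L, downstream = 200L) {
  .anchorWindows(tss, upstream, downstream)
}

## the 500 bp record window anchored on a summit, oriented by strand
.recordWindows <- function(chrom, summit, strand,
                           upstream = 300L, downstream = 200L) {
  anchors <- GenomicRanges::GRanges(chrom, IRanges::IRanges(summit, summit),
                                    strand = strand)
  .anchorWindows(anchors, upstream, downstream)
}

#' Label peaks whose summit falls in a TSS promoter window
#'
#' A peak whose summit lies within -300 bp to +200 bp (strand-aware) of any
#' catalog TSS yields one promoter record: a 500 bp window anchored on the
#' peak summit with the same -300/+200 offsets, oriented by the strand of
#' the matched TSS (nearest TSS on ties, then smaller coordinate). One peak
#' yields at most one record however many TSSs it reaches.
#'
#' @param peaks GRanges from [callPeaks()] (metadata `summit`, `name`).
#' @param tssCatalog width-1 GRanges from [buildNonredundantTss()].
#' @param tissue tissue/sample label stored with each record.
#' @param upstream,downstream promoter window offsets (default 300/200).
#' @param mode `"summit"` (default) tests the peak summit against the TSS
#'   window; `"overlap"` tests any overlap of the peak interval.
#' @return GRanges of 500 bp records with metadata `label` ("promoter"),
#'   `tissue`, `sourcePeak`, `summit`, `gene_id`.
#' @export
labelPromoterPeaks <- function(peaks, tssCatalog, tissue = "NA",
                               upstream = 300L, downstream = 200L,
                               mode = c("summit", "overlap")) {
  mode <- match.arg(mode)
  empty <- GenomicRanges::GRanges(
    label = character(), tissue = character(), sourcePeak = character(),
    summit = integer(), gene_id = character())
  if (length(peaks) == 0L || length(tssCatalog) == 0L) return(empty)
  win <- tssWindows(tssCatalog, upstream, downstream)
  query <- if (mode == "summit")
    GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                           IRanges::IRanges(peaks$summit, peaks$summit))
  else GenomicRanges::granges(peaks)
  hit <- GenomicRanges::findOverlaps(query, win, ignore.strand = TRUE)
  if (length(hit) == 0L) return(empty)

  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  # one record per peak: nearest TSS, ties to the smaller coordinate
  dist <- abs(peaks$summit[qh] - GenomicRanges::start(tssCatalog)[sh])
  ord <- order(qh, dist, GenomicRanges::start(tssCatalog)[sh])
  keep <- ord[!duplicated(qh[ord])]
  qh <- qh[keep]; sh <- sh[keep]

  rec <- .recordWindows(as.character(GenomicRanges::seqnames(peaks))[qh],
                        peaks$summit[qh],
                        as.character(GenomicRanges::strand(tssCatalog))[sh],
                        upstream, downstream)
  S4Vectors::mcols(rec)$label <- "promoter"
  S4Vectors::mcols(rec)$tissue <- tissue
  S4Vectors::mcols(rec)$sourcePeak <- peaks$name[qh]
  S4Vectors::mcols(rec)$summit <- peaks$summit[qh]
  S4Vectors::mcols(rec)$gene_id <- tssCatalog$gene_id[sh]
  rec
}

#' Select non-promoter records from peaks inside gene bodies
#'
#' A peak yields a non-promoter record when (i) its summit lies inside a
#' gene body and its 500 bp record window lies entirely within that gene,
#' (ii) the summit is not within -300/+200 bp of any catalog TSS, (iii) the
#' host gene's own promoter window contains the summit of some peak (the
#' host transcript is Pol-II-bound at its promoter), and (iv) the record
#' window does not overlap any exclusion interval (homolog promoters, EST 5'
#' ends). Width-1 exclusion anchors are expanded to -300/+200 windows;
#' wider exclusion intervals are used as given.
#'
#' @param peaks GRanges from [callPeaks()].
#' @param genes GRanges of gene bodies from [readGeneTable()].
#' @param tssCatalog width-1 GRanges of all known TSSs.
#' @param exclusions GRanges of exclusion intervals or anchors (optional).
#' @param tissue tissue/sample label.
#' @param upstream,downstream promoter window offsets (default 300/200).
#' @return GRanges of 500 bp records with metadata `label`
#'   ("nonpromoter"), `tissue`, `sourcePeak`, `summit`, `gene_id` (host).
#' @export
selectNonpromoterPeaks <- function(peaks, genes, tssCatalog,
                                   exclusions = GenomicRanges::GRanges(),
                                   tissue = "NA",
                                   upstream = 300L, downstream = 200L) {
  empty <- GenomicRanges::GRanges(
    label = character(), tissue = character(), sourcePeak = character(),
    summit = integer(), gene_id = character())
  if (length(peaks) == 0L || length(genes) == 0L) return(empty)

  summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                    IRanges::IRanges(peaks$summit,
                                                     peaks$summit))
  tssWin <- tssWindows(tssCatalog, upstream, downstream)

  # (iii) per-gene promoter status: any peak summit in the gene's own
  # TSS window (TSS taken from the gene model itself)
  geneTss <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                    IRanges::IRanges(genes$tss, genes$tss),
                                    strand = GenomicRanges::strand(genes))
  geneProm <- tssWindows(geneTss, upstream, downstream)
  promBound <- GenomicRanges::countOverlaps(geneProm, summits,
                                            ignore.strand = TRUE) > 0

  # (ii) summit near any TSS disqualifies
  nearTss <- GenomicRanges::countOverlaps(summits, tssWin,
                                          ignore.strand = TRUE) > 0

  # (i) summit inside a gene with a bound promoter, and the full record
  # window inside that gene
  hit <- GenomicRanges::findOverlaps(summits, genes, type = "within",
                                     ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  ok <- promBound[sh] & !nearTss[qh]
  qh <- qh[ok]; sh <- sh[ok]
  if (length(qh) == 0L) return(empty)
  recAll <- .recordWindows(as.character(GenomicRanges::seqnames(peaks))[qh],
                           peaks$summit[qh],
                           as.character(GenomicRanges::strand(genes))[sh],
                           upstream, downstream)
  # pairwise containment of the record window in its host gene
  inside <- GenomicRanges::start(recAll) >= GenomicRanges::start(genes)[sh] &
    GenomicRanges::end(recAll) <= GenomicRanges::end(genes)[sh]
  qh <- qh[inside]; sh <- sh[inside]; recAll <- recAll[inside]
  if (length(qh) == 0L) return(empty)

  # one record per peak: host gene with the smallest start coordinate
  ord <- order(qh, GenomicRanges::start(genes)[sh])
  keep <- ord[!duplicated(qh[ord])]
  qh <- qh[keep]; sh <- sh[keep]; rec <- recAll[keep]

  # (iv) exclusion intervals: expand width-1 anchors to promoter windows
  if (length(exclusions) > 0L) {
    excl <- exclusions
    w1 <- GenomicRanges::width(excl) == 1L
    if (any(w1))
      excl <- c(.anchorWindows(excl[w1], upstream, downstream),
                excl[!w1])
    drop <- IRanges::overlapsAny(rec, excl, ignore.strand = TRUE)
    qh <- qh[!drop]; sh <- sh[!drop]; rec <- rec[!drop]
  }
  if (length(qh) == 0L) return(empty)

  S4Vectors::mcols(rec)$label <- "nonpromoter"
  S4Vectors::mcols(rec)$tissue <- tissue
  S4Vectors::mcols(rec)$sourcePeak <- peaks$name[qh]
  S4Vectors::mcols(rec)$summit <- peaks$summit[qh]
  S4Vectors::mcols(rec)$gene_id <- genes$gene_id[sh]
  rec
}

#' Remove non-promoter records overlapping promoter records across tissues
#'
#' Any non-promoter record whose window overlaps (>= 1 bp, either strand)
#' any promoter record from any tissue is dropped; the promoter set is
#' untouched. Applied after pooling records from all tissues.
#'
#' @param promoterRecords,nonpromoterRecords GRanges of labeled records.
#' @return list with elements `promoter` and `nonpromoter`.
#' @export
deduplicateCrossTissue <- function(promoterRecords, nonpromoterRecords) {
  if (length(nonpromoterRecords) > 0L && length(promoterRecords) > 0L) {
    drop <- IRanges::overlapsAny(nonpromoterRecords, promoterRecords,
                                 ignore.strand = TRUE)
    nonpromoterRecords <- nonpromoterRecords[!drop]
  }
  list(promoter = promoterRecords, nonpromoter = nonpromoterRecords)
}

#' Stratified train/test split of labeled records
#'
#' Samples `trainFraction` of each label class (rounded to the nearest
#' integer) into the training set, reproducibly for a given seed.
#'
#' @param records GRanges with a `label` metadata column, or a data.frame
#'   with a `label` column.
#' @param trainFraction fraction of each class used for training
#'   (default 0.75).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive), plus the `seed`.
#' @export
splitTrainTest <- function(records, trainFraction = 0.75, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  label <- if (is(records, "GRanges")) records$label else records$label
  if (is.null(label))
    stop("records must carry a 'label' column")
  set.seed(seed)
  train <- integer()
  for (lv in unique(label)) {
    idx <- which(label == lv)
    nTrain <- round(length(idx) * trainFraction)
    train <- c(train, sort(sample(idx, nTrain)))
  }
  train <- sort(train)
  list(train = train,
       test = setdiff(seq_along(label), train),
       seed = as.integer(seed))
}
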