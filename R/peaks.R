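## Poisson-background peak calling: sliding windows scored against a global
## background rate, Benjamini-Hochberg control at the target FDR, merging of
## significant windows into enriched regions.

#' Upper-tail Poisson p-value
#'
#' `P(X >= count)` for `X ~ Poisson(lambda)`, computed through the stable
#' survival function. `poissonTail(0, lambda)` is 1 for any rate.
#'
#' @param count observed tag count (non-negative integer, vectorised).
#' @param lambda expected background count (> 0).
#' @return p-value in (0, 1].
#' @examples
#' poissonTail(3, 1)  # 1 - exp(-1) * (1 + 1 + 0.5) = 0.0803014
#' @export
poissonTail <- function(count, lambda) {
  stopifnot(all(lambda > 0), all(count >= 0))
  stats::ppois(count - 1, lambda, lower.tail = FALSE)
}

#' Call tag-enriched regions against a Poisson background
#'
#' Scores sliding windows by the upper-tail Poisson probability of their tag
#' count under a global background rate
#' `lambda = librarySize * windowBp / effectiveGenomeSize`, converts the
#' p-values to q-values by Benjamini-Hochberg, and merges overlapping or
#' adjacent windows passing the target FDR into enriched regions. Each
#' region reports its summit (leftmost base of maximal coverage), total tag
#' count, and the best window p- and q-value.
#'
#' @param track a [TagTrack-class].
#' @param windowBp sliding window size in bp (default 500).
#' @param stepBp step between window starts in bp (default 50).
#' @param fdr target false discovery rate (default 0.001).
#' @param effectiveGenomeSize genome size used for the background rate;
#'   defaults to the total covered length of the track.
#' @return GRanges of enriched regions with metadata columns `summit`,
#'   `tagCount`, `pValue`, `qValue` and `name`; empty when nothing passes.
#' @export
callPeaks <- function(track, windowBp = 500L, stepBp = 50L, fdr = 0.001,
                      effectiveGenomeSize = sum(trackSeqlengths(track))) {
  stopifnot(is(track, "TagTrack"), fdr > 0, fdr < 1,
            windowBp >= 1, stepBp >= 1)
  empty <- GenomicRanges::GRanges(
    summit = integer(), tagCount = numeric(),
    pValue = numeric(), qValue = numeric(), name = character())

  lambda <- track@librarySize * windowBp / effectiveGenomeSize
  if (lambda <= 0) return(empty)

  winChrom <- character(); winStart <- integer(); winCount <- numeric()
  for (ch in names(track@coverage)) {
    cov <- track@coverage[[ch]]
    if (length(cov) < windowBp) next
    cs <- cumsum(cov)
    starts <- seq.int(1L, length(cov) - windowBp + 1L, by = stepBp)
    prev <- numeric(length(starts))
    prev[starts > 1L] <- cs[starts[starts > 1L] - 1L]
    cnt <- cs[starts + windowBp - 1L] - prev
    winChrom <- c(winChrom, rep(ch, length(starts)))
    winStart <- c(winStart, starts)
    winCount <- c(winCount, cnt)
  }
  if (length(winStart) == 0L) return(empty)

  p <- poissonTail(winCount, lambda)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q <= fdr
  if (!any(sig)) return(empty)

  win <- GenomicRanges::GRanges(winChrom[sig],
                                IRanges::IRanges(winStart[sig],
                                                 winStart[sig] + windowBp - 1L))
  S4Vectors::mcols(win)$p <- p[sig]
  S4Vectors::mcols(win)$q <- q[sig]
  merged <- GenomicRanges::reduce(win, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(merged, win)
  byRegion <- split(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit))

  n <- length(merged)
  summit <- integer(n); tagCount <- numeric(n)
  pBest <- numeric(n); qBest <- numeric(n)
  for (i in seq_len(n)) {
    ch <- as.character(GenomicRanges::seqnames(merged)[i])
    lo <- GenomicRanges::start(merged)[i]
    hi <- min(GenomicRanges::end(merged)[i],
              length(track@coverage[[ch]]))
    seg <- track@coverage[[ch]][lo:hi]
    summit[i] <- lo + which.max(seg) - 1L   # leftmost maximum
    tagCount[i] <- sum(seg)
    ii <- byRegion[[as.character(i)]]
    pBest[i] <- min(win$p[ii])
    qBest[i] <- min(win$q[ii])
  }
  S4Vectors::mcols(merged)$summit <- summit
  S4Vectors::mcols(merged)$tagCount <- tagCount
  S4Vectors::mcols(merged)$pValue <- pBest
  S4Vectors::mcols(merged)$qValue <- qBest
  S4Vectors::mcols(merged)$name <- paste0("peak_", seq_len(n))
  merged
}

#' Per-base mask of significant regions
#'
#' True exactly inside the given peak intervals. Used to restrict feature
#' computation to tags that are part of significant regions.
#'
#' @param peaks GRanges of enriched regions.
#' @param chromSizes named vector of chromosome lengths.
#' @return named list of logical vectors, one per chromosome.
#' @export
significantRegionMask <- function(peaks, chromSizes) {
  mask <- lapply(chromSizes, function(n) logical(n))
  names(mask) <- names(chromSizes)
  if (length(peaks) == 0L) return(mask)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  for (i in seq_along(peaks)) {
    ch <- chroms[i]
    if (!ch %in% names(mask)) next
    lo <- max(1L, GenomicRanges::start(peaks)[i])
    hi <- min(length(mask[[ch]]), GenomicRanges::end(peaks)[i])
    if (lo <= hi) mask[[ch]][lo:hi] <- TRUE
  }
  mask
}

#' Write peak calls as BED6+ with p- and q-value columns
#'
#' @param peaks GRanges from [callPeaks()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePeaksBed <- function(peaks, path) {
  gr <- peaks
  S4Vectors::mcols(gr)$score <- round(-10 * log10(pmax(gr$pValue, 1e-300)), 2)
  writeBed(gr, path, extraCols = c("summit", "tagCount", "pValue", "qValue"))
}

#' Read peaks from a BED file produced by this package or an external caller
#'
#' External BED6 peaks without summit/tagCount columns get their interval
#' midpoint as summit.
#'
#' @param path BED path.
#' @return GRanges with `summit`, `tagCount`, `pValue`, `qValue`, `name`.
#' @export
readPeaksBed <- function(path) {
  gr <- readBed(path, extraCols = c("summit", "tagCount", "pValue", "qValue"))
  if (is.null(gr$summit))
    S4Vectors::mcols(gr)$summit <-
      as.integer((GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2)
  if (is.null(gr$tagCount)) S4Vectors::mcols(gr)$tagCount <- NA_real_
  if (is.null(gr$pValue)) S4Vectors::mcols(gr)$pValue <- NA_real_
  if (is.null(gr$qValue)) S4Vectors::mcols(gr)$qValue <- NA_real_
  if (is.null(gr$name)) S4Vectors::mcols(gr)$name <-
      paste0("peak_", seq_along(gr))
  gr
}
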