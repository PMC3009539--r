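# shared fixtures and independent oracles

# brute-force sliding-window k-mer counter (oracle for countKmers)
bruteKmers <- function(seq, k) {
  out <- stats::setNames(integer(4^k), allKmers(k))
  if (nchar(seq) < k) return(out)
  for (i in seq_len(nchar(seq) - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    if (grepl("^[ACGT]+$", w)) out[w] <- out[w] + 1L
  }
  out
}

# pairwise-comparison AUC (oracle for rocPoints trapezoid AUC)
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# 22 constant property scales named by the physchem features
# (k mirrors the packaged layout: 18 dinucleotide, 2 trinucleotide,
#  1 tetranucleotide, 1 mononucleotide)
constantScales <- function(value = 1) {
  ks <- c(rep(2L, 18L), 3L, 3L, 4L, 1L)
  nms <- promoterFeatureNames("physchem")
  ks <- stats::setNames(ks, c(nms[1:18], "trinuc_bendability",
                              "nucleosome_preference",
                              "tetranuc_flexibility", "eiip"))
  out <- lapply(nms, function(nm) {
    k <- ks[[nm]]
    propertyScale(nm, k, stats::setNames(rep(value, 4^k), allKmers(k)))
  })
  stats::setNames(out, nms)
}

# TagTrack from per-base coverage on one chromosome
mkTrack <- function(cov, assay = "polII", lib = NULL, chrom = "chr1",
                    sampleId = "t1") {
  if (is.null(lib)) lib <- max(sum(cov), 1)
  TagTrack(sampleId, assay, stats::setNames(list(cov), chrom), lib)
}

# peaks GRanges with given summits (minimal metadata, as from callPeaks)
mkPeaks <- function(summits, chrom = "chr1", halfWidth = 100L) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(pmax(1L, summits - halfWidth), summits + halfWidth))
  S4Vectors::mcols(gr)$summit <- as.integer(summits)
  S4Vectors::mcols(gr)$tagCount <- NA_real_
  S4Vectors::mcols(gr)$pValue <- NA_real_
  S4Vectors::mcols(gr)$qValue <- NA_real_
  S4Vectors::mcols(gr)$name <- paste0("peak_", seq_along(gr))
  gr
}

# width-1 TSS catalog
mkTss <- function(pos, strand, chrom = "chr1",
                  gene_id = paste0("g", seq_along(pos)),
                  biotype = "coding") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$tss <- as.integer(pos)
  S4Vectors::mcols(gr)$biotype <- rep_len(biotype, length(pos))
  S4Vectors::mcols(gr)$source <- "test"
  gr
}

# cached expensive fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

# benchmark at the study scale (~500 promoter / ~2000 non-promoter records)
acceptanceBenchmark <- function() {
  if (is.null(.fixtures$bm))
    .fixtures$bm <- makeBenchmark(simulationConfig(seed = 7))
  .fixtures$bm
}

# small benchmark for pipeline-level tests
miniBenchmark <- function() {
  if (is.null(.fixtures$mini))
    .fixtures$mini <- makeBenchmark(simulationConfig(seed = 11, nGenes = 40L))
  .fixtures$mini
}
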