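# helper to make minimal promoter calls with the scanPeaks metadata layout
.mkCalls <- function(starts, ends, peak, score = 0.9, gene = NULL,
                     sampleId = "s1", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr)$score <- rep_len(score, length(gr))
  S4Vectors::mcols(gr)$strands <- "+"
  S4Vectors::mcols(gr)$peak <- peak
  S4Vectors::mcols(gr)$summit <-
    as.integer((starts + ends) %/% 2)
  S4Vectors::mcols(gr)$sampleId <- sampleId
  if (!is.null(gene)) {
    S4Vectors::mcols(gr)$gene_id <- gene
    S4Vectors::mcols(gr)$biotype <- "coding"
  }
  gr
}

test_that("both-strand calls on one peak merge into a single promoter", {
  calls <- c(.mkCalls(9701L, 10200L, "peak_1"),
             .mkCalls(9802L, 10301L, "peak_1"))
  calls$strands <- c("+", "-")
  calls$score <- c(0.7, 0.9)
  merged <- mergeStrandCalls(calls)
  expect_length(merged, 1L)
  expect_equal(GenomicRanges::start(merged), 9701L)  # union interval
  expect_equal(GenomicRanges::end(merged), 10301L)
  expect_equal(merged$score, 0.9)                    # max score
  expect_equal(merged$strands, "+-")
})

test_that("calls on distinct peaks stay distinct through merging", {
  calls <- c(.mkCalls(9701L, 10200L, "peak_1"),
             .mkCalls(50001L, 50500L, "peak_2"))
  expect_length(mergeStrandCalls(calls), 2L)

  # toy enumeration: 3 peaks, both strands called on one of them
  calls3 <- c(.mkCalls(c(9701L, 9802L), c(10200L, 10301L), "peak_1"),
              .mkCalls(50001L, 50500L, "peak_2"),
              .mkCalls(90001L, 90500L, "peak_3"))
  expect_length(mergeStrandCalls(calls3), 3L)  # 1 merged + 2 single
})

test_that("gene assignment honours the inclusive -2 kb/+500 bp window", {
  tss <- mkTss(50001L, "+")
  mk <- function(summit) {
    gr <- .mkCalls(summit - 300L, summit + 199L, paste0("p", summit))
    gr$summit <- as.integer(summit)
    gr
  }
  # -2000 boundary inclusive: summit at TSS - 2000
  a <- assignToGenes(mk(48001L), tss)
  expect_length(a$assigned, 1L)
  expect_equal(a$assigned$gene_id, "g1")
  # one base further out: unassigned (potential novel promoter)
  b <- assignToGenes(mk(48000L), tss)
  expect_length(b$assigned, 0L)
  expect_length(b$unassigned, 1L)
  # +500 boundary inclusive, next base not
  expect_length(assignToGenes(mk(50501L), tss)$assigned, 1L)
  expect_length(assignToGenes(mk(50502L), tss)$assigned, 0L)

  # minus strand mirrors: window is [TSS-500, TSS+2000]
  tssM <- mkTss(50001L, "-")
  expect_length(assignToGenes(mk(52001L), tssM)$assigned, 1L)
  expect_length(assignToGenes(mk(52002L), tssM)$assigned, 0L)
  expect_length(assignToGenes(mk(49501L), tssM)$assigned, 1L)
  expect_length(assignToGenes(mk(49500L), tssM)$assigned, 0L)
})

test_that("assignment picks the nearest TSS, ties to the smaller coordinate", {
  tss <- mkTss(c(50001L, 51001L), c("+", "+"), gene_id = c("gL", "gR"))
  mk <- function(summit) {
    gr <- .mkCalls(summit - 300L, summit + 199L, "p1")
    gr$summit <- as.integer(summit)
    gr
  }
  expect_equal(assignToGenes(mk(50400L), tss)$assigned$gene_id, "gL")
  expect_equal(assignToGenes(mk(50700L), tss)$assigned$gene_id, "gR")
  # exactly equidistant: deterministic tie-break to the smaller coordinate
  expect_equal(assignToGenes(mk(50501L), tss)$assigned$gene_id, "gL")
})

test_that("assigned and unassigned calls partition the input", {
  tss <- mkTss(50001L, "+")
  calls <- c(.mkCalls(49701L, 50200L, "p1"),
             .mkCalls(99701L, 100200L, "p2"))
  calls$summit <- c(50001L, 100001L)
  a <- assignToGenes(calls, tss)
  expect_equal(length(a$assigned) + length(a$unassigned), length(calls))
  expect_equal(a$unassigned$peak, "p2")
})

test_that("combining samples clusters overlapping calls by single linkage", {
  # the same promoter seen in 7 samples, windows overlapping
  calls7 <- do.call(c, lapply(1:7, function(s)
    .mkCalls(10001L + 10L * s, 10500L + 10L * s, paste0("p", s), gene = "gA",
             sampleId = paste0("s", s))))
  comb <- combineSamples(calls7)
  expect_equal(nrow(comb$genes), 1L)
  expect_equal(comb$genes$promoterCount, 1L)
  expect_equal(comb$promoters$nCalls, 7L)

  # two non-overlapping windows near two TSSs of one gene
  two <- c(.mkCalls(10001L, 10500L, "p1", gene = "gA"),
           .mkCalls(20001L, 20500L, "p2", gene = "gA"))
  expect_equal(combineSamples(two)$genes$promoterCount, 2L)

  # chain A overlaps B, B overlaps C, A does not overlap C -> one cluster
  chain <- c(.mkCalls(10001L, 10500L, "pA", gene = "gA"),
             .mkCalls(10400L, 10900L, "pB", gene = "gA"),
             .mkCalls(10800L, 11300L, "pC", gene = "gA"))
  expect_equal(combineSamples(chain)$genes$promoterCount, 1L)
  # adjacency without overlap does not chain
  apart <- c(.mkCalls(10001L, 10500L, "pA", gene = "gA"),
             .mkCalls(10501L, 11000L, "pB", gene = "gA"))
  expect_equal(combineSamples(apart)$genes$promoterCount, 2L)

  # sample input order does not matter
  asList <- list(calls7[1:3], calls7[4:7])
  asListRev <- list(calls7[4:7], calls7[1:3])
  expect_equal(combineSamples(asList)$genes,
               combineSamples(asListRev)$genes)
})

test_that("alternative-promoter summary counts 1 / 2 / 3+ promoter genes", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      biotype = "coding",
                      promoterCount = c(1L, 1L, 2L, 3L))
  s <- summarizeAlternativePromoters(genes)
  expect_equal(s$one, 2L)
  expect_equal(s$two, 1L)
  expect_equal(s$threePlus, 1L)
  expect_equal(s$fractionMultiple, 0.5)
  expect_equal(s$one + s$two + s$threePlus, s$genes)

  allSingle <- data.frame(gene_id = letters[1:5], biotype = "coding",
                          promoterCount = 1L)
  expect_equal(summarizeAlternativePromoters(allSingle)$fractionMultiple, 0)

  mixed <- rbind(genes,
                 data.frame(gene_id = "e", biotype = "noncoding",
                            promoterCount = 2L))
  sm <- summarizeAlternativePromoters(mixed)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$genes[sm$biotype == "noncoding"], 1L)
})

test_that("scanning peaks end to end produces traceable, thresholded calls", {
  bm <- miniBenchmark()
  tr <- bm$split$train
  model <- trainModel(bm$features[tr, ], bm$labels[tr], ntree = 60,
                      seed = 21)
  calls <- scanPeaks(bm$peaks, model, bm$sim$genome,
                     bm$tracks[c("polII", "h3k4me3", "cage")],
                     threshold = 0.5, sampleId = "sim")
  expect_true(all(calls$score >= 0.5))
  # every call traces to exactly one source peak
  expect_lte(max(table(calls$peak)), 1L)
  expect_true(all(calls$peak %in% bm$peaks$name))

  # most true promoter peaks should be called, and assignment maps the
  # calls back to their genes
  asg <- assignToGenes(calls, bm$sim$tss)
  expect_equal(length(asg$assigned) + length(asg$unassigned), length(calls))
  comb <- combineSamples(asg$assigned)
  expect_true(all(comb$genes$promoterCount >= 1L))
})
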