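test_that("k-mer counting matches the printed toy cases and skips N windows", {
  expect_equal(countKmers("AAA", 2)[["AA"]], 2L)
  cg <- countKmers("CGCG", 2)
  expect_equal(cg[["CG"]], 2L)
  expect_equal(cg[["GC"]], 1L)
  expect_equal(sum(cg), 3L)
  # both dinucleotide windows of "ANA" contain N
  expect_equal(sum(countKmers("ANA", 2)), 0L)
  expect_error(countKmers("A", 2), "shorter")
})

test_that("k-mer counts agree with a brute-force oracle, with and without N", {
  set.seed(1)
  for (i in 1:150) {
    seq <- randomSeq(sample(20:60, 1),
                     alphabet = c("A", "C", "G", "T", "N"))
    for (k in 1:4)
      expect_equal(as.integer(countKmers(seq, k)),
                   as.integer(bruteKmers(seq, k)),
                   info = paste("seq", i, "k", k))
  }
})

test_that("composition features match the printed formulas on toy cases", {
  acgt <- strrep("ACGT", 125)  # 500 bp
  f <- compositionFeatures(acgt)
  expect_equal(unname(f[c("a_fraction", "c_fraction",
                          "g_fraction", "t_fraction")]),
               rep(0.25, 4))
  expect_equal(unname(f[c("purpyr_fraction", "amke_fraction",
                          "west_fraction")]), rep(0, 3))

  allA <- strrep("A", 500)
  fA <- compositionFeatures(allA)
  expect_equal(unname(fA["a_fraction"]), 1)
  expect_equal(unname(fA[c("cpg1", "cpg2", "cpg3")]), rep(0, 3))

  # CGCG: nCG = 2, nGC = 1 -> (2*2 + 2*1) / 3 = 2
  expect_equal(unname(compositionFeatures("CGCG")["cpg1"]), 2)
  # ACG: single trinucleotide window, nACG = 1, L - 2 = 1
  f3 <- compositionFeatures("ACG")
  expect_equal(unname(f3["cpg2"]), 1)
  expect_equal(unname(f3["cpg3"]), 0)

  # N contributes 0 to counts but L stays in the denominator
  expect_equal(unname(compositionFeatures("ANA")["a_fraction"]), 2 / 3)
})

test_that("composition identities hold on random N-free sequences", {
  set.seed(2)
  for (i in 1:50) {
    f <- compositionFeatures(randomSeq(sample(10:200, 1)))
    expect_equal(unname(f["a_fraction"] + f["c_fraction"] +
                          f["g_fraction"] + f["t_fraction"]), 1)
    expect_equal(unname(f["purpyr_fraction"] + f["amke_fraction"] +
                          f["west_fraction"]),
                 unname(4 * f["a_fraction"] - 1))
  }
})

test_that("reverse-complement symmetries of composition features", {
  set.seed(3)
  for (i in 1:25) {
    s <- randomSeq(sample(10:100, 1))
    f <- compositionFeatures(s)
    g <- compositionFeatures(revComp(s))
    expect_equal(unname(g["west_fraction"]), unname(f["west_fraction"]))
    expect_equal(unname(g["cpg1"]), unname(f["cpg1"]))
    expect_equal(unname(g["purpyr_fraction"]),
                 -unname(f["purpyr_fraction"]))
  }
})

test_that("property features: mean-per-window normalization and linearity", {
  # constant scale -> the constant, for any N-free window
  cs <- propertyScale("c", 2, stats::setNames(rep(3.5, 16), allKmers(2)))
  set.seed(4)
  expect_equal(propertyFeature(randomSeq(40), cs), 3.5)

  # phi(AA) = 1 else 0, "AAA": nAA = 2 over 2 windows -> 1
  v <- stats::setNames(rep(0, 16), allKmers(2)); v["AA"] <- 1
  expect_equal(propertyFeature("AAA", propertyScale("aa", 2, v)), 1)

  # "ACGT" with phi(AC)=1, phi(CG)=2, phi(GT)=3 -> (1+2+3)/3 = 2
  v2 <- stats::setNames(rep(0, 16), allKmers(2))
  v2[c("AC", "CG", "GT")] <- c(1, 2, 3)
  expect_equal(propertyFeature("ACGT", propertyScale("t", 2, v2)), 2)

  # linearity: scale 2*phi doubles the feature
  set.seed(5)
  v3 <- stats::setNames(runif(16), allKmers(2))
  s <- randomSeq(60)
  expect_equal(propertyFeature(s, propertyScale("x", 2, 2 * v3)),
               2 * propertyFeature(s, propertyScale("x", 2, v3)))

  # no valid window -> 0
  expect_equal(propertyFeature("NNNN", propertyScale("x", 2, v3)), 0)

  # a scale must be total over its k-mer set
  expect_error(propertyScale("bad", 2, v3[-1]), "k-mers")
})

test_that("signal features: closed forms, degenerate case, TPM invariance", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))

  # uniform coverage -> max/avg ratio 1
  f <- signalFeatures(win, mkTrack(rep(4, 500), lib = 1e6))
  expect_equal(unname(f["max_over_avg"]), 1)

  # single covered base h among 500
  h <- 7; lib <- 2e6
  cov <- numeric(500); cov[123] <- h
  f1 <- signalFeatures(win, mkTrack(cov, lib = lib))
  expect_equal(unname(f1["avg_tpm"]), h * 1e6 / (lib * 500))
  expect_equal(unname(f1["max_tpm"]), h * 1e6 / lib)
  expect_equal(unname(f1["max_over_avg"]), 500)

  # zero coverage -> all zero (ratio defined as 0)
  f0 <- signalFeatures(win, mkTrack(numeric(500), lib = 10))
  expect_equal(unname(f0), c(0, 0, 0))

  # scaling coverage and library together changes nothing
  set.seed(6)
  cov2 <- rpois(500, 2)
  a <- signalFeatures(win, mkTrack(cov2, lib = 1e5))
  b <- signalFeatures(win, mkTrack(cov2 * 3, lib = 3e5))
  expect_equal(a, b)
})

test_that("CAGE total TPM sums only tags inside the window", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 600))
  cov <- numeric(1000)
  cov[201:210] <- 1                       # 10 tags inside
  expect_equal(cageFeature(win, mkTrack(cov, "cage", lib = 1e6)), 10)
  expect_equal(cageFeature(win, mkTrack(numeric(1000), "cage", lib = 1e6)), 0)
  covOut <- numeric(1000); covOut[700:720] <- 5   # outside only
  expect_equal(cageFeature(win, mkTrack(covOut, "cage", lib = 1e6)), 0)
})

test_that("the 39-feature vector matches a componentwise hand computation", {
  seqChr <- paste0(strrep("T", 100), strrep("ACGT", 125), strrep("T", 100))
  genome <- Biostrings::DNAStringSet(c(chr1 = seqChr))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 600))
  covP <- numeric(700); covP[101:600] <- 2          # uniform Pol-II
  covH <- numeric(700); covH[301] <- 10             # one H3K4me3 spike
  covC <- numeric(700); covC[350:359] <- 3          # 30 CAGE tag-bases
  tracks <- list(polII = list(mkTrack(covP, "polII", lib = 1e6)),
                 h3k4me3 = list(mkTrack(covH, "h3k4me3", lib = 1e6)),
                 cage = list(mkTrack(covC, "cage", lib = 1e6)))
  fv <- extractFeatures(win, genome, scales = constantScales(2.25),
                        tracks = tracks)
  expect_equal(length(fv), 39L)
  expect_named(fv, promoterFeatureNames())
  expect_equal(unname(fv["a_fraction"]), 0.25)
  expect_equal(unname(fv["west_fraction"]), 0)
  # repeated ACGT: nCG = 125 and GC never occurs
  expect_equal(unname(fv["cpg1"]), 2 * 125 / 499)
  # constant scales give the constant for every property
  expect_equal(unname(fv[promoterFeatureNames("physchem")]),
               rep(2.25, 22))
  expect_equal(unname(fv["polII_avg_tpm"]), 2)
  expect_equal(unname(fv["polII_max_over_avg"]), 1)
  expect_equal(unname(fv["h3k4me3_max_tpm"]), 10)
  expect_equal(unname(fv["h3k4me3_avg_tpm"]), 10 / 500)
  expect_equal(unname(fv["h3k4me3_max_over_avg"]), 500)
  expect_equal(unname(fv["cage_total_tpm"]), 30)
})

test_that("an all-N window with no tracks yields the degenerate zero vector", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 600)))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 550))
  ws <- capture_warnings(
    fv <- extractFeatures(win, genome, scales = constantScales(9),
                          tracks = list(), allowMissingTracks = TRUE))
  expect_length(ws, 3L)  # one per missing assay
  expect_match(ws, "tracks supplied", all = TRUE)
  expect_equal(unname(fv), rep(0, 39))
  # but missing assays are an error by default
  expect_error(extractFeatures(win, genome, scales = constantScales(9)),
               "tracks supplied")
})

test_that("minus-strand windows are reverse-complemented for sequence features", {
  set.seed(7)
  s <- randomSeq(600)
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  winP <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 550),
                                 strand = "+")
  winM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 550),
                                 strand = "-")
  tracks <- list(polII = list(mkTrack(rpois(600, 1), lib = 1e4)),
                 h3k4me3 = list(mkTrack(rpois(600, 1), "h3k4me3", lib = 1e4)),
                 cage = list(mkTrack(rpois(600, 1), "cage", lib = 1e4)))
  fp <- extractFeatures(winP, genome, scales = constantScales(),
                        tracks = tracks)
  fm <- extractFeatures(winM, genome, scales = constantScales(),
                        tracks = tracks)
  expected <- compositionFeatures(revComp(substr(s, 51, 550)))
  expect_equal(fm[names(expected)], expected)
  # signal features ignore strand
  expect_equal(fm[promoterFeatureNames("experimental")],
               fp[promoterFeatureNames("experimental")])
})

test_that("windows beyond the chromosome edge are N-padded, not shortened", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 400)))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 700))
  tracks <- list(polII = list(mkTrack(rep(1, 400), lib = 1e4)),
                 h3k4me3 = list(mkTrack(rep(1, 400), "h3k4me3", lib = 1e4)),
                 cage = list(mkTrack(rep(1, 400), "cage", lib = 1e4)))
  fv <- extractFeatures(win, genome, scales = constantScales(),
                        tracks = tracks)
  # 200 real A bases over the fixed L = 500 denominator
  expect_equal(unname(fv["a_fraction"]), 200 / 500)
})

test_that("multi-sample pooling converts to TPM per sample before combining", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  cov <- numeric(500); cov[100] <- 10
  deep <- mkTrack(cov * 10, lib = 1e7)   # 10x depth, same relative signal
  shallow <- mkTrack(cov, lib = 1e6)
  fSum <- signalFeatures(win, list(deep, shallow))
  # per-sample max TPM is 10 for both, so the sum pooling gives 20
  expect_equal(unname(fSum["max_tpm"]), 20)
  fMean <- signalFeatures(win, list(deep, shallow), pooling = "mean")
  expect_equal(unname(fMean["max_tpm"]), unname(fSum["max_tpm"]) / 2)
})

test_that("significant-region masking zeroes coverage outside the mask", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  cov <- rep(1, 500); cov[200:210] <- 20
  mask <- list(chr1 = c(rep(FALSE, 199), rep(TRUE, 12), rep(FALSE, 289)))
  f <- signalFeatures(win, mkTrack(cov, lib = 1e6), mask = mask)
  # background singletons outside the mask do not contribute
  expect_equal(unname(f["avg_tpm"]), sum(cov[200:211]) * 1e6 / 1e6 / 500)
})

test_that("packaged synthetic scales load as 22 total mappings", {
  sc <- defaultPropertyScales()
  expect_length(sc, 22L)
  expect_identical(names(sc), promoterFeatureNames("physchem"))
  for (s in sc) expect_length(s@values, 4^s@k)
  ks <- vapply(sc, function(s) s@k, integer(1))
  expect_equal(unname(ks[c("eiip", "trinuc_bendability",
                           "tetranuc_flexibility")]), c(1L, 3L, 4L))
})
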