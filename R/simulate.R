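## Fully synthetic genomes, gene catalogs and tag tracks carrying the
## statistical structure the classifier exploits: CpG-enriched promoter
## sequence, Pol-II mass at promoters plus elongating-polymerase spread
## (linear 5'->3' decay with discrete pause bumps) through gene bodies,
## H3K4me3 promoter enrichment, CAGE tags concentrated at the TSS, and
## homogeneous Poisson background everywhere.

#' Simulation configuration
#'
#' Returns a validated configuration list for the synthetic-data generator.
#' Rates are tags per base; each base draws its tag count from a Poisson
#' with rate = background + the local signal terms, all multiplied by
#' `depth`. Defaults are chosen so that promoter peaks, internal gene-body
#' peaks and a ~1:4 promoter:non-promoter record ratio emerge at benchmark
#' scale.
#'
#' @param seed integer seed; every downstream draw is reproducible from it.
#' @param nGenes number of genes (default 500).
#' @param geneLength two-element range of gene body lengths in bp.
#' @param intergenic two-element range of intergenic gap lengths in bp.
#' @param cpgEnrichment odds multiplier applied to CG and GC transitions of
#'   the promoter dinucleotide Markov model (1 = no enrichment; default 5).
#' @param polIIBackground,polIIPromoter genome-wide background and promoter
#'   rates for Pol-II (tags/bp over the 500 bp truth window).
#' @param polIIBodyStart,polIIBodyEnd gene-body Pol-II rate at the 5' and 3'
#'   end; the rate decays linearly along transcription.
#' @param polIIPause extra rate over each gene-body pause site.
#' @param pausesPerGene number of discrete pause bumps per gene body.
#' @param pauseWidth width of each pause bump in bp.
#' @param h3k4me3Background,h3k4me3Promoter H3K4me3 rates; the promoter term
#'   covers `h3k4me3Width` bases centred on the TSS.
#' @param h3k4me3Width width of the H3K4me3 promoter domain in bp.
#' @param cageBackground,cageTss CAGE rates; the TSS term covers
#'   `cageWidth` bases centred on the TSS.
#' @param cageWidth width of the CAGE TSS footprint in bp.
#' @param depth global depth multiplier on all rates (default 1).
#' @param codingFraction fraction of genes labeled coding (default 0.9).
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 500L,
                             geneLength = c(6000L, 9000L),
                             intergenic = c(1000L, 2000L),
                             cpgEnrichment = 5,
                             polIIBackground = 0.01,
                             polIIPromoter = 0.5,
                             polIIBodyStart = 0.03,
                             polIIBodyEnd = 0.005,
                             polIIPause = 0.3,
                             pausesPerGene = 4L,
                             pauseWidth = 300L,
                             h3k4me3Background = 0.005,
                             h3k4me3Promoter = 0.4,
                             h3k4me3Width = 1000L,
                             cageBackground = 5e-4,
                             cageTss = 2,
                             cageWidth = 40L,
                             depth = 1,
                             codingFraction = 0.9) {
  cfg <- as.list(environment())
  rates <- c("cpgEnrichment", "polIIBackground", "polIIPromoter",
             "polIIBodyStart", "polIIBodyEnd", "polIIPause",
             "h3k4me3Background", "h3k4me3Promoter", "cageBackground",
             "cageTss", "depth")
  stopifnot(all(vapply(cfg[rates], function(v) is.numeric(v) && v >= 0,
                       logical(1))),
            cfg$depth > 0, cfg$nGenes >= 1,
            cfg$geneLength[1] >= 1500, diff(cfg$geneLength) >= 0,
            cfg$intergenic[1] >= 700,
            cfg$codingFraction >= 0, cfg$codingFraction <= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

## dinucleotide Markov sequence with CG/GC transition odds multiplied by f
.markovSeq <- function(n, f) {
  bases <- c("A", "C", "G", "T")
  P <- matrix(1, 4, 4, dimnames = list(bases, bases))
  P["C", "G"] <- f
  P["G", "C"] <- f
  P <- P / rowSums(P)
  out <- integer(n)
  out[1] <- sample.int(4, 1)
  for (i in 2:n)
    out[i] <- sample.int(4, 1, prob = P[out[i - 1], ])
  paste(bases[out], collapse = "")
}

#' Simulate a genome with CpG-enriched promoters and a gene catalog
#'
#' Background sequence is drawn from a uniform base model; each truth
#' promoter window (TSS - 300 to TSS + 200, strand-aware) is replaced by a
#' CpG-enriched dinucleotide Markov sequence. Genes are laid out left to
#' right with random strands and lengths; truth windows never overlap gene
#' bodies of other genes.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` (DNAStringSet, one chromosome "chr1"),
#'   `genes` (GRanges with `gene_id`, `tss`, `biotype`, `source`), `tss`
#'   (width-1 GRanges catalog) and `truth` (GRanges of true promoter
#'   windows).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nGenes
  glen <- round(runif(n, config$geneLength[1], config$geneLength[2]))
  gap <- round(runif(n, config$intergenic[1], config$intergenic[2]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  pos <- 1000L  # left margin so promoter windows stay in bounds
  for (i in seq_len(n)) {
    start[i] <- pos + gap[i]
    pos <- start[i] + glen[i]
  }
  genomeLength <- pos + 1000L
  tssPos <- ifelse(strand == "+", start, start + glen - 1L)

  base <- sample(c("A", "C", "G", "T"), genomeLength, replace = TRUE)
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start, start + glen - 1L),
                                  strand = strand)
  S4Vectors::mcols(genes)$gene_id <- sprintf("gene_%04d", seq_len(n))
  S4Vectors::mcols(genes)$tss <- as.integer(tssPos)
  S4Vectors::mcols(genes)$biotype <-
    ifelse(runif(n) < config$codingFraction, "coding", "noncoding")
  S4Vectors::mcols(genes)$source <- "simulated"

  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tssPos, tssPos),
                                strand = strand)
  S4Vectors::mcols(tss) <- S4Vectors::mcols(genes)
  truth <- tssWindows(tss)

  for (i in seq_len(n)) {
    lo <- GenomicRanges::start(truth)[i]
    hi <- GenomicRanges::end(truth)[i]
    base[lo:hi] <- strsplit(.markovSeq(hi - lo + 1L, config$cpgEnrichment),
                            "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- "chr1"
  list(genome = genome, genes = genes, tss = tss, truth = truth)
}

## per-base Poisson rate vectors for the three assays
.signalRates <- function(sim, config) {
  L <- Biostrings::width(sim$genome)[1]
  genes <- sim$genes
  polII <- rep(config$polIIBackground, L)
  h3k <- rep(config$h3k4me3Background, L)
  cage <- rep(config$cageBackground, L)
  pausePos <- list()
  for (i in seq_along(genes)) {
    gs <- GenomicRanges::start(genes)[i]
    ge <- GenomicRanges::end(genes)[i]
    plus <- as.character(GenomicRanges::strand(genes))[i] == "+"
    t <- genes$tss[i]
    # promoter bump over the truth window
    lo <- GenomicRanges::start(sim$truth)[i]
    hi <- GenomicRanges::end(sim$truth)[i]
    polII[lo:hi] <- polII[lo:hi] + config$polIIPromoter
    # elongating-polymerase spread: linear decay 5' -> 3'
    body <- gs:ge
    frac <- if (plus) (body - gs) / (ge - gs) else (ge - body) / (ge - gs)
    polII[body] <- polII[body] + config$polIIBodyStart +
      (config$polIIBodyEnd - config$polIIBodyStart) * frac
    # discrete pause bumps, kept clear of the TSS window and the gene ends
    k <- config$pausesPerGene
    if (k > 0) {
      margin <- 1200L
      inner <- if (plus) (gs + margin):(ge - 600L) else
        (gs + 600L):(ge - margin)
      slots <- seq(min(inner), max(inner),
                   length.out = k + 2L)[2:(k + 1L)]
      centers <- round(slots + runif(k, -100, 100))
      pausePos[[i]] <- as.integer(centers)
      for (p in centers) {
        w <- (p - config$pauseWidth %/% 2):(p + config$pauseWidth %/% 2)
        w <- w[w >= gs & w <= ge]
        polII[w] <- polII[w] + config$polIIPause
      }
    }
    # H3K4me3 promoter domain centred on the TSS
    hw <- config$h3k4me3Width %/% 2
    w <- max(1L, t - hw):min(L, t + hw)
    h3k[w] <- h3k[w] + config$h3k4me3Promoter
    # CAGE footprint at the TSS
    cw <- config$cageWidth %/% 2
    w <- max(1L, t - cw):min(L, t + cw)
    cage[w] <- cage[w] + config$cageTss
  }
  list(polII = polII * config$depth, h3k4me3 = h3k * config$depth,
       cage = cage * config$depth,
       pauseSites = pausePos)
}

#' Simulate Pol-II, H3K4me3 and CAGE tag tracks
#'
#' Per-base tag counts are Poisson draws from
#' background + promoter bump + gene-body spread (Pol-II only) +
#' TSS-concentrated term (CAGE only), all scaled by `depth`. Library size is
#' the realized total tag count of each track.
#'
#' @param sim output of [simulateGenome()].
#' @param config the same [simulationConfig()].
#' @return named list with elements `polII`, `h3k4me3`, `cage`, each a list
#'   of one [TagTrack-class], plus `pauseSites` (per-gene pause centers,
#'   the true non-promoter peak positions).
#' @export
simulateTags <- function(sim, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  rates <- .signalRates(sim, config)
  mk <- function(assay, rate) {
    cnt <- stats::rpois(length(rate), rate)
    TagTrack(paste0("sim_", assay), assay, list(chr1 = cnt),
             librarySize = max(sum(cnt), 1))
  }
  list(polII = list(mk("polII", rates$polII)),
       h3k4me3 = list(mk("h3k4me3", rates$h3k4me3)),
       cage = list(mk("cage", rates$cage)),
       pauseSites = rates$pauseSites)
}

#' Build a ready-to-train synthetic benchmark
#'
#' Runs the full upstream pipeline on simulated data: simulate genome and
#' tags, call Pol-II peaks at the target FDR, build labeled promoter /
#' non-promoter records by the summit rules, deduplicate, extract the
#' 39-feature matrix (with significant-region masking per assay when
#' `maskSignificant`), and split train/test.
#'
#' @param config a [simulationConfig()].
#' @param scales property scales (default the packaged synthetic ones).
#' @param fdr peak-calling FDR (default 0.001).
#' @param trainFraction train split fraction (default 0.75).
#' @param maskSignificant mask each assay's coverage outside its own called
#'   significant regions before feature computation (default TRUE).
#' @return list with `features` (data.frame), `labels` (character vector),
#'   `records` (GRanges), `split` (from [splitTrainTest()]), `peaks`,
#'   `tracks`, `sim` (genome/genes/tss/truth) and `config`.
#' @export
makeBenchmark <- function(config = simulationConfig(),
                          scales = defaultPropertyScales(), fdr = 0.001,
                          trainFraction = 0.75, maskSignificant = TRUE) {
  sim <- simulateGenome(config)
  tracks <- simulateTags(sim, config)
  peaks <- callPeaks(tracks$polII[[1]], fdr = fdr)

  prom <- labelPromoterPeaks(peaks, sim$tss, tissue = "sim")
  nonprom <- selectNonpromoterPeaks(peaks, sim$genes, sim$tss,
                                    tissue = "sim")
  dd <- deduplicateCrossTissue(prom, nonprom)
  records <- c(dd$promoter, dd$nonpromoter)
  if (length(records) == 0L)
    stop("simulation produced no labeled records")

  mask <- NULL
  if (maskSignificant) {
    sizes <- trackSeqlengths(tracks$polII[[1]])
    mask <- list(
      polII = significantRegionMask(peaks, sizes),
      h3k4me3 = significantRegionMask(
        callPeaks(tracks$h3k4me3[[1]], fdr = fdr), sizes),
      cage = significantRegionMask(
        callPeaks(tracks$cage[[1]], windowBp = 100L, stepBp = 20L,
                  fdr = fdr), sizes))
  }
  fm <- .featureMatrixPerAssayMask(records, sim$genome, scales,
                                   tracks[c("polII", "h3k4me3", "cage")],
                                   mask)
  labels <- records$label
  split <- splitTrainTest(records, trainFraction, seed = config$seed + 2L)
  list(features = fm, labels = labels, records = records, split = split,
       peaks = peaks, tracks = tracks, sim = sim, config = config)
}

## featureMatrix with a separate significance mask per assay: sequence
## features once, signal features per assay with its own mask
.featureMatrixPerAssayMask <- function(windows, genome, scales, tracks,
                                       masks) {
  if (is.null(masks))
    return(featureMatrix(windows, genome, scales = scales, tracks = tracks))
  fm <- featureMatrix(windows, genome, scales = scales, tracks = tracks,
                      mask = NULL)
  chroms <- as.character(GenomicRanges::seqnames(windows))
  starts <- GenomicRanges::start(windows)
  ends <- GenomicRanges::end(windows)
  for (assay in names(tracks)) {
    tr <- tracks[[assay]]
    m <- masks[[assay]]
    for (i in seq_along(windows)) {
      tpm <- .windowPooledTpm(chroms[i], starts[i], ends[i], tr, mask = m)
      if (assay == "cage") {
        fm[i, "cage_total_tpm"] <- sum(tpm)
      } else {
        avg <- mean(tpm); mx <- max(tpm)
        fm[i, paste0(assay, "_avg_tpm")] <- avg
        fm[i, paste0(assay, "_max_tpm")] <- mx
        fm[i, paste0(assay, "_max_over_avg")] <- if (avg > 0) mx / avg else 0
      }
    }
  }
  fm
}

#' Write simulated data to standard files
#'
#' Emits the genome FASTA, a UCSC-style gene table, the truth promoter BED
#' and one bedGraph per assay, so the pipeline can consume synthetic data
#' through the same readers as real data.
#'
#' @param sim output of [simulateGenome()].
#' @param tracks output of [simulateTags()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths.
#' @export
writeSimulatedData <- function(sim, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  genesPath <- file.path(dir, "genes.tsv")
  g <- sim$genes
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               strand = as.character(GenomicRanges::strand(g)),
               txStart = GenomicRanges::start(g) - 1L,
               txEnd = GenomicRanges::end(g),
               name = g$gene_id, biotype = g$biotype),
    genesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  truthPath <- file.path(dir, "truth_promoters.bed")
  tr <- sim$truth
  S4Vectors::mcols(tr)$name <- sim$genes$gene_id
  writeBed(tr, truthPath)
  trackPaths <- list()
  for (assay in c("polII", "h3k4me3", "cage")) {
    tt <- tracks[[assay]][[1]]
    p <- file.path(dir, paste0(assay, ".bedGraph"))
    cov <- tt@coverage[[1]]
    nz <- which(cov > 0)
    utils::write.table(
      data.frame(chrom = names(tt@coverage)[1], start = nz - 1L, end = nz,
                 value = cov[nz]),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    trackPaths[[assay]] <- p
  }
  c(list(genome = fa, genes = genesPath, truth = truthPath), trackPaths)
}
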