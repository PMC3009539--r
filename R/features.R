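## 39-feature representation of 500 bp windows:
## 10 composition/CpG features, 22 physico-chemical property features,
## 7 experimental signal features (CAGE / Pol-II / H3K4me3 TPM statistics).

.COMPOSITION_FEATURES <- c(
  "a_fraction", "c_fraction", "g_fraction", "t_fraction",
  "purpyr_fraction", "amke_fraction", "west_fraction",
  "cpg1", "cpg2", "cpg3")

.PHYSCHEM_FEATURES <- c(
  "a_philicity", "base_stacking", "bdna_twist", "bending_stiffness",
  "dinuc_flex_energy", "denaturation", "duplex_disrupt_energy",
  "duplex_free_energy", "helical_rise", "helical_twist", "helical_tilt",
  "helical_roll", "helical_shift", "helical_slide", "propeller_twist",
  "protein_deformability", "protein_dna_twist", "zdna_energy",
  "trinuc_bendability", "nucleosome_preference", "tetranuc_flexibility",
  "eiip")

.EXPERIMENTAL_FEATURES <- c(
  "cage_total_tpm",
  "polII_avg_tpm", "polII_max_tpm", "polII_max_over_avg",
  "h3k4me3_avg_tpm", "h3k4me3_max_tpm", "h3k4me3_max_over_avg")

#' Names of the 39 window features, in fixed column order
#'
#' Column order is fixed: 10 sequence-composition features, then the 22
#' physico-chemical property features, then the 7 experimental signal
#' features.
#'
#' @param group `"all"`, `"composition"`, `"physchem"` or `"experimental"`.
#' @return character vector of feature names.
#' @export
promoterFeatureNames <- function(group = c("all", "composition", "physchem",
                                           "experimental")) {
  group <- match.arg(group)
  switch(group,
    all = c(.COMPOSITION_FEATURES, .PHYSCHEM_FEATURES,
            .EXPERIMENTAL_FEATURES),
    composition = .COMPOSITION_FEATURES,
    physchem = .PHYSCHEM_FEATURES,
    experimental = .EXPERIMENTAL_FEATURES)
}

#' Count overlapping k-mers in a sequence
#'
#' Counts every overlapping k-mer window of the sequence; windows containing
#' a letter outside A/C/G/T (e.g. N) are skipped, so the counts sum to at
#' most `L - k + 1`.
#'
#' @param seq character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param k k-mer size, 1 to 4.
#' @return named integer vector of length `4^k` (lexicographic order).
#' @examples
#' countKmers("CGCG", 2)[c("CG", "GC")]  # 2 and 1
#' @export
countKmers <- function(seq, k) {
  stopifnot(k %in% 1:4)
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) < k)
    stop("sequence shorter than k")
  Biostrings::oligonucleotideFrequency(seq, width = k)
}

## k-mer count matrix for a set of windows (rows) at word size k
.kmerCountMatrix <- function(seqs, k) {
  Biostrings::oligonucleotideFrequency(seqs, width = k)
}

## composition features from k-mer count matrices; L = full window length
.compositionFromCounts <- function(c1, c2, c3, L) {
  n <- function(m, x) if (x %in% colnames(m)) m[, x] else 0
  a <- n(c1, "A"); c <- n(c1, "C"); g <- n(c1, "G"); t <- n(c1, "T")
  cpg2 <- (n(c3, "ACG") + n(c3, "AGC") + n(c3, "CAG") + n(c3, "CCG") +
           n(c3, "CGA") + n(c3, "CGC") + 2 * n(c3, "CGG") + n(c3, "CGT") +
           n(c3, "CTG") + n(c3, "GAC") + n(c3, "GCA") + 2 * n(c3, "GCC") +
           n(c3, "GCG") + n(c3, "GCT") + 2 * n(c3, "GGC") + n(c3, "GTC") +
           n(c3, "TCG") + n(c3, "TGC")) / (L - 2)
  cpg3 <- (4 * n(c3, "CAG") + n(c3, "CCG") + n(c3, "CGG") +
           4 * n(c3, "CTG") + 4 * n(c3, "GAC") + n(c3, "GCC") +
           n(c3, "GGC") + 4 * n(c3, "GTC")) / (L - 2)
  cbind(
    a_fraction = a / L, c_fraction = c / L,
    g_fraction = g / L, t_fraction = t / L,
    purpyr_fraction = (a + g - c - t) / L,
    amke_fraction = (a + c - g - t) / L,
    west_fraction = (a + t - c - g) / L,
    cpg1 = (2 * n(c2, "CG") + 2 * n(c2, "GC")) / (L - 1),
    cpg2 = cpg2, cpg3 = cpg3)
}

#' Sequence-composition and CpG features of one window
#'
#' Computes the 10 composition features: the four base fractions,
#' purine-pyrimidine, amino-keto and weak-strong skews, and the three
#' CpG-island statistics. Denominators are the fixed window lengths L, L-1
#' and L-2; N bases contribute 0 to every count but leave L unchanged.
#'
#' @param seq character string or DNAString (length >= 3).
#' @return named numeric vector of the 10 composition features.
#' @examples
#' compositionFeatures("CGCG")["cpg1"]  # (2*2 + 2*1) / 3 = 2
#' @export
compositionFeatures <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  L <- length(seq)
  if (L < 3)
    stop("window shorter than 3 bp")
  ss <- Biostrings::DNAStringSet(list(seq))
  out <- .compositionFromCounts(.kmerCountMatrix(ss, 1),
                                .kmerCountMatrix(ss, 2),
                                .kmerCountMatrix(ss, 3), L)
  out[1, ]
}

#' Physico-chemical property feature of one window
#'
#' The feature value is the mean scale value over all N-free k-mer windows
#' of the sequence: `sum(n_x * phi(x)) / sum(n_x)` where `n_x` counts k-mer
#' `x`. A window with no valid k-mer (e.g. all N) scores 0. The value is
#' linear in the scale and equals `c` for a constant scale `phi == c`.
#'
#' @param seq character string or DNAString.
#' @param scale a [PropertyScale-class].
#' @return a single finite numeric value.
#' @examples
#' sc <- propertyScale("toy", 2, setNames(rep(0, 16), allKmers(2)))
#' sc@values["AA"] <- 1
#' propertyFeature("AAA", propertyScale("toy", 2, sc@values))  # 1
#' @export
propertyFeature <- function(seq, scale) {
  stopifnot(is(scale, "PropertyScale"))
  counts <- countKmers(seq, scale@k)
  valid <- sum(counts)
  if (valid == 0) return(0)
  sum(counts * scale@values[names(counts)]) / valid
}

#' Read physico-chemical property scales from TSV
#'
#' The file must have a header and columns `property`, `k`, `kmer`, `value`
#' (extra columns such as `citation` or `provenance` are carried along).
#' Every property must define a value for all `4^k` k-mers.
#'
#' @param path path to the TSV.
#' @return named list of [PropertyScale-class] objects.
#' @export
readPropertyScales <- function(path) {
  if (!file.exists(path))
    stop("scale file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("property", "k", "kmer", "value")
  if (!all(need %in% names(tab)))
    stop("scale file must have columns: ", paste(need, collapse = ", "))
  cit <- if ("citation" %in% names(tab)) tab$citation else ""
  out <- lapply(split(seq_len(nrow(tab)), tab$property), function(i) {
    k <- unique(tab$k[i])
    if (length(k) != 1L)
      stop("inconsistent k for property ", tab$property[i[1]])
    propertyScale(tab$property[i[1]], k,
                  stats::setNames(tab$value[i], tab$kmer[i]),
                  citation = if (length(cit) > 1) cit[i[1]] else cit)
  })
  out[order(names(out))]
}

#' The packaged synthetic property scales
#'
#' Loads the 22 stand-in conversion tables shipped with the package
#' (`inst/extdata/property_scales_synthetic.tsv`). These values are
#' SYNTHETIC: they were drawn once within plausible physical ranges per
#' property and are not the literature tables, which are not reproduced
#' here. The feature mechanics (mean property per k-mer window) are
#' identical whichever table is supplied; use [readPropertyScales()] to load
#' real literature tables.
#'
#' @return named list of 22 [PropertyScale-class] objects, in feature column
#'   order.
#' @export
defaultPropertyScales <- function() {
  path <- system.file("extdata", "property_scales_synthetic.tsv",
                      package = "PolPromoter", mustWork = TRUE)
  sc <- readPropertyScales(path)
  miss <- setdiff(.PHYSCHEM_FEATURES, names(sc))
  if (length(miss))
    stop("packaged scale file lacks properties: ",
         paste(miss, collapse = ", "))
  sc[.PHYSCHEM_FEATURES]
}

## pooled per-base TPM vector for a window [start, end] on chrom.
## Each track is converted to TPM independently, then samples of the assay
## are combined by `pooling` (sum keeps breadth of evidence; mean available).
## Positions outside the chromosome contribute 0 (the N-padding analogue).
.windowPooledTpm <- function(chrom, start, end, tracks,
                             pooling = c("sum", "mean"), mask = NULL) {
  pooling <- match.arg(pooling)
  L <- end - start + 1L
  acc <- numeric(L)
  for (tr in tracks) {
    if (!chrom %in% names(tr@coverage))
      stop("chromosome ", chrom, " absent from track ", tr@sampleId)
    cov <- tr@coverage[[chrom]]
    lo <- max(start, 1L); hi <- min(end, length(cov))
    v <- numeric(L)
    if (lo <= hi) {
      seg <- cov[lo:hi]
      if (!is.null(mask)) {
        m <- mask[[chrom]]
        if (!is.null(m)) seg <- seg * m[lo:hi]
      }
      v[(lo - start + 1L):(hi - start + 1L)] <- seg
    }
    acc <- acc + v * 1e6 / tr@librarySize
  }
  if (pooling == "mean" && length(tracks) > 0) acc <- acc / length(tracks)
  acc
}

#' Per-base TPM profile of a window for one track
#'
#' @param window a length-1 GRanges.
#' @param track a [TagTrack-class].
#' @return numeric vector of per-base tags-per-million values, one per base
#'   of the window.
#' @export
windowTpmProfile <- function(window, track) {
  stopifnot(is(window, "GRanges"), length(window) == 1L,
            is(track, "TagTrack"))
  .windowPooledTpm(as.character(GenomicRanges::seqnames(window)),
                   GenomicRanges::start(window),
                   GenomicRanges::end(window), list(track))
}

#' Average, maximum and max/avg TPM of a window
#'
#' The ratio is defined as 0 when the average is 0 (no evidence).
#'
#' @param window a length-1 GRanges.
#' @param tracks a [TagTrack-class] or list of them (pooled per-base).
#' @param pooling `"sum"` (default) or `"mean"` across samples.
#' @param mask optional named list of per-chromosome logical vectors; tag
#'   coverage outside the mask is ignored (significant-region masking).
#' @return named numeric vector `c(avg_tpm, max_tpm, max_over_avg)`.
#' @export
signalFeatures <- function(window, tracks, pooling = "sum", mask = NULL) {
  if (is(tracks, "TagTrack")) tracks <- list(tracks)
  tpm <- .windowPooledTpm(as.character(GenomicRanges::seqnames(window)),
                          GenomicRanges::start(window),
                          GenomicRanges::end(window), tracks,
                          pooling = pooling, mask = mask)
  avg <- mean(tpm); mx <- max(tpm)
  c(avg_tpm = avg, max_tpm = mx,
    max_over_avg = if (avg > 0) mx / avg else 0)
}

#' Total CAGE TPM falling in a window
#'
#' @inheritParams signalFeatures
#' @return single numeric: the sum of per-base TPM over the window.
#' @export
cageFeature <- function(window, tracks, pooling = "sum", mask = NULL) {
  if (is(tracks, "TagTrack")) tracks <- list(tracks)
  sum(.windowPooledTpm(as.character(GenomicRanges::seqnames(window)),
                       GenomicRanges::start(window),
                       GenomicRanges::end(window), tracks,
                       pooling = pooling, mask = mask))
}

## extract window sequences with N padding beyond chromosome ends;
## minus-strand windows are reverse-complemented.
.windowSequences <- function(windows, genome) {
  chroms <- as.character(GenomicRanges::seqnames(windows))
  starts <- GenomicRanges::start(windows)
  ends <- GenomicRanges::end(windows)
  strands <- as.character(GenomicRanges::strand(windows))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- character(length(windows))
  for (i in seq_along(windows)) {
    ch <- chroms[i]
    if (!ch %in% names(genome))
      stop("chromosome ", ch, " absent from genome")
    L <- ends[i] - starts[i] + 1L
    lo <- max(starts[i], 1L); hi <- min(ends[i], lens[[ch]])
    body <- if (lo <= hi)
      as.character(Biostrings::subseq(genome[[ch]], lo, hi)) else ""
    seqs[i] <- paste0(strrep("N", max(0L, 1L - starts[i])), body,
                      strrep("N", max(0L, ends[i] - lens[[ch]])))
    stopifnot(nchar(seqs[i]) == L)
  }
  out <- Biostrings::DNAStringSet(seqs)
  rc <- strands == "-"
  if (any(rc)) out[rc] <- Biostrings::reverseComplement(out[rc])
  out
}

#' Compute the 39-feature matrix for a set of windows
#'
#' For each window the function computes the 10 composition features and 22
#' property features from the (strand-oriented) sequence, and the 7
#' experimental features from the pooled TPM of the Pol-II, H3K4me3 and CAGE
#' tracks. Minus-strand windows are reverse-complemented before sequence
#' feature computation; signal features are computed on genomic coordinates
#' regardless of strand. Windows extending beyond a chromosome end are
#' padded with N (composition denominators keep the full window length).
#'
#' @param windows GRanges of (typically 500 bp) windows.
#' @param genome DNAStringSet from [readGenomeFasta()].
#' @param scales list of exactly 22 [PropertyScale-class] objects named by
#'   the physchem feature columns; defaults to [defaultPropertyScales()].
#' @param tracks named list with elements `polII`, `h3k4me3`, `cage`, each a
#'   list of [TagTrack-class] objects (multiple samples pooled).
#' @param pooling `"sum"` (default) or `"mean"` pooling across samples of
#'   one assay; each sample is converted to TPM before pooling.
#' @param mask optional named list of per-chromosome logical vectors (from
#'   [significantRegionMask()]); coverage outside it is ignored.
#' @param allowMissingTracks if TRUE a missing assay group yields zero
#'   signal features with a warning instead of an error.
#' @return data.frame with the 39 feature columns in fixed order
#'   ([promoterFeatureNames()]); row names follow the windows.
#' @export
featureMatrix <- function(windows, genome, scales = defaultPropertyScales(),
                          tracks = list(), pooling = "sum", mask = NULL,
                          allowMissingTracks = FALSE) {
  stopifnot(is(windows, "GRanges"))
  if (!setequal(names(scales), .PHYSCHEM_FEATURES) || length(scales) != 22L)
    stop("exactly 22 property scales named by the physchem features ",
         "are required")
  scales <- scales[.PHYSCHEM_FEATURES]
  n <- length(windows)
  L <- unique(GenomicRanges::width(windows))
  if (length(L) != 1L)
    stop("all windows must have identical length")

  seqs <- .windowSequences(windows, genome)
  cnt <- lapply(1:4, function(k) .kmerCountMatrix(seqs, k))
  comp <- .compositionFromCounts(cnt[[1]], cnt[[2]], cnt[[3]], L)

  phys <- matrix(0, n, length(scales),
                 dimnames = list(NULL, names(scales)))
  for (nm in names(scales)) {
    sc <- scales[[nm]]
    m <- cnt[[sc@k]]
    valid <- rowSums(m)
    v <- as.numeric(m %*% sc@values[colnames(m)])
    phys[, nm] <- ifelse(valid > 0, v / pmax(valid, 1), 0)
  }

  sig <- matrix(0, n, length(.EXPERIMENTAL_FEATURES),
                dimnames = list(NULL, .EXPERIMENTAL_FEATURES))
  getTracks <- function(assay) {
    tr <- tracks[[assay]]
    if (is(tr, "TagTrack")) tr <- list(tr)
    if (is.null(tr) || length(tr) == 0L) {
      if (allowMissingTracks) {
        warning("no ", assay, " tracks supplied; signal features set to 0")
        return(NULL)
      }
      stop("no ", assay, " tracks supplied ",
           "(set allowMissingTracks = TRUE to zero-fill)")
    }
    tr
  }
  chroms <- as.character(GenomicRanges::seqnames(windows))
  starts <- GenomicRanges::start(windows)
  ends <- GenomicRanges::end(windows)
  for (assay in c("polII", "h3k4me3", "cage")) {
    tr <- getTracks(assay)
    if (is.null(tr)) next
    for (i in seq_len(n)) {
      tpm <- .windowPooledTpm(chroms[i], starts[i], ends[i], tr,
                              pooling = pooling, mask = mask)
      if (assay == "cage") {
        sig[i, "cage_total_tpm"] <- sum(tpm)
      } else {
        avg <- mean(tpm); mx <- max(tpm)
        sig[i, paste0(assay, "_avg_tpm")] <- avg
        sig[i, paste0(assay, "_max_tpm")] <- mx
        sig[i, paste0(assay, "_max_over_avg")] <- if (avg > 0) mx / avg else 0
      }
    }
  }

  out <- data.frame(comp, phys, sig, check.names = FALSE)
  out <- out[, promoterFeatureNames(), drop = FALSE]
  if (!is.null(names(windows)) && anyDuplicated(names(windows)) == 0L)
    rownames(out) <- names(windows)
  out
}

#' Extract the 39-feature vector of a single window
#'
#' Convenience wrapper around [featureMatrix()] for one window.
#'
#' @inheritParams featureMatrix
#' @param window a length-1 GRanges.
#' @return named numeric vector of the 39 features.
#' @export
extractFeatures <- function(window, genome,
                            scales = defaultPropertyScales(),
                            tracks = list(), pooling = "sum", mask = NULL,
                            allowMissingTracks = FALSE) {
  stopifnot(length(window) == 1L)
  fm <- featureMatrix(window, genome, scales = scales, tracks = tracks,
                      pooling = pooling, mask = mask,
                      allowMissingTracks = allowMissingTracks)
  unlist(fm[1, , drop = TRUE])
}

#' Write a feature matrix as TSV
#'
#' @param fm data.frame from [featureMatrix()] (optionally with extra
#'   identifier/label columns).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  utils::write.table(cbind(window = rownames(fm), fm), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
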