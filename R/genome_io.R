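#' Read a genome FASTA into a DNAStringSet
#'
#' Sequence names are trimmed at the first whitespace, sequence is
#' upper-cased and any letter outside A/C/G/T is preserved as N. N bases are
#' kept: downstream feature code defines their handling (k-mer windows
#' containing N are skipped while composition denominators stay fixed).
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    stop("FASTA file contains no records: ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("FASTA file contains an empty record: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  # normalise: uppercase, any IUPAC ambiguity code collapsed to N
  chr <- toupper(as.character(x))
  chr <- gsub("[^ACGTN]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Read a UCSC-style gene table
#'
#' Reads a tab-delimited gene table (refGene-like) and computes the
#' strand-aware TSS for each transcript. Input coordinates are 0-based
#' half-open (the UCSC convention) by default and are converted to 1-based
#' closed GRanges at this boundary. Malformed rows (bad strand, non-numeric
#' or inverted coordinates) are skipped with a warning reporting the count.
#' Rows duplicated on (chrom, tss, strand, name) are collapsed.
#'
#' @param path path to the table.
#' @param source source label stored with every gene (e.g. "refseq").
#' @param columns named character vector mapping the roles
#'   `chrom`, `strand`, `txStart`, `txEnd`, `name` (and optionally
#'   `biotype`) to column names in the file.
#' @param zeroBased logical; are txStart/txEnd 0-based half-open?
#' @param header logical; does the file have a header line?
#' @return a [GenomicRanges::GRanges] of gene bodies with metadata columns
#'   `gene_id`, `tss` (1-based TSS position), `biotype`, `source`.
#' @export
readGeneTable <- function(path, source = "unknown",
                          columns = c(chrom = "chrom", strand = "strand",
                                      txStart = "txStart", txEnd = "txEnd",
                                      name = "name"),
                          zeroBased = TRUE, header = TRUE) {
  if (!file.exists(path))
    stop("gene table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!header)
    names(tab) <- columns[seq_len(min(length(columns), ncol(tab)))]
  need <- c("chrom", "strand", "txStart", "txEnd", "name")
  miss <- setdiff(need, names(columns))
  if (length(miss))
    stop("column map lacks roles: ", paste(miss, collapse = ", "))
  absent <- setdiff(columns[need], names(tab))
  if (length(absent))
    stop("gene table lacks columns: ", paste(absent, collapse = ", "))
  chrom <- as.character(tab[[columns[["chrom"]]]])
  strand <- as.character(tab[[columns[["strand"]]]])
  txStart <- suppressWarnings(as.numeric(tab[[columns[["txStart"]]]]))
  txEnd <- suppressWarnings(as.numeric(tab[[columns[["txEnd"]]]]))
  name <- as.character(tab[[columns[["name"]]]])
  biotype <- if ("biotype" %in% names(columns) &&
                 columns[["biotype"]] %in% names(tab))
    as.character(tab[[columns[["biotype"]]]]) else rep("coding", nrow(tab))

  ok <- nzchar(chrom) & strand %in% c("+", "-") &
    !is.na(txStart) & !is.na(txEnd) & txStart < txEnd & nzchar(name)
  ok[is.na(ok)] <- FALSE
  nbad <- sum(!ok)
  if (nbad > 0)
    warning(nbad, " malformed row(s) skipped in ", basename(path))
  if (!any(ok))
    stop("no valid gene rows in ", path)

  start1 <- if (zeroBased) txStart[ok] + 1 else txStart[ok]
  end1 <- txEnd[ok]            # 0-based half-open end == 1-based closed end
  if (!zeroBased) end1 <- txEnd[ok]
  tss <- ifelse(strand[ok] == "+", start1, end1)

  gr <- GenomicRanges::GRanges(chrom[ok],
                               IRanges::IRanges(start1, end1),
                               strand = strand[ok])
  S4Vectors::mcols(gr)$gene_id <- name[ok]
  S4Vectors::mcols(gr)$tss <- as.integer(tss)
  S4Vectors::mcols(gr)$biotype <- biotype[ok]
  S4Vectors::mcols(gr)$source <- source

  key <- paste(GenomicRanges::seqnames(gr), gr$tss,
               GenomicRanges::strand(gr), gr$gene_id)
  gr[!duplicated(key)]
}

#' Build a non-redundant TSS catalog from one or more gene lists
#'
#' Takes the union of the TSSs of several gene lists (e.g. RefSeq, Vega,
#' Ensembl, UCSC) and collapses entries identical on (chrom, tss, strand),
#' concatenating gene ids and source labels. Coding status wins over
#' noncoding when collapsed entries disagree. Applying the function to its
#' own output changes nothing.
#'
#' @param ... GRanges as returned by [readGeneTable()], or a single list of
#'   them.
#' @return a width-1 [GenomicRanges::GRanges] of TSS positions with metadata
#'   `gene_id`, `biotype`, `source`.
#' @export
buildNonredundantTss <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) && !is(lists[[1]], "GRanges"))
    lists <- lists[[1]]
  if (length(lists) == 0L)
    stop("at least one gene list is required")
  ent <- do.call(rbind, lapply(lists, function(g) {
    if (length(g) == 0L) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               tss = g$tss,
               strand = as.character(GenomicRanges::strand(g)),
               gene_id = g$gene_id,
               biotype = g$biotype,
               source = g$source,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ent) || nrow(ent) == 0L)
    stop("union of TSS entries is empty")
  key <- paste(ent$chrom, ent$tss, ent$strand)
  agg <- function(x) paste(sort(unique(unlist(strsplit(x, ";")))),
                           collapse = ";")
  idx <- split(seq_len(nrow(ent)), key)
  rows <- lapply(idx, function(i) {
    data.frame(chrom = ent$chrom[i[1]], tss = ent$tss[i[1]],
               strand = ent$strand[i[1]],
               gene_id = agg(ent$gene_id[i]),
               biotype = if (any(ent$biotype[i] == "coding")) "coding"
                         else ent$biotype[i[1]],
               source = agg(ent$source[i]),
               stringsAsFactors = FALSE)
  })
  ent <- do.call(rbind, rows)
  ord <- order(ent$chrom, ent$tss, ent$strand)
  ent <- ent[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(ent$chrom,
                               IRanges::IRanges(ent$tss, ent$tss),
                               strand = ent$strand)
  S4Vectors::mcols(gr)$gene_id <- ent$gene_id
  S4Vectors::mcols(gr)$tss <- as.integer(ent$tss)
  S4Vectors::mcols(gr)$biotype <- ent$biotype
  S4Vectors::mcols(gr)$source <- ent$source
  gr
}

#' Read tag data into a TagTrack
#'
#' Supports two plain-text layouts: a BED of tag positions (each row adds +1
#' coverage to every base of its interval; the library size defaults to the
#' number of rows) and a bedGraph of coverage (chrom, start, end, value; the
#' library size defaults to the total coverage mass). Both use 0-based
#' half-open coordinates, converted here.
#'
#' @param path path to the file.
#' @param assay assay label for the track.
#' @param sampleId sample identifier; defaults to the file name.
#' @param format `"bed"` or `"bedGraph"`.
#' @param chromSizes optional named vector of chromosome lengths; defaults
#'   to the largest end coordinate seen per chromosome.
#' @param librarySize optional explicit library size.
#' @return a [TagTrack-class].
#' @export
readTagTrack <- function(path, assay, sampleId = basename(path),
                         format = c("bed", "bedGraph"),
                         chromSizes = NULL, librarySize = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("tag file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  chrom <- as.character(tab[[1]])
  start0 <- as.numeric(tab[[2]])
  end0 <- as.numeric(tab[[3]])
  if (any(is.na(start0)) || any(is.na(end0)) || any(start0 >= end0))
    stop("malformed intervals in ", path)
  val <- if (format == "bedGraph") as.numeric(tab[[4]]) else rep(1, nrow(tab))
  if (any(val < 0))
    stop("negative coverage in ", path)
  if (is.null(chromSizes))
    chromSizes <- vapply(split(end0, chrom), max, numeric(1))
  cov <- lapply(names(chromSizes), function(ch) numeric(chromSizes[[ch]]))
  names(cov) <- names(chromSizes)
  for (i in seq_along(chrom)) {
    ch <- chrom[i]
    if (!ch %in% names(cov))
      stop("chromosome ", ch, " not in chromSizes")
    idx <- (start0[i] + 1):min(end0[i], length(cov[[ch]]))
    cov[[ch]][idx] <- cov[[ch]][idx] + val[i]
  }
  if (is.null(librarySize))
    librarySize <- if (format == "bed") nrow(tab)
                   else sum(vapply(cov, sum, numeric(1)))
  TagTrack(sampleId, assay, cov, librarySize)
}

#' Write genomic intervals as BED
#'
#' Writes standard 6-column BED (0-based half-open). Any further metadata
#' columns of `gr` are appended after the strand column (BED6+).
#'
#' @param gr a GRanges; metadata columns `name` and `score` are used for BED
#'   columns 4-5 when present.
#' @param path output path.
#' @param extraCols character vector of metadata column names to append.
#' @return the path, invisibly.
#' @export
writeBed <- function(gr, path, extraCols = character()) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) as.character(gr$name)
          else paste0("region_", seq_len(max(n, 0)))
  score <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, n)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  for (col in extraCols)
    df[[col]] <- S4Vectors::mcols(gr)[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as GRanges
#'
#' Accepts BED3 to BED6+ (0-based half-open in the file, converted to
#' 1-based closed). Columns beyond the sixth are kept as metadata columns
#' named by `extraCols`.
#'
#' @param path path to the BED file.
#' @param extraCols names for columns beyond the sixth, in order.
#' @return a [GenomicRanges::GRanges] with `name` and `score` metadata when
#'   present.
#' @export
readBed <- function(path, extraCols = character()) {
  if (!file.exists(path))
    stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  strand <- if (ncol(tab) >= 6) ifelse(tab[[6]] %in% c("+", "-"),
                                       tab[[6]], "*") else "*"
  gr <- GenomicRanges::GRanges(as.character(tab[[1]]),
                               IRanges::IRanges(tab[[2]] + 1L, tab[[3]]),
                               strand = strand)
  if (ncol(tab) >= 4) S4Vectors::mcols(gr)$name <- as.character(tab[[4]])
  if (ncol(tab) >= 5) S4Vectors::mcols(gr)$score <- as.numeric(tab[[5]])
  if (length(extraCols) && ncol(tab) >= 7) {
    for (j in seq_along(extraCols)) {
      if (6 + j <= ncol(tab))
        S4Vectors::mcols(gr)[[extraCols[j]]] <- tab[[6 + j]]
    }
  }
  gr
}
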