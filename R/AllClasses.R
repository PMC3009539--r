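#' @import methods
#' @importFrom stats ppois p.adjust predict rpois runif setNames aggregate quantile sd
#' @importFrom utils read.table write.table head tail
NULL

#' TagTrack: per-base tag coverage for one sequencing sample
#'
#' A `TagTrack` stores the per-base tag coverage of one ChIP-seq or CAGE
#' sample, one numeric vector per chromosome, together with the library size
#' used for tags-per-million (TPM) scaling. It is the container behind all
#' experimental signal features (average TPM, maximum TPM, max/avg ratio and
#' total CAGE TPM).
#'
#' @slot sampleId single string identifying the sample.
#' @slot assay one of `"polII"`, `"h3k4me3"`, `"cage"`.
#' @slot coverage named list of non-negative numeric vectors, one per
#'   chromosome; `coverage[[chrom]][i]` is the tag count at base `i`
#'   (1-based).
#' @slot librarySize total mapped tags used as the TPM denominator; must be
#'   positive.
#'
#' @export
setClass("TagTrack",
  representation(
    sampleId = "character",
    assay = "character",
    coverage = "list",
    librarySize = "numeric"
  )
)

setValidity("TagTrack", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (length(object@assay) != 1L ||
      !object@assay %in% c("polII", "h3k4me3", "cage"))
    msg <- c(msg, "assay must be one of 'polII', 'h3k4me3', 'cage'")
  if (length(object@coverage) == 0L || is.null(names(object@coverage)) ||
      any(!nzchar(names(object@coverage))))
    msg <- c(msg, "coverage must be a non-empty named list of vectors")
  else {
    bad <- vapply(object@coverage,
                  function(v) !is.numeric(v) || anyNA(v) || any(v < 0),
                  logical(1))
    if (any(bad))
      msg <- c(msg, "coverage vectors must be non-negative and NA-free")
  }
  if (length(object@librarySize) != 1L || is.na(object@librarySize) ||
      object@librarySize <= 0)
    msg <- c(msg, "librarySize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a TagTrack
#'
#' @param sampleId sample identifier.
#' @param assay assay type: `"polII"`, `"h3k4me3"` or `"cage"`.
#' @param coverage named list of per-chromosome tag counts per base.
#' @param librarySize total mapped tags; defaults to the total coverage mass
#'   (i.e. the number of tag-bases) in `coverage`.
#' @return a [TagTrack-class] object.
#' @examples
#' tt <- TagTrack("s1", "polII", list(chr1 = c(0, 2, 1, 0)), librarySize = 3)
#' librarySize(tt)
#' @export
TagTrack <- function(sampleId, assay, coverage,
                     librarySize = sum(vapply(coverage, sum, numeric(1)))) {
  new("TagTrack", sampleId = as.character(sampleId),
      assay = as.character(assay),
      coverage = lapply(coverage, as.numeric) |>
        stats::setNames(names(coverage)),
      librarySize = as.numeric(librarySize))
}

#' @describeIn TagTrack library size accessor
#' @param x a `TagTrack`.
#' @export
librarySize <- function(x) {
  stopifnot(is(x, "TagTrack"))
  x@librarySize
}

#' @describeIn TagTrack per-chromosome coverage accessor
#' @export
trackCoverage <- function(x) {
  stopifnot(is(x, "TagTrack"))
  x@coverage
}

#' @describeIn TagTrack chromosome lengths implied by the coverage vectors
#' @export
trackSeqlengths <- function(x) {
  stopifnot(is(x, "TagTrack"))
  vapply(x@coverage, length, integer(1))
}

setMethod("show", "TagTrack", function(object) {
  cat("TagTrack '", object@sampleId, "' (", object@assay, ")\n", sep = "")
  cat("  chromosomes:", length(object@coverage),
      "| total bases:", sum(vapply(object@coverage, length, integer(1))), "\n")
  cat("  library size:", format(object@librarySize, big.mark = ","),
      "| coverage mass:",
      format(sum(vapply(object@coverage, sum, numeric(1))), big.mark = ","),
      "\n")
})

#' PropertyScale: a k-mer to value conversion table
#'
#' A `PropertyScale` maps every k-mer over \{A,C,G,T\} to a numeric value for
#' one physico-chemical or structural DNA property (e.g. base stacking
#' energy, propeller twist, tri-nucleotide bendability). A window's feature
#' value for the property is the mean scale value over all N-free k-mer
#' windows of the sequence.
#'
#' @slot name property name (one of the 22 feature column names).
#' @slot k k-mer size, 1 to 4.
#' @slot values named numeric vector of length `4^k` covering every k-mer.
#' @slot citation free-text provenance of the table.
#'
#' @export
setClass("PropertyScale",
  representation(
    name = "character",
    k = "integer",
    values = "numeric",
    citation = "character"
  )
)

setValidity("PropertyScale", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@k) != 1L || !object@k %in% 1:4)
    msg <- c(msg, "k must be an integer in 1..4")
  else {
    want <- allKmers(object@k)
    if (length(object@values) != length(want) ||
        !setequal(names(object@values), want))
      msg <- c(msg, sprintf(
        "values must be named with all %d k-mers of size %d",
        4L^object@k, object@k))
    if (anyNA(object@values) || any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite and NA-free")
  }
  if (length(msg)) msg else TRUE
})

#' All k-mers over the DNA alphabet, in lexicographic order
#' @param k k-mer size (1 to 4).
#' @return character vector of length `4^k`.
#' @export
allKmers <- function(k) {
  stopifnot(k %in% 1:4)
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) for (i in 2:k)
    out <- as.vector(t(outer(out, bases, paste0)))
  sort(out)
}

#' Construct a PropertyScale
#'
#' @param name property name.
#' @param k k-mer size (1 to 4).
#' @param values named numeric vector with one entry per k-mer of size `k`.
#' @param citation provenance string.
#' @return a [PropertyScale-class] object.
#' @examples
#' sc <- propertyScale("toy", 1, c(A = 1, C = 2, G = 3, T = 4))
#' @export
propertyScale <- function(name, k, values, citation = "") {
  new("PropertyScale", name = name, k = as.integer(k),
      values = values[allKmers(k)], citation = citation)
}

setMethod("show", "PropertyScale", function(object) {
  cat("PropertyScale '", object@name, "' (k = ", object@k, ")\n", sep = "")
  cat("  range: [", min(object@values), ", ", max(object@values), "]\n",
      sep = "")
  if (nzchar(object@citation)) cat("  source:", object@citation, "\n")
})

#' PromoterModel: a fitted ensemble promoter classifier
#'
#' Wraps a fitted bagging or random-forest classifier together with the
#' feature column order it was trained on, so that prediction refuses to run
#' on a mismatched feature matrix.
#'
#' @slot algorithm `"bagging"` or `"random_forest"`.
#' @slot fit the fitted randomForest object.
#' @slot featureNames feature column names, in training order.
#' @slot hyperparameters list of tuning values (ntree, mtry).
#' @slot seed integer seed used for the fit.
#'
#' @export
setClass("PromoterModel",
  representation(
    algorithm = "character",
    fit = "ANY",
    featureNames = "character",
    hyperparameters = "list",
    seed = "integer"
  )
)

setValidity("PromoterModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("bagging", "random_forest"))
    msg <- c(msg, "algorithm must be 'bagging' or 'random_forest'")
  if (length(object@featureNames) == 0L)
    msg <- c(msg, "featureNames must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PromoterModel", function(object) {
  cat("PromoterModel (", object@algorithm, ")\n", sep = "")
  cat("  features:", length(object@featureNames),
      "| ntree:", object@hyperparameters$ntree,
      "| mtry:", object@hyperparameters$mtry, "\n")
})
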