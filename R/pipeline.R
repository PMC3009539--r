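## YAML-driven pipeline commands behind the command-line dispatcher
## (inst/scripts/polpromoter). Every command validates its configuration,
## funnels all randomness through the configured seed, and writes a run log
## (parameters, seed, input checksums) next to its outputs.

.CONFIG_KEYS <- list(
  top = c("seed", "output_dir", "genome_fasta", "gene_tables", "tracks",
          "scales_path", "exclusions_bed", "records_bed", "features_tsv",
          "model_path", "peaks_bed", "peaks", "dataset", "model",
          "simulate"),
  peaks = c("window_bp", "step_bp", "fdr", "effective_genome_size"),
  dataset = c("train_fraction", "tissue"),
  model = c("algorithm", "ntree", "threshold"),
  simulate = c("n_genes", "cpg_enrichment", "depth"))

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file; unknown keys anywhere in the known
#' sections are rejected so that typos fail before any stage runs.
#'
#' @param path path to a YAML configuration.
#' @return a validated named list (class `RunConfig`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  .checkKeys(cfg, .CONFIG_KEYS$top, "top level")
  for (sec in c("peaks", "dataset", "model", "simulate"))
    if (!is.null(cfg[[sec]]))
      .checkKeys(cfg[[sec]], .CONFIG_KEYS[[sec]], sec)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "polpromoter_out"
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.checkKeys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s) at ", where, ": ",
         paste(unknown, collapse = ", "))
}

.cfgGet <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

.writeRunLog <- function(dir, command, cfg, inputs = character()) {
  log <- list(command = command, seed = cfg$seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              parameters = unclass(cfg))
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs))
    log$input_md5 <- as.list(tools::md5sum(inputs))
  yaml::write_yaml(log, file.path(dir, paste0("run_", command, ".log.yaml")))
}

.readConfigTracks <- function(cfg, assays = c("polII", "h3k4me3", "cage")) {
  out <- list()
  for (assay in assays) {
    specs <- cfg$tracks[[assay]]
    if (is.null(specs)) next
    out[[assay]] <- lapply(specs, function(s) {
      readTagTrack(s$path, assay,
                   sampleId = if (!is.null(s$sample_id)) s$sample_id
                              else basename(s$path),
                   format = if (!is.null(s$format)) s$format else "bed",
                   librarySize = s$library_size)
    })
  }
  out
}

.readConfigGenes <- function(cfg) {
  if (is.null(cfg$gene_tables))
    stop("config lacks gene_tables")
  lapply(cfg$gene_tables, function(g) {
    cols <- c(chrom = "chrom", strand = "strand", txStart = "txStart",
              txEnd = "txEnd", name = "name", biotype = "biotype")
    readGeneTable(g$path, source = if (!is.null(g$source)) g$source
                                   else "unknown", columns = cols)
  })
}

.readConfigScales <- function(cfg) {
  if (is.null(cfg$scales_path)) defaultPropertyScales()
  else readPropertyScales(cfg$scales_path)[promoterFeatureNames("physchem")]
}

#' Pipeline commands
#'
#' Each command reads a validated [readRunConfig()] configuration, runs one
#' pipeline stage through the package functions, writes its outputs and a
#' run log under `output_dir`, and returns the main result invisibly.
#' `runSimulate` writes synthetic genome/genes/truth/tracks;
#' `runCallPeaks` calls Pol-II peaks to BED; `runBuildDataset` builds
#' labeled records and a manifest; `runExtract` writes the 39-column feature
#' matrix; `runTrain` fits and saves a model; `runEvaluate` scores a feature
#' matrix against its labels; `runCv` runs stratified cross-validation;
#' `runAnnotate` scans peaks genome-wide and writes promoter calls, gene
#' assignments and the alternative-promoter summary.
#'
#' @param cfg a `RunConfig` from [readRunConfig()].
#' @return invisibly, the stage's main result.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulationConfig(seed = cfg$seed,
                         nGenes = .cfgGet(cfg, "simulate", "n_genes", 500L),
                         cpgEnrichment =
                           .cfgGet(cfg, "simulate", "cpg_enrichment", 5),
                         depth = .cfgGet(cfg, "simulate", "depth", 1))
  sim <- simulateGenome(sc)
  tracks <- simulateTags(sim, sc)
  paths <- writeSimulatedData(sim, tracks, cfg$output_dir)
  .writeRunLog(cfg$output_dir, "simulate", cfg)
  invisible(paths)
}

#' @rdname pipeline
#' @export
runCallPeaks <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- .readConfigTracks(cfg, "polII")
  if (is.null(tracks$polII))
    stop("config lacks tracks.polII")
  peaksAll <- list()
  for (tr in tracks$polII) {
    pk <- callPeaks(tr,
                    windowBp = .cfgGet(cfg, "peaks", "window_bp", 500L),
                    stepBp = .cfgGet(cfg, "peaks", "step_bp", 50L),
                    fdr = .cfgGet(cfg, "peaks", "fdr", 0.001))
    out <- file.path(cfg$output_dir, paste0("peaks_", tr@sampleId, ".bed"))
    writePeaksBed(pk, out)
    peaksAll[[tr@sampleId]] <- pk
  }
  .writeRunLog(cfg$output_dir, "callpeaks", cfg,
               vapply(cfg$tracks$polII, function(s) s$path, character(1)))
  invisible(peaksAll)
}

#' @rdname pipeline
#' @export
runBuildDataset <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$peaks_bed))
    stop("config lacks peaks_bed")
  peaks <- readPeaksBed(cfg$peaks_bed)
  genes <- .readConfigGenes(cfg)
  tss <- buildNonredundantTss(genes)
  genesAll <- do.call(c, unname(genes))
  excl <- if (!is.null(cfg$exclusions_bed)) readBed(cfg$exclusions_bed)
          else GenomicRanges::GRanges()
  tissue <- .cfgGet(cfg, "dataset", "tissue", "NA")
  prom <- labelPromoterPeaks(peaks, tss, tissue = tissue)
  nonprom <- selectNonpromoterPeaks(peaks, genesAll, tss, excl,
                                    tissue = tissue)
  dd <- deduplicateCrossTissue(prom, nonprom)
  records <- c(dd$promoter, dd$nonpromoter)
  S4Vectors::mcols(records)$name <-
    paste0(records$label, "_", seq_along(records))
  writeBed(records, file.path(cfg$output_dir, "records.bed"))
  utils::write.table(
    data.frame(name = records$name, tissue = records$tissue,
               label = records$label, source_peak = records$sourcePeak,
               gene_id = records$gene_id),
    file.path(cfg$output_dir, "records_manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  .writeRunLog(cfg$output_dir, "builddataset", cfg, cfg$peaks_bed)
  invisible(records)
}

#' @rdname pipeline
#' @export
runExtract <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$genome_fasta)) stop("config lacks genome_fasta")
  if (is.null(cfg$records_bed)) stop("config lacks records_bed")
  genome <- readGenomeFasta(cfg$genome_fasta)
  records <- readBed(cfg$records_bed)
  tracks <- .readConfigTracks(cfg)
  fm <- featureMatrix(records, genome, scales = .readConfigScales(cfg),
                      tracks = tracks)
  lab <- sub("_[0-9]+$", "", records$name)
  out <- cbind(window = records$name, label = lab, fm)
  utils::write.table(out, file.path(cfg$output_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeRunLog(cfg$output_dir, "extract", cfg,
               c(cfg$genome_fasta, cfg$records_bed))
  invisible(out)
}

.readFeatureTsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- promoterFeatureNames()
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  list(features = tab[, need], labels = tab$label, windows = tab$window)
}

#' @rdname pipeline
#' @export
runTrain <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$features_tsv)) stop("config lacks features_tsv")
  ft <- .readFeatureTsv(cfg$features_tsv)
  model <- trainModel(ft$features, ft$labels,
                      algorithm = .cfgGet(cfg, "model", "algorithm",
                                          "random_forest"),
                      ntree = .cfgGet(cfg, "model", "ntree", 100L),
                      seed = cfg$seed)
  out <- file.path(cfg$output_dir, "model.rds")
  savePromoterModel(model, out)
  .writeRunLog(cfg$output_dir, "train", cfg, cfg$features_tsv)
  invisible(model)
}

#' @rdname pipeline
#' @export
runEvaluate <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$features_tsv)) stop("config lacks features_tsv")
  if (is.null(cfg$model_path)) stop("config lacks model_path")
  ft <- .readFeatureTsv(cfg$features_tsv)
  model <- loadPromoterModel(cfg$model_path)
  pr <- predictPromoter(model, ft$features,
                        threshold = .cfgGet(cfg, "model", "threshold", 0.5))
  cm <- confusionCounts(pr$label, ft$labels)
  rep <- evalMetrics(cm["tp"], cm["fn"], cm["tn"], cm["fp"])
  roc <- rocPoints(pr$score, ft$labels)
  rep$auc <- roc$auc
  jsonlite::write_json(rep[c("sn", "ppv", "mcc", "tpc", "auc",
                             "tp", "fn", "tn", "fp")],
                       file.path(cfg$output_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(roc$points,
                     file.path(cfg$output_dir, "roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeRunLog(cfg$output_dir, "evaluate", cfg,
               c(cfg$features_tsv, cfg$model_path))
  invisible(rep)
}

#' @rdname pipeline
#' @export
runCv <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$features_tsv)) stop("config lacks features_tsv")
  ft <- .readFeatureTsv(cfg$features_tsv)
  cv <- crossValidate(ft$features, ft$labels,
                      algorithm = .cfgGet(cfg, "model", "algorithm",
                                          "random_forest"),
                      ntree = .cfgGet(cfg, "model", "ntree", 100L),
                      seed = cfg$seed)
  rep <- cv$report; rep$auc <- cv$auc
  jsonlite::write_json(rep[c("sn", "ppv", "mcc", "tpc", "auc",
                             "tp", "fn", "tn", "fp")],
                       file.path(cfg$output_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeRunLog(cfg$output_dir, "cv", cfg, cfg$features_tsv)
  invisible(cv)
}

#' @rdname pipeline
#' @export
runAnnotate <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in c("genome_fasta", "peaks_bed", "model_path"))
    if (is.null(cfg[[key]])) stop("config lacks ", key)
  genome <- readGenomeFasta(cfg$genome_fasta)
  peaks <- readPeaksBed(cfg$peaks_bed)
  model <- loadPromoterModel(cfg$model_path)
  tracks <- .readConfigTracks(cfg)
  tss <- buildNonredundantTss(.readConfigGenes(cfg))
  calls <- scanPeaks(peaks, model, genome, tracks,
                     scales = .readConfigScales(cfg),
                     threshold = .cfgGet(cfg, "model", "threshold", 0.5))
  S4Vectors::mcols(calls)$name <- paste0("promoter_call_", seq_along(calls))
  S4Vectors::mcols(calls)$score <- calls$score
  writeBed(calls, file.path(cfg$output_dir, "promoter_calls.bed"),
           extraCols = c("strands", "peak", "sampleId"))
  asg <- assignToGenes(calls, tss)
  comb <- combineSamples(asg$assigned)
  utils::write.table(
    data.frame(gene_id = comb$promoters$gene_id,
               biotype = comb$promoters$biotype,
               cluster = comb$promoters$cluster,
               chrom = as.character(
                 GenomicRanges::seqnames(comb$promoters)),
               start = GenomicRanges::start(comb$promoters) - 1L,
               end = GenomicRanges::end(comb$promoters)),
    file.path(cfg$output_dir, "gene_assignment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- summarizeAlternativePromoters(comb$genes)
  utils::write.table(summary,
                     file.path(cfg$output_dir, "promoter_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeRunLog(cfg$output_dir, "annotate", cfg,
               c(cfg$genome_fasta, cfg$peaks_bed, cfg$model_path))
  invisible(list(calls = calls, assigned = asg, summary = summary,
                 unassigned = asg$unassigned))
}

#' Command-line entry point
#'
#' Dispatches `polpromoter <command> --config <file>` to the corresponding
#' pipeline function. Commands: simulate, callpeaks, builddataset, extract,
#' train, evaluate, cv, annotate.
#'
#' @param args character vector of command-line arguments (excluding the
#'   program name), e.g. `c("simulate", "--config", "run.yaml")`.
#' @return 0 invisibly on success; stops with a message otherwise.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  dispatch <- list(simulate = runSimulate, callpeaks = runCallPeaks,
                   builddataset = runBuildDataset, extract = runExtract,
                   train = runTrain, evaluate = runEvaluate, cv = runCv,
                   annotate = runAnnotate)
  if (length(args) < 1L || !args[1] %in% names(dispatch))
    stop("usage: polpromoter <", paste(names(dispatch), collapse = "|"),
         "> --config <file>", call. = FALSE)
  ci <- which(args %in% c("--config", "-c"))
  if (length(ci) != 1L || ci + 1L > length(args))
    stop("a single --config <file> argument is required", call. = FALSE)
  cfg <- readRunConfig(args[ci + 1L])
  dispatch[[args[1]]](cfg)
  invisible(0L)
}
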