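#' Assemble a pipeline configuration
#'
#' Collects every parameter of the search-to-enrichment pipeline into a
#' plain named list, applying the packaged defaults: BLOSUM50 scoring
#' (gap open -10, gap extension -2), E-value cut-off 0.1, the
#' query-length-dependent identity cut-off of [searchThresholds()]
#' (57.1% for the packaged 7-mer LDSYQCT, 55.6% for the 9-mer
#' EMTPVNPGV), up to 500 hits, 5% consensus alternate threshold and
#' 0.2 FDR cut-off. A single `seed` drives every stochastic stage
#' (E-value calibration uses `seed`; stage \eqn{k} of any further
#' randomness uses `seed + k`).
#'
#' @param query Query peptide string.
#' @param databasePath Path to the protein FASTA to scan.
#' @param annotationPath Path to the annotation TSV.
#' @param outDir Output directory (created if missing).
#' @param gapOpen,gapExtend Gap penalties. Defaults -10 / -2.
#' @param maxEvalue,minIdentity,maxHits Search cut-offs; see
#'   [searchThresholds()].
#' @param evdSamples Number of shuffled sequences for E-value
#'   calibration. Default 500.
#' @param altThreshold Consensus alternate threshold, percent.
#'   Default 5.
#' @param fdrCutoff Enrichment significance cut-off. Default 0.2.
#' @param seed Integer master seed. Default 1.
#' @return Named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(query, databasePath, annotationPath, outDir,
                           gapOpen = -10L, gapExtend = -2L,
                           maxEvalue = 0.1, minIdentity = NULL,
                           maxHits = 500L, evdSamples = 500L,
                           altThreshold = 5, fdrCutoff = 0.2, seed = 1L) {
  th <- searchThresholds(query, maxEvalue, minIdentity, maxHits)
  list(query = query, databasePath = databasePath,
       annotationPath = annotationPath, outDir = outDir,
       matrixName = "BLOSUM50", gapOpen = as.integer(gapOpen),
       gapExtend = as.integer(gapExtend),
       maxEvalue = th$maxEvalue, minIdentity = th$minIdentity,
       maxHits = th$maxHits, evdSamples = as.integer(evdSamples),
       altThreshold = altThreshold, fdrCutoff = fdrCutoff,
       seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping with keys matching [pipelineConfig()]'s
#' arguments (`query`, `databasePath`, `annotationPath`, `outDir`
#' required) and fills the remaining defaults.
#'
#' @param path YAML file path.
#' @return Named list understood by [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("query", "databasePath", "annotationPath", "outDir")
  if (!all(need %in% names(y)))
    stop("pipeline config must provide: ", paste(need, collapse = ", "))
  do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[slimscan] %-12s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full motif-discovery pipeline
#'
#' Executes, in fixed order: E-value calibration, database scan,
#' motif deduplication, position frequencies, consensus notation, logo
#' information content, taxonomic profiling and GO enrichment, writing
#' eight artifacts into the output directory: `hits.tsv`, `motifs.txt`,
#' `pfm.tsv`, `consensus.txt`, `logo.tsv`, `taxonomy.tsv`,
#' `enrich.tsv` and `manifest.json` (inputs, every parameter, seed and
#' package version). Reruns with an identical configuration are
#' byte-identical. Any stage error aborts with the stage name and
#' cause.
#'
#' The enrichment study set is the unique gene symbols of the hit
#' table; the background is every gene in the annotation table.
#'
#' @param config A list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return Invisibly, the manifest as a named list (with element
#'   `artifacts` naming each written file).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outDir,
    c(hits = "hits.tsv", motifs = "motifs.txt", pfm = "pfm.tsv",
      consensus = "consensus.txt", logo = "logo.tsv",
      taxonomy = "taxonomy.tsv", enrich = "enrich.tsv",
      manifest = "manifest.json"))
  names(paths) <- c("hits", "motifs", "pfm", "consensus", "logo",
                    "taxonomy", "enrich", "manifest")

  scheme <- .stage("scoring", buildScoring(config$matrixName,
                                           config$gapOpen, config$gapExtend))
  db <- .stage("read-db", readFasta(config$databasePath))
  ann <- .stage("read-ann", readAnnotations(config$annotationPath))
  evd <- .stage("calibrate", calibrateEvd(
    config$query, scheme,
    lengths = as.integer(round(mean(Biostrings::width(db)))),
    nSamples = config$evdSamples, seed = config$seed))
  th <- list(maxEvalue = config$maxEvalue, minIdentity = config$minIdentity,
             maxHits = config$maxHits)
  hits <- .stage("scan", scanDatabase(config$query, db, scheme, evd,
                                      thresholds = th, annotations = ann))
  writeTable(hits, paths[["hits"]])

  mset <- .stage("dedup", dedupMotifs(hits))
  writeLines(motifs(mset), paths[["motifs"]])

  if (length(mset) > 0) {
    pfm <- .stage("pfm", positionFrequencies(mset))
    pfmDf <- data.frame(position = seq_len(nrow(frequencies(pfm))),
                        frequencies(pfm), check.names = FALSE)
    writeTable(pfmDf, paths[["pfm"]])
    cons <- .stage("consensus", consensusNotation(pfm, config$altThreshold))
    writeLines(cons$notation, paths[["consensus"]])
    logo <- .stage("logo", logoColumns(pfm, corrected = TRUE))
    writeTable(logo, paths[["logo"]])
  } else {
    writeTable(data.frame(position = integer()), paths[["pfm"]])
    writeLines(character(), paths[["consensus"]])
    writeTable(data.frame(position = integer(), residue = character(),
                          height = numeric(),
                          information_content = numeric()), paths[["logo"]])
  }

  tax <- .stage("taxonomy", taxonProfile(hits))
  writeTable(tax, paths[["taxonomy"]])

  study <- unique(hits$gene_symbol[!is.na(hits$gene_symbol)])
  enr <- if (length(study)) {
    .stage("enrich", enrichTerms(study, annotations = ann,
                                 fdrCutoff = config$fdrCutoff))
  } else {
    data.frame(term = character(), namespace = character(), k = integer(),
               n = integer(), K = integer(), N_bg = integer(),
               fold_enrichment = numeric(), p_value = numeric(),
               fdr = numeric(), significant = logical())
  }
  writeTable(enr, paths[["enrich"]])

  manifest <- list(
    package = "slimscan",
    version = as.character(packageVersion("slimscan")),
    parameters = config[setdiff(names(config), "outDir")],
    evd = list(mu = evd@mu, beta = evd@beta,
               databaseSize = evd@databaseSize),
    counts = list(hits = nrow(hits), uniqueMotifs = length(mset),
                  enrichedTerms = sum(enr$significant)),
    artifacts = as.list(setNames(basename(paths), names(paths))))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, paths[["manifest"]])
  invisible(manifest)
}
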