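#' @import methods
#' @importFrom stats rnorm runif sd setNames phyper p.adjust
#' @importFrom utils read.delim write.table packageVersion
NULL

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Standard residues in the conventional one-letter code, alphabetical
#' order. \code{X} (unknown/ambiguous) is tolerated in sequences but is
#' not part of this alphabet; ambiguity codes B, Z, U, O are mapped to
#' \code{X} on input.
#'
#' @return Character vector of the 20 residue letters.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Taxonomic category vocabulary
#'
#' The fixed set of taxon labels recognised by [readAnnotations()],
#' [taxonProfile()] and the synthetic generator: prokaryotes (bacteria,
#' viruses, archaea), mammals (human, primates, other mammals),
#' vertebrates (birds, fishes, amphibia), invertebrates (reptiles,
#' insects, nematodes), plants (higher plants, algae) and other
#' eukaryotes (yeast, fungi, other eukaryotes).
#'
#' @return Character vector of 17 category labels.
#' @export
taxonCategories <- function() {
  c("bacteria", "viruses", "archaea",
    "human", "primates", "other_mammals",
    "birds", "fishes", "amphibia",
    "reptiles", "insects", "nematodes",
    "higher_plants", "algae",
    "yeast", "fungi", "other_eukaryotes")
}

## ---------------------------------------------------------------------------
## ScoringScheme
## ---------------------------------------------------------------------------

#' @rdname buildScoring
#' @export
setClass("ScoringScheme",
  representation(
    matrixName = "character",
    matrix = "matrix",
    gapOpen = "integer",
    gapExtend = "integer"
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  m <- object@matrix
  letters21 <- c(aminoAcids(), "X")
  if (!identical(rownames(m), letters21) || !identical(colnames(m), letters21))
    msg <- c(msg, "matrix must be 21x21 over the 20 residues plus X")
  if (!isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "substitution matrix must be symmetric")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0L))
    msg <- c(msg, "penalties must satisfy gapOpen <= gapExtend <= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GlocalAlignment
## ---------------------------------------------------------------------------

#' @rdname alignGlocal
#' @export
setClass("GlocalAlignment",
  representation(
    query = "character",
    queryAln = "character",
    targetAln = "character",
    score = "integer",
    targetStart = "integer",
    targetEnd = "integer",
    identity = "numeric",
    evalue = "numeric"
  )
)

setValidity("GlocalAlignment", function(object) {
  msg <- character()
  qa <- strsplit(object@queryAln, "")[[1]]
  ta <- strsplit(object@targetAln, "")[[1]]
  if (length(qa) != length(ta))
    msg <- c(msg, "aligned strings must have equal length")
  if (any(qa == "-" & ta == "-"))
    msg <- c(msg, "no column may be gap-in-both")
  if (paste(qa[qa != "-"], collapse = "") != object@query)
    msg <- c(msg, "queryAln with gaps removed must equal the full query")
  span <- sum(ta != "-")
  if (span > 0 && object@targetEnd - object@targetStart + 1L != span)
    msg <- c(msg, "target coordinates must cover the ungapped target span")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## EValueModel (calibrated Gumbel parameters)
## ---------------------------------------------------------------------------

#' @rdname calibrateEvd
#' @export
setClass("EValueModel",
  representation(
    mu = "numeric",
    beta = "numeric",
    databaseSize = "numeric",
    nSamples = "integer"
  )
)

setValidity("EValueModel", function(object) {
  if (object@beta <= 0) "scale parameter beta must be > 0" else TRUE
})

## ---------------------------------------------------------------------------
## AnnotationTable
## ---------------------------------------------------------------------------

#' @rdname readAnnotations
#' @export
setClass("AnnotationTable",
  representation(
    accession = "character",
    geneSymbol = "character",
    taxonCategory = "character",
    goTerms = "list"
  )
)

setValidity("AnnotationTable", function(object) {
  msg <- character()
  n <- length(object@accession)
  if (length(object@geneSymbol) != n || length(object@taxonCategory) != n ||
      length(object@goTerms) != n)
    msg <- c(msg, "all columns must have equal length")
  if (anyDuplicated(object@accession))
    msg <- c(msg, "accessions must be unique")
  if (n && !all(object@taxonCategory %in% taxonCategories()))
    msg <- c(msg, paste0("unknown taxon category: ",
      paste(setdiff(object@taxonCategory, taxonCategories()), collapse = ", ")))
  ns <- unlist(lapply(object@goTerms, function(x) x$namespace),
               use.names = FALSE)
  if (length(ns) && !all(ns %in% c("MF", "BP")))
    msg <- c(msg, "GO namespaces restricted to MF/BP")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MotifSet
## ---------------------------------------------------------------------------

#' @rdname dedupMotifs
#' @export
setClass("MotifSet",
  representation(
    motifs = "character",
    provenance = "list",
    query = "character"
  )
)

setValidity("MotifSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@motifs))
    msg <- c(msg, "motif sequences must be unique")
  if (!identical(sort(names(object@provenance)), sort(object@motifs)) &&
      length(object@motifs))
    msg <- c(msg, "provenance must cover every motif")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PositionFrequencyMatrix
## ---------------------------------------------------------------------------

#' @rdname positionFrequencies
#' @export
setClass("PositionFrequencyMatrix",
  representation(
    freq = "matrix",       # L x 20, percentages
    motifCount = "integer" # the paper-style denominator b
  )
)

setValidity("PositionFrequencyMatrix", function(object) {
  msg <- character()
  f <- object@freq
  if (!identical(colnames(f), aminoAcids()))
    msg <- c(msg, "columns must be the 20 residues in alphabetical order")
  if (any(f < 0))
    msg <- c(msg, "frequencies must be non-negative")
  if (nrow(f) && any(abs(rowSums(f) - 100) > 1e-9))
    msg <- c(msg, "each position's percentages must sum to 100")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MotifProfile (generator parameter object)
## ---------------------------------------------------------------------------

#' @rdname motifProfile
#' @export
setClass("MotifProfile",
  representation(
    name = "character",
    probs = "matrix" # L x 20, probabilities summing to 1 per row
  )
)

setValidity("MotifProfile", function(object) {
  msg <- character()
  p <- object@probs
  if (!identical(colnames(p), aminoAcids()))
    msg <- c(msg, "columns must be the 20 residues in alphabetical order")
  if (any(p < 0))
    msg <- c(msg, "probabilities must be non-negative")
  if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "probabilities must sum to 1 per position")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SyntheticConfig
## ---------------------------------------------------------------------------

#' @rdname generateDatabase
#' @export
setClass("SyntheticConfig",
  representation(
    nProteins = "integer",
    lengthMean = "numeric",
    lengthSd = "numeric",
    background = "numeric",     # named length-20 composition
    plantingRate = "numeric",
    profile = "MotifProfile",
    taxonMixture = "numeric",   # named over taxonCategories()
    goCatalog = "data.frame",   # term, namespace, backgroundProb, plantedFold
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@plantingRate < 0 || object@plantingRate > 1)
    msg <- c(msg, "plantingRate must lie in [0, 1]")
  if (!identical(names(object@background), aminoAcids()) ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background composition must be named over the 20 residues and sum to 1")
  if (!all(names(object@taxonMixture) %in% taxonCategories()) ||
      abs(sum(object@taxonMixture) - 1) > 1e-9)
    msg <- c(msg, "taxon mixture must be over the fixed vocabulary and sum to 1")
  gc <- object@goCatalog
  need <- c("term", "namespace", "backgroundProb", "plantedFold")
  if (!all(need %in% names(gc)))
    msg <- c(msg, "goCatalog needs columns term, namespace, backgroundProb, plantedFold")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme:", object@matrixName,
      " gapOpen:", object@gapOpen,
      " gapExtend:", object@gapExtend, "\n")
})

setMethod("show", "GlocalAlignment", function(object) {
  cat("GlocalAlignment (query global / target local)\n")
  cat("  query : ", object@queryAln, "\n", sep = "")
  cat("  target: ", object@targetAln, "  [",
      object@targetStart, "-", object@targetEnd, "]\n", sep = "")
  cat(sprintf("  score: %d  identity: %.1f%%", object@score, object@identity))
  if (!is.na(object@evalue)) cat(sprintf("  E-value: %.3g", object@evalue))
  cat("\n")
})

setMethod("show", "EValueModel", function(object) {
  cat(sprintf(
    "EValueModel (Gumbel): mu = %.3f, beta = %.3f, databaseSize = %g (n = %d)\n",
    object@mu, object@beta, object@databaseSize, object@nSamples))
})

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable with", length(object@accession), "proteins,",
      length(unique(object@taxonCategory)), "taxon categories\n")
})

setMethod("show", "MotifSet", function(object) {
  cat("MotifSet for query", object@query, "with",
      length(object@motifs), "unique motifs\n")
  if (length(object@motifs))
    cat("  head:", paste(utils::head(object@motifs, 5), collapse = " "), "\n")
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat("PositionFrequencyMatrix:", nrow(object@freq), "positions from",
      object@motifCount, "motifs\n")
})

setMethod("show", "MotifProfile", function(object) {
  cat("MotifProfile", object@name, "of length", nrow(object@probs), "\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nProteins, "proteins, planting rate",
      object@plantingRate, ", profile", object@profile@name,
      ", seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## Simple accessors
## ---------------------------------------------------------------------------

#' Accessors for slimscan classes
#'
#' Small read-only accessors for the package's S4 containers.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
motifs <- function(x) {
  stopifnot(is(x, "MotifSet"))
  x@motifs
}

#' @rdname accessors
#' @export
provenance <- function(x) {
  stopifnot(is(x, "MotifSet"))
  x@provenance
}

#' @rdname accessors
#' @export
motifCount <- function(x) {
  stopifnot(is(x, "PositionFrequencyMatrix"))
  x@motifCount
}

#' @rdname accessors
#' @export
frequencies <- function(x) {
  if (is(x, "PositionFrequencyMatrix")) return(x@freq)
  if (is(x, "MotifProfile")) return(x@probs)
  stop("no frequencies() accessor for class ", class(x))
}

#' @rdname accessors
#' @export
alignmentScore <- function(x) {
  stopifnot(is(x, "GlocalAlignment"))
  x@score
}

#' @rdname accessors
#' @export
targetRange <- function(x) {
  stopifnot(is(x, "GlocalAlignment"))
  c(start = x@targetStart, end = x@targetEnd)
}

#' Annotation table as a data frame
#'
#' Flattens an [AnnotationTable-class] to one row per accession with GO
#' terms re-joined as semicolon-separated \code{term:namespace} pairs
#' (the on-disk TSV representation).
#'
#' @param x An `AnnotationTable`.
#' @param ... Unused.
#' @return A `data.frame` with columns `accession`, `gene_symbol`,
#'   `taxon_category`, `go_terms`.
#' @export
setMethod("as.data.frame", "AnnotationTable", function(x, ...) {
  go <- vapply(x@goTerms, function(g) {
    if (!nrow(g)) return("")
    paste(paste0(g$term, ":", g$namespace), collapse = ";")
  }, character(1))
  data.frame(
    accession = x@accession,
    gene_symbol = x@geneSymbol,
    taxon_category = x@taxonCategory,
    go_terms = go,
    stringsAsFactors = FALSE
  )
})

#' Long-format GO annotation table
#'
#' @param ann An `AnnotationTable`.
#' @return A `data.frame` with one row per (accession, term) pair and
#'   columns `accession`, `gene_symbol`, `taxon_category`, `term`,
#'   `namespace`.
#' @export
goLong <- function(ann) {
  stopifnot(is(ann, "AnnotationTable"))
  n <- vapply(ann@goTerms, nrow, integer(1))
  data.frame(
    accession = rep(ann@accession, n),
    gene_symbol = rep(ann@geneSymbol, n),
    taxon_category = rep(ann@taxonCategory, n),
    term = unlist(lapply(ann@goTerms, function(g) g$term), use.names = FALSE),
    namespace = unlist(lapply(ann@goTerms, function(g) g$namespace),
                       use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
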