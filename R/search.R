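#' Default acceptance thresholds for a query peptide
#'
#' The cut-offs applied to database alignments: maximum E-value 0.1 and
#' a minimum identity degree that depends on query length — 57.1% for
#' 7-mer queries (4/7 identities) and 55.6% for 9-mer queries (5/9),
#' the values used for the two packaged queries. Other query lengths
#' default to the same majority-of-columns rule,
#' \eqn{\lceil L/2 \rceil / L}. At most `maxHits` alignments are
#' retained.
#'
#' @param query Query peptide (its length selects the identity cut-off).
#' @param maxEvalue Maximum E-value; default 0.1.
#' @param minIdentity Minimum identity degree (percent); default chosen
#'   from the query length as described.
#' @param maxHits Maximum number of retained alignments; default 500.
#' @return A list with elements `maxEvalue`, `minIdentity`, `maxHits`.
#' @export
#' @examples
#' searchThresholds("LDSYQCT")$minIdentity    # 57.1
#' searchThresholds("EMTPVNPGV")$minIdentity  # 55.6
searchThresholds <- function(query, maxEvalue = 0.1, minIdentity = NULL,
                             maxHits = 500L) {
  L <- nchar(query)
  if (is.null(minIdentity)) {
    k <- ceiling(L / 2) # majority of columns: 4/7 = 57.1%, 5/9 = 55.6%
    minIdentity <- round(100 * k / L, 1)
  }
  if (maxEvalue <= 0) stop("maxEvalue must be > 0")
  if (minIdentity < 0 || minIdentity > 100)
    stop("minIdentity must lie in [0, 100]")
  maxHits <- as.integer(maxHits)
  if (maxHits < 1L) stop("maxHits must be >= 1")
  list(maxEvalue = maxEvalue, minIdentity = minIdentity, maxHits = maxHits)
}

#' Scan a protein database for motifs similar to a query peptide
#'
#' Computes one best glocal alignment per database record, assigns
#' E-values under the calibrated Gumbel model (scaled to the database
#' size), and keeps alignments passing both cut-offs: E-value \eqn{\le}
#' `maxEvalue` and identity degree \eqn{\ge} `minIdentity`. Hits are
#' sorted by ascending E-value (ties by accession) and truncated at
#' `maxHits`. Fully deterministic.
#'
#' @param query Query peptide string.
#' @param database An `AAStringSet` (e.g. from [readFasta()]).
#' @param scheme A [ScoringScheme-class].
#' @param evd An [EValueModel-class] from [calibrateEvd()]; if its
#'   `databaseSize` is `NA` it is set to `length(database)`.
#' @param thresholds A list as returned by [searchThresholds()].
#' @param annotations Optional [AnnotationTable-class]; if supplied,
#'   gene symbols and taxon categories are attached to hits (missing
#'   accessions yield `NA`).
#' @return A `data.frame` with one row per hit: `accession`,
#'   `gene_symbol`, `taxon_category`, `motif` (ungapped target
#'   subsequence), `target_start`, `target_end` (1-based inclusive),
#'   `score`, `identity`, `evalue`, `query_aln`, `target_aln`, plus the
#'   query as attribute `"query"`.
#' @export
scanDatabase <- function(query, database, scheme = buildScoring(), evd,
                         thresholds = searchThresholds(query),
                         annotations = NULL) {
  stopifnot(is(evd, "EValueModel"))
  if (length(database) == 0L) stop("database is empty")
  if (is.na(evd@databaseSize))
    databaseSize(evd) <- length(database)
  acc <- accessions(database)
  seqs <- as.character(database)
  rows <- lapply(seq_along(seqs), function(i) {
    aln <- alignGlocal(query, seqs[[i]], scheme, evd)
    data.frame(
      accession = acc[i],
      motif = gsub("-", "", aln@targetAln, fixed = TRUE),
      target_start = aln@targetStart,
      target_end = aln@targetEnd,
      score = aln@score,
      identity = aln@identity,
      evalue = aln@evalue,
      query_aln = aln@queryAln,
      target_aln = aln@targetAln,
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  keep <- hits$evalue <= thresholds$maxEvalue &
          hits$identity >= thresholds$minIdentity
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$evalue, hits$accession), , drop = FALSE]
  if (nrow(hits) > thresholds$maxHits)
    hits <- hits[seq_len(thresholds$maxHits), , drop = FALSE]
  if (!is.null(annotations)) {
    idx <- match(hits$accession, annotations@accession)
    hits$gene_symbol <- annotations@geneSymbol[idx]
    hits$taxon_category <- annotations@taxonCategory[idx]
  } else {
    hits$gene_symbol <- rep(NA_character_, nrow(hits))
    hits$taxon_category <- rep(NA_character_, nrow(hits))
  }
  hits <- hits[, c("accession", "gene_symbol", "taxon_category", "motif",
                   "target_start", "target_end", "score", "identity",
                   "evalue", "query_aln", "target_aln")]
  rownames(hits) <- NULL
  attr(hits, "query") <- query
  hits
}

#' Deduplicate hits into a unique motif set
#'
#' Collapses a hit table to unique motif sequences: the first
#' occurrence (best E-value, given [scanDatabase()]'s sort) represents
#' each motif, and provenance aggregates every contributing accession.
#' This mirrors the exclusion of identical motifs recovered from the
#' same protein in different taxonomies. Idempotent.
#'
#' @param hits A hit `data.frame` from [scanDatabase()] (must carry the
#'   `"query"` attribute; mixing hits of different queries is an error).
#' @return A [MotifSet-class].
#' @export
#' @examples
#' h <- data.frame(accession = c("p1", "p2"), motif = c("MDSYQCT", "MDSYQCT"),
#'                 evalue = c(1e-5, 1e-4))
#' attr(h, "query") <- "LDSYQCT"
#' dedupMotifs(h)
dedupMotifs <- function(hits) {
  query <- attr(hits, "query")
  if (is.null(query) || length(query) != 1L)
    stop("hits must come from a single query (missing \"query\" attribute)")
  if (!nrow(hits))
    return(new("MotifSet", motifs = character(), provenance = list(),
               query = query))
  if (is.unsorted(hits$evalue)) {
    hits <- hits[order(hits$evalue), , drop = FALSE]
  }
  uniq <- !duplicated(hits$motif)
  prov <- split(hits$accession, hits$motif)
  motifs <- hits$motif[uniq]
  new("MotifSet", motifs = motifs, provenance = prov[motifs], query = query)
}

#' @rdname dedupMotifs
#' @param x A `MotifSet`.
#' @export
setMethod("length", "MotifSet", function(x) length(x@motifs))
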