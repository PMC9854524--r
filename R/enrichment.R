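#' Count unique genes per GO term
#'
#' For a study gene list, counts the number of distinct genes carrying
#' each GO term (a gene annotated twice with the same term counts
#' once; one gene may contribute to many terms). Genes absent from the
#' annotation table are skipped with a message. Results are ranked by
#' descending count, ties alphabetical by term.
#'
#' @param studyGenes Character vector of gene symbols.
#' @param annotations An [AnnotationTable-class].
#' @return A `data.frame` with columns `term`, `namespace`, `count`,
#'   sorted as described.
#' @export
classifyTerms <- function(studyGenes, annotations) {
  if (!length(studyGenes)) stop("empty study gene set")
  long <- goLong(annotations)
  missing <- setdiff(studyGenes, annotations@geneSymbol)
  if (length(missing))
    message(length(missing), " study gene(s) missing from annotations; skipped")
  long <- long[long$gene_symbol %in% studyGenes, , drop = FALSE]
  long <- unique(long[, c("gene_symbol", "term", "namespace")])
  if (!nrow(long))
    return(data.frame(term = character(), namespace = character(),
                      count = integer(), stringsAsFactors = FALSE))
  agg <- aggregate(gene_symbol ~ term + namespace, data = long,
                   FUN = function(g) length(unique(g)))
  names(agg)[3] <- "count"
  agg <- agg[order(-agg$count, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Hypergeometric GO-term enrichment with BH-FDR
#'
#' For every GO term carried by at least one study gene, computes the
#' upper-tail hypergeometric probability of observing `k` or more
#' study genes with the term when `n` study genes are drawn from a
#' background of `N_bg` genes of which `K` carry it —
#' \eqn{p = P[X \ge k]}, \eqn{X \sim \mathrm{Hypergeom}(N_{bg}, K, n)}.
#' Nominal p-values are adjusted across all tested terms by
#' Benjamini-Hochberg; fold enrichment is \eqn{(k/n) / (K/N_{bg})}
#' (the study fraction over the background fraction). Terms with
#' `fdr <= fdrCutoff` are flagged `significant`. Results are sorted by
#' descending fold enrichment, then ascending p.
#'
#' Annotations are taken as given (flat): no GO-DAG ancestor
#' propagation is performed.
#'
#' @param studyGenes Character vector of study gene symbols (must be a
#'   subset of `backgroundGenes`).
#' @param backgroundGenes Character vector of background gene symbols;
#'   defaults to every gene in `annotations`.
#' @param annotations An [AnnotationTable-class].
#' @param fdrCutoff Significance flag cut-off on the BH-adjusted value;
#'   default 0.2.
#' @return A `data.frame` with columns `term`, `namespace`, `k`, `n`,
#'   `K`, `N_bg`, `fold_enrichment`, `p_value`, `fdr`, `significant`.
#' @export
enrichTerms <- function(studyGenes, backgroundGenes = NULL, annotations,
                        fdrCutoff = 0.2) {
  if (is.null(backgroundGenes))
    backgroundGenes <- unique(annotations@geneSymbol)
  studyGenes <- unique(studyGenes)
  backgroundGenes <- unique(backgroundGenes)
  if (!length(studyGenes) || !length(backgroundGenes))
    stop("study and background gene sets must be non-empty")
  if (!all(studyGenes %in% backgroundGenes))
    stop("study genes must be a subset of the background: missing ",
         paste(utils::head(setdiff(studyGenes, backgroundGenes), 3),
               collapse = ", "))
  long <- goLong(annotations)
  long <- unique(long[, c("gene_symbol", "term", "namespace")])
  long <- long[long$gene_symbol %in% backgroundGenes, , drop = FALSE]
  n <- length(studyGenes)
  N <- length(backgroundGenes)
  termKey <- paste(long$term, long$namespace, sep = "\r")
  Kall <- tapply(long$gene_symbol, termKey, function(g) length(unique(g)))
  inStudy <- long[long$gene_symbol %in% studyGenes, , drop = FALSE]
  if (!nrow(inStudy))
    return(data.frame(term = character(), namespace = character(),
                      k = integer(), n = integer(), K = integer(),
                      N_bg = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  kTab <- tapply(inStudy$gene_symbol,
                 paste(inStudy$term, inStudy$namespace, sep = "\r"),
                 function(g) length(unique(g)))
  keys <- names(kTab)
  k <- as.integer(kTab)
  K <- as.integer(Kall[keys])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fdr <- bhFdr(p)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  res <- data.frame(
    term = vapply(parts, `[`, character(1), 1L),
    namespace = vapply(parts, `[`, character(1), 2L),
    k = k, n = n, K = K, N_bg = N,
    fold_enrichment = (k / n) / (K / N),
    p_value = p, fdr = fdr,
    significant = fdr <= fdrCutoff,
    stringsAsFactors = FALSE)
  res <- res[order(-res$fold_enrichment, res$p_value, res$term), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: on sorted
#' p-values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, mapped back
#' to the input order.
#'
#' @param pValues Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted values, same order as the input.
#' @export
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))  # all 0.03
bhFdr <- function(pValues) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Taxonomic distribution of a hit set
#'
#' Counts unique genes per taxonomic category among annotated hits and
#' converts to percentages. A gene symbol recovered from several
#' proteins within one category counts once there; orthologs appearing
#' in different categories count once per category. The full
#' [taxonCategories()] vocabulary is always present (zero counts kept),
#' so output columns are stable.
#'
#' @param hits A hit `data.frame` from [scanDatabase()] with
#'   `gene_symbol` and `taxon_category` filled, or any data frame with
#'   those columns.
#' @return A `data.frame` with columns `taxon_category`, `unique_genes`,
#'   `percent`, one row per vocabulary category.
#' @export
taxonProfile <- function(hits) {
  need <- c("gene_symbol", "taxon_category")
  if (!all(need %in% names(hits)))
    stop("hits must carry gene_symbol and taxon_category columns")
  h <- hits[!is.na(hits$taxon_category), need, drop = FALSE]
  unknown <- setdiff(unique(h$taxon_category), taxonCategories())
  if (length(unknown))
    stop("unknown taxon category label(s): ", paste(unknown, collapse = ", "))
  h <- unique(h)
  counts <- table(factor(h$taxon_category, levels = taxonCategories()))
  total <- sum(counts)
  pct <- if (total > 0) 100 * as.numeric(counts) / total
         else rep(0, length(counts))
  data.frame(
    taxon_category = taxonCategories(),
    unique_genes = as.integer(counts),
    percent = pct,
    stringsAsFactors = FALSE)
}
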