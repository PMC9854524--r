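#' Read a protein FASTA file
#'
#' Parses a protein FASTA into an `AAStringSet` (the Bioconductor
#' container for amino-acid sequences). Sequences are uppercased; the
#' ambiguity codes B, Z, U and O are mapped to X with a single warning;
#' any residue outside the 20-letter alphabet plus X raises an error
#' naming the offending line. Record order is preserved and names carry
#' the full header (`accession description`).
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] with one element per record.
#' @seealso [writeFasta()], [accessions()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "LDSYQCT"), f)
#' readFasta(f)
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## read without alphabet restriction so residue validation (with line
  ## numbers) happens here rather than deep inside Biostrings
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) return(aa)
  seqs <- toupper(as.character(aa))
  mapped <- chartr("BZUO", "XXXX", seqs)
  if (any(mapped != seqs))
    warning("ambiguity codes B/Z/U/O mapped to X in ",
            sum(mapped != seqs), " sequence(s)")
  bad <- grepl(paste0("[^", paste(c(aminoAcids(), "X"), collapse = ""), "]"),
               mapped)
  if (any(bad)) {
    .fastaResidueError(path, which(bad)[1])
  }
  empty <- !nzchar(mapped)
  if (any(empty))
    stop("empty sequence for record: ", names(aa)[which(empty)[1]])
  out <- Biostrings::AAStringSet(mapped)
  names(out) <- names(aa)
  out
}

## locate the first illegal residue line for an informative parse error
.fastaResidueError <- function(path, recordIdx) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  from <- headers[recordIdx] + 1L
  to <- if (recordIdx < length(headers)) headers[recordIdx + 1L] - 1L
        else length(lines)
  legal <- paste0("[^", paste(c(aminoAcids(), "X"), collapse = ""), "]")
  for (ln in seq(from, to)) {
    probe <- chartr("BZUO", "XXXX", toupper(lines[ln]))
    if (grepl(legal, probe))
      stop("illegal residue at line ", ln, " of ", path, ": ",
           regmatches(probe, regexpr(legal, probe)))
  }
  stop("illegal residue in record ", recordIdx, " of ", path)
}

#' Write a protein FASTA file
#'
#' Writes sequences one record per block; round-trips with
#' [readFasta()] byte-identically at the sequence level.
#'
#' @param sequences An `AAStringSet` (or named character vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(sequences, path) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path, width = 60L)
  invisible(path)
}

#' @rdname readFasta
#' @param sequences An `AAStringSet` as returned by [readFasta()].
#' @return `accessions()`: character vector of the first whitespace-
#'   delimited token of each header.
#' @export
accessions <- function(sequences) {
  sub("\\s.*$", "", names(sequences))
}

#' Read a protein annotation table
#'
#' Reads a TSV with header columns `accession`, `gene_symbol`,
#' `taxon_category` and `go_terms`, the last holding semicolon-joined
#' `GO:nnnnnnn:NS` triples with namespace `MF` or `BP` (empty cell =
#' no annotation). Lines starting with `#` are ignored. Duplicate
#' accessions, unknown namespaces and taxon labels outside
#' [taxonCategories()] are errors.
#'
#' @param path Path to the TSV.
#' @return An [AnnotationTable-class].
#' @seealso [writeAnnotations()], [goLong()]
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, comment.char = "#", colClasses = "character",
                   na.strings = NULL, check.names = FALSE)
  need <- c("accession", "gene_symbol", "taxon_category", "go_terms")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("duplicate accession in annotation table: ",
         df$accession[duplicated(df$accession)][1])
  go <- lapply(df$go_terms, .parseGoCell)
  ann <- new("AnnotationTable",
    accession = df$accession,
    geneSymbol = df$gene_symbol,
    taxonCategory = df$taxon_category,
    goTerms = go)
  validObject(ann)
  ann
}

.parseGoCell <- function(cell) {
  if (is.na(cell) || !nzchar(cell))
    return(data.frame(term = character(), namespace = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(cell, ";", fixed = TRUE)[[1]]
  ns <- sub("^.*:", "", parts)
  term <- sub(":[^:]*$", "", parts)
  if (!all(ns %in% c("MF", "BP")))
    stop("unknown GO namespace: ", paste(setdiff(ns, c("MF", "BP")),
                                         collapse = ", "))
  unique(data.frame(term = term, namespace = ns, stringsAsFactors = FALSE))
}

#' Write an annotation table as TSV
#'
#' @param ann An [AnnotationTable-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAnnotations <- function(ann, path) {
  writeTable(as.data.frame(ann), path)
}

#' Write a tabular result as TSV
#'
#' The single tabular dialect used for all stage outputs: tab-separated,
#' UTF-8, header row, no quoting, no row names. Floating-point columns
#' are rendered with 6 significant digits (scientific notation where
#' shorter, so E-values like `3.9e-11` stay readable); integer-valued
#' columns are written as integers. Deterministic column order (the
#' order of `df`).
#'
#' @param df A data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns. Default 6.
#' @return Invisibly, `path`.
#' @seealso [readTable()]
#' @export
writeTable <- function(df, path, digits = 6L) {
  out <- df
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.double(x)) {
      out[[j]] <- ifelse(is.na(x), "NA",
                         trimws(formatC(x, digits = digits, format = "g")))
    }
  }
  con <- file(path, open = "wb") # fixed newline convention across platforms
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [writeTable()]
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
readTable <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}
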