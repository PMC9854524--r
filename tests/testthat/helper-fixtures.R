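# Shared fixtures, all generated in code.

# write a FASTA file from a named character vector, return its path
tmpFasta <- function(seqs, dir = tempdir()) {
  path <- tempfile("db", tmpdir = dir, fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}

# write an annotation TSV, return its path; rows = list of character
# vectors c(accession, gene, taxon, go)
tmpAnnotations <- function(rows, dir = tempdir()) {
  path <- tempfile("ann", tmpdir = dir, fileext = ".tsv")
  writeLines(c(
    "accession\tgene_symbol\ttaxon_category\tgo_terms",
    vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# annotation table built directly (no file), for enrichment tests:
# genes annotated with term sets; taxon defaults to bacteria
makeAnnotations <- function(geneTerms, taxa = NULL) {
  genes <- names(geneTerms)
  acc <- paste0("acc_", genes)
  if (is.null(taxa)) taxa <- rep("bacteria", length(genes))
  go <- lapply(geneTerms, function(tt) {
    if (!length(tt))
      return(data.frame(term = character(), namespace = character(),
                        stringsAsFactors = FALSE))
    data.frame(term = tt, namespace = rep("MF", length(tt)),
               stringsAsFactors = FALSE)
  })
  new("AnnotationTable", accession = acc, geneSymbol = genes,
      taxonCategory = taxa, goTerms = unname(go))
}

# exhaustive hypergeometric upper tail by subset enumeration:
# probability of drawing >= k marked among n draws from N with K marked
enumHyperTail <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(sets %in% marked, nrow = n))
  mean(hits >= k)
}

# random residue string
randSeq <- function(L, alphabet = aminoAcids()) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}
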