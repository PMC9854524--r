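#' Build a substitution scoring scheme
#'
#' Assembles a validated [ScoringScheme-class]: a 21x21 integer
#' substitution matrix (the 20 standard residues plus X) together with
#' affine gap penalties. The default parameters — BLOSUM50 with gap open
#' -10 and gap extension -2 — are the GLSEARCH defaults used throughout
#' the package. The matrix values are the canonical NCBI BLOSUM50 table
#' as packaged by Biostrings; X scores with its BLOSUM50 row.
#'
#' A gap run of length \eqn{L} costs \eqn{gapOpen + (L-1) \cdot
#' gapExtend} (FastA convention: the first gapped residue pays the open
#' penalty, each further residue the extension penalty).
#'
#' @param matrixName Name of the substitution matrix; only
#'   \code{"BLOSUM50"} is packaged.
#' @param gapOpen Integer penalty (\eqn{\le 0}) for the first residue of
#'   a gap run. Default -10.
#' @param gapExtend Integer penalty (\eqn{\le 0}) for each subsequent
#'   residue of a gap run. Default -2. Must satisfy
#'   \code{gapOpen <= gapExtend <= 0}.
#' @return A [ScoringScheme-class] object.
#' @export
#' @examples
#' sc <- buildScoring()
#' substitutionMatrix(sc)["C", "C"]  # 13
buildScoring <- function(matrixName = "BLOSUM50", gapOpen = -10L,
                         gapExtend = -2L) {
  if (!identical(matrixName, "BLOSUM50"))
    stop("unknown substitution matrix: ", matrixName)
  gapOpen <- as.integer(gapOpen)
  gapExtend <- as.integer(gapExtend)
  if (is.na(gapOpen) || is.na(gapExtend) ||
      !(gapOpen <= gapExtend && gapExtend <= 0L))
    stop("gap penalties must satisfy gapOpen <= gapExtend <= 0")
  letters21 <- c(aminoAcids(), "X")
  full <- get(data("BLOSUM50", package = "Biostrings",
                   envir = environment()), envir = environment())
  m <- full[letters21, letters21]
  storage.mode(m) <- "integer"
  new("ScoringScheme", matrixName = matrixName, matrix = m,
      gapOpen = gapOpen, gapExtend = gapExtend)
}

#' @rdname buildScoring
#' @param scheme A `ScoringScheme`.
#' @export
substitutionMatrix <- function(scheme) {
  stopifnot(is(scheme, "ScoringScheme"))
  scheme@matrix
}

#' @rdname buildScoring
#' @export
gapPenalties <- function(scheme) {
  stopifnot(is(scheme, "ScoringScheme"))
  c(open = scheme@gapOpen, extend = scheme@gapExtend)
}

## residue string -> 0-based indices into the 21-letter matrix
.residueIndex <- function(x) {
  letters21 <- c(aminoAcids(), "X")
  idx <- match(strsplit(x, "")[[1]], letters21) - 1L
  if (anyNA(idx))
    stop("illegal residue in sequence: ",
         paste(unique(setdiff(strsplit(x, "")[[1]], letters21)),
               collapse = ", "))
  idx
}
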