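#' Per-position residue frequencies of a motif set
#'
#' For an equal-length, gap-free motif collection, computes the L x 20
#' percentage matrix \eqn{N = a / b \times 100\%}, where \eqn{a} is the
#' count of a residue at a position and \eqn{b} the total number of
#' motifs counted. Motifs containing X are excluded from counting with
#' a warning (X is not one of the 20 logo residues).
#'
#' @param motifSet A [MotifSet-class], or a character vector of motifs.
#' @return A [PositionFrequencyMatrix-class] whose `motifCount()` is
#'   the denominator \eqn{b}.
#' @seealso [consensusNotation()], [logoColumns()]
#' @export
#' @examples
#' pfm <- positionFrequencies(c("LDS", "LDT", "MDS", "LES"))
#' frequencies(pfm)["1", "L"]  # 75
positionFrequencies <- function(motifSet) {
  m <- if (is(motifSet, "MotifSet")) motifs(motifSet) else motifSet
  if (!length(m)) stop("empty motif set")
  hasX <- grepl("X", m, fixed = TRUE)
  if (any(hasX)) {
    warning(sum(hasX), " motif(s) containing X excluded from frequency counts")
    m <- m[!hasX]
    if (!length(m)) stop("no motifs left after excluding X-containing ones")
  }
  L <- unique(nchar(m))
  if (length(L) != 1L)
    stop("motifs must be of equal length (got lengths ",
         paste(sort(L), collapse = ", "), ")")
  b <- length(m)
  chars <- matrix(unlist(strsplit(m, ""), use.names = FALSE),
                  nrow = b, ncol = L, byrow = TRUE)
  freq <- t(apply(chars, 2, function(col) {
    100 * tabulate(factor(col, levels = aminoAcids()), nbins = 20L) / b
  }))
  colnames(freq) <- aminoAcids()
  rownames(freq) <- as.character(seq_len(L))
  new("PositionFrequencyMatrix", freq = freq, motifCount = as.integer(b))
}

#' Consensus notation with bracketed alternates
#'
#' Per position, the major residue is the one with maximal frequency
#' (ties broken alphabetically, with a message); alternates are the
#' remaining residues with frequency at or above `altThreshold`
#' percent, listed in descending frequency. The notation concatenates
#' the major residue followed by the alternates in square brackets,
#' brackets omitted when there are none — e.g. `L[MIV]D[NE]...`.
#'
#' @param pfm A [PositionFrequencyMatrix-class].
#' @param altThreshold Inclusion threshold for alternates, percent
#'   (inclusive: a residue at exactly the threshold is listed).
#'   Default 5.
#' @return A list with elements `major` (character vector, one residue
#'   per position), `alternates` (list of character vectors, descending
#'   frequency) and `notation` (single string).
#' @export
#' @examples
#' pfm <- positionFrequencies(c(rep("LD", 6), rep("MD", 3), rep("ID", 1)))
#' consensusNotation(pfm)$notation  # "L[MI]D"
consensusNotation <- function(pfm, altThreshold = 5) {
  stopifnot(is(pfm, "PositionFrequencyMatrix"))
  if (altThreshold <= 0 || altThreshold >= 100)
    stop("altThreshold must lie strictly between 0 and 100")
  f <- frequencies(pfm)
  major <- character(nrow(f))
  alternates <- vector("list", nrow(f))
  pieces <- character(nrow(f))
  for (p in seq_len(nrow(f))) {
    row <- f[p, ]
    top <- max(row)
    cand <- names(row)[row == top]
    if (length(cand) > 1L)
      message("position ", p, ": tie for major residue among ",
              paste(cand, collapse = "/"), "; broken alphabetically")
    major[p] <- sort(cand)[1]
    rest <- row[setdiff(names(row), major[p])]
    alt <- rest[rest >= altThreshold]
    alt <- alt[order(-alt, names(alt))]
    alternates[[p]] <- names(alt)
    pieces[p] <- if (length(alt))
      paste0(major[p], "[", paste(names(alt), collapse = ""), "]")
    else major[p]
  }
  list(major = major, alternates = alternates,
       notation = paste(pieces, collapse = ""))
}

#' Parse a consensus notation string
#'
#' Inverse of the notation built by [consensusNotation()]: splits a
#' string like `"L[MIV]D[NE]CT[S]"` back into per-position major
#' residues and alternate lists.
#'
#' @param notation Consensus string.
#' @return A list with elements `major` and `alternates` matching
#'   [consensusNotation()]'s output.
#' @export
parseConsensus <- function(notation) {
  tokens <- regmatches(notation,
    gregexpr("[A-Z](\\[[A-Z]+\\])?", notation))[[1]]
  if (nchar(paste(tokens, collapse = "")) != nchar(notation))
    stop("malformed consensus notation: ", notation)
  major <- substr(tokens, 1, 1)
  alternates <- lapply(tokens, function(tk) {
    if (nchar(tk) > 1L)
      strsplit(substr(tk, 3, nchar(tk) - 1L), "")[[1]]
    else character()
  })
  list(major = major, alternates = alternates)
}

#' Sequence-logo information content per position
#'
#' For each position with residue fractions \eqn{f} (frequencies /
#' 100), the Shannon entropy is \eqn{H = -\sum f \log_2 f} over
#' \eqn{f > 0} and the information content is \eqn{IC = \log_2 20 - H -
#' e_n}, floored at zero, where the optional small-sample correction is
#' \eqn{e_n = (20 - 1) / (2 \ln 2 \cdot b)} with \eqn{b} the motif
#' count (the WebLogo convention). Symbol heights partition the IC in
#' proportion to residue fraction, as in a sequence logo stack.
#'
#' @param pfm A [PositionFrequencyMatrix-class].
#' @param corrected Apply the small-sample correction? Default `TRUE`
#'   (WebLogo parity); the PFM/consensus path itself never corrects.
#' @return A `data.frame` with one row per (position, residue) pair of
#'   positive height, plus per-position `information_content` in bits;
#'   attribute `"ic"` holds the per-position IC vector.
#' @export
logoColumns <- function(pfm, corrected = TRUE) {
  stopifnot(is(pfm, "PositionFrequencyMatrix"))
  f <- frequencies(pfm) / 100
  b <- motifCount(pfm)
  corr <- if (corrected) (20 - 1) / (2 * log(2) * b) else 0
  ic <- apply(f, 1, function(row) {
    pos <- row[row > 0]
    H <- -sum(pos * log2(pos))
    max(log2(20) - H - corr, 0)
  })
  rows <- lapply(seq_len(nrow(f)), function(p) {
    nz <- f[p, ] > 0
    data.frame(
      position = p,
      residue = colnames(f)[nz],
      height = unname(f[p, nz] * ic[p]),
      information_content = unname(ic[p]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ic") <- unname(ic)
  out
}
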