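#' Glocal (global-in-query, local-in-target) pairwise alignment
#'
#' Aligns the \emph{entire} query peptide against the best-scoring
#' contiguous substring of the target — the semi-global semantics of
#' GLSEARCH. Gaps are scored with affine cost (see [buildScoring()]);
#' end gaps are free on the target only, so the local window may start
#' and end anywhere in the target, while every query residue appears in
#' the alignment. The dynamic program returns one optimal alignment;
#' ties during traceback prefer a residue pair, then a gap in the
#' target, then a gap in the query, and the smallest target end
#' coordinate wins among equal-scoring endpoints, making the result
#' deterministic.
#'
#' @param query Residue string (uppercase, 20-letter alphabet plus X);
#'   the full query is always consumed.
#' @param target Residue string to be searched.
#' @param scheme A [ScoringScheme-class]; defaults to BLOSUM50 with gap
#'   open -10, gap extension -2.
#' @param evd Optional [EValueModel-class]; if supplied, the alignment's
#'   E-value is filled in, otherwise it is `NA`.
#' @return A [GlocalAlignment-class] with the aligned strings, integer
#'   score, 1-based inclusive target coordinates, identity degree
#'   (percent) and E-value.
#' @seealso [identityDegree()], [calibrateEvd()], [scanDatabase()]
#' @export
#' @examples
#' aln <- alignGlocal("LDSYQCT", "MDSYQCT")
#' identityDegree(aln)  # 85.7
alignGlocal <- function(query, target, scheme = buildScoring(), evd = NULL) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("query must be a non-empty residue string")
  if (!is.character(target) || length(target) != 1L || !nzchar(target))
    stop("target must be a non-empty residue string")
  qi <- .residueIndex(query)
  ti <- .residueIndex(target)
  res <- .glocal_align_cpp(qi, ti, substitutionMatrix(scheme),
                           scheme@gapOpen, scheme@gapExtend)
  qChars <- strsplit(query, "")[[1]]
  tChars <- strsplit(target, "")[[1]]
  qa <- ifelse(res$qcol > 0L, qChars[pmax(res$qcol, 1L)], "-")
  ta <- ifelse(res$tcol > 0L, tChars[pmax(res$tcol, 1L)], "-")
  aln <- new("GlocalAlignment",
    query = query,
    queryAln = paste(qa, collapse = ""),
    targetAln = paste(ta, collapse = ""),
    score = as.integer(res$score),
    targetStart = if (is.na(res$targetStart)) 1L else res$targetStart,
    targetEnd = if (is.na(res$targetEnd)) 0L else res$targetEnd,
    identity = NA_real_,
    evalue = NA_real_)
  aln@identity <- identityDegree(aln)
  if (!is.null(evd))
    aln@evalue <- eValue(aln@score, evd)
  aln
}

#' Identity degree of an alignment
#'
#' The percentage of alignment columns in which query and target carry
#' the same residue. Gap columns count in the denominator (total
#' alignment columns), so gaps dilute identity; for gap-free alignments
#' this reduces to matches over alignment length, reproducing the
#' \eqn{k/7} and \eqn{k/9} identity degrees of the worked 7-mer and
#' 9-mer alignments. Reported rounded to one decimal.
#'
#' @param alignment A [GlocalAlignment-class].
#' @return Percentage in \eqn{[0, 100]}, rounded to one decimal place.
#' @export
#' @examples
#' identityDegree(alignGlocal("EMTPVNPGV", "KLGPVDPGV"))  # 55.6
identityDegree <- function(alignment) {
  stopifnot(is(alignment, "GlocalAlignment"))
  qa <- strsplit(alignment@queryAln, "")[[1]]
  ta <- strsplit(alignment@targetAln, "")[[1]]
  same <- qa != "-" & ta != "-" & qa == ta
  round(100 * sum(same) / length(qa), 1)
}

#' Calibrate an empirical extreme-value (Gumbel) E-value model
#'
#' Aligns the query against `nSamples` random sequences drawn from a
#' residue composition and fits a Gumbel distribution to the score
#' sample by the method of moments: \eqn{\beta = s \sqrt{6} / \pi} and
#' \eqn{\mu = \bar{x} - \gamma \beta} (Euler-Mascheroni \eqn{\gamma}).
#' The resulting model converts glocal scores into E-values — the
#' expected number of chance alignments scoring at least as high in a
#' database of `databaseSize` sequences. This is an empirical stand-in
#' for the regression statistics of a full FastA search; it reproduces
#' the behaviour (monotone decreasing in score, linear in database
#' size), not any particular published E-value.
#'
#' @param query Residue string used for calibration.
#' @param scheme A [ScoringScheme-class].
#' @param lengths Integer vector of target lengths; random sequences
#'   sample their lengths uniformly from it (recycle a single value for
#'   fixed length). Default 300.
#' @param composition Named numeric vector over [aminoAcids()] summing
#'   to 1; default uniform.
#' @param nSamples Number of random sequences (>= 100). Default 500.
#' @param databaseSize Number of sequences in the database the E-values
#'   will refer to; may be left `NA` and supplied by [scanDatabase()].
#' @param seed Integer seed; calibration is deterministic given it.
#' @return An [EValueModel-class].
#' @export
calibrateEvd <- function(query, scheme = buildScoring(), lengths = 300L,
                         composition = NULL, nSamples = 500L,
                         databaseSize = NA_real_, seed = 1L) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 100L)
    stop("nSamples must be at least 100 for a stable Gumbel fit")
  if (is.null(composition))
    composition <- setNames(rep(1 / 20, 20), aminoAcids())
  stopifnot(identical(names(composition), aminoAcids()),
            abs(sum(composition) - 1) < 1e-9)
  scores <- withSeed(as.integer(seed), {
    lengths <- as.integer(lengths)
    ls <- if (length(lengths) == 1L) rep(lengths, nSamples)
          else sample(lengths, nSamples, replace = TRUE)
    vapply(ls, function(L) {
      tgt <- paste(sample(aminoAcids(), L, replace = TRUE,
                          prob = composition), collapse = "")
      alignGlocal(query, tgt, scheme)@score
    }, double(1))
  })
  fit <- fitGumbelMoments(scores)
  new("EValueModel", mu = fit[["mu"]], beta = fit[["beta"]],
      databaseSize = as.numeric(databaseSize), nSamples = nSamples)
}

#' Method-of-moments Gumbel fit
#'
#' Estimates the location and scale of a Gumbel (type-I extreme value)
#' distribution from a sample: \eqn{\hat\beta = s\sqrt{6}/\pi},
#' \eqn{\hat\mu = \bar{x} - \gamma \hat\beta}.
#'
#' @param x Numeric sample (non-degenerate).
#' @return Named numeric vector `c(mu, beta)`.
#' @export
fitGumbelMoments <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate score sample (zero variance); cannot fit Gumbel")
  beta <- s * sqrt(6) / pi
  c(mu = mean(x) - 0.5772156649015329 * beta, beta = beta)
}

#' E-value of a glocal score
#'
#' Under the calibrated Gumbel model the per-sequence probability of a
#' chance score \eqn{\ge s} is \eqn{p = 1 - \exp(-\exp(-(s - \mu) /
#' \beta))}; the E-value scales it by the database size, \eqn{E = N
#' \cdot p}, clipped to \eqn{[0, N]}. Strictly decreasing in the score.
#'
#' @param score Numeric alignment score(s).
#' @param evd An [EValueModel-class] with `databaseSize` set.
#' @return Numeric E-value(s), in \eqn{[0, databaseSize]}.
#' @export
eValue <- function(score, evd) {
  stopifnot(is(evd, "EValueModel"))
  if (is.na(evd@databaseSize))
    stop("EValueModel has no databaseSize; set it or let scanDatabase fill it")
  p <- 1 - exp(-exp(-(score - evd@mu) / evd@beta))
  pmin(pmax(evd@databaseSize * p, 0), evd@databaseSize)
}

#' @rdname calibrateEvd
#' @param evd An `EValueModel`.
#' @param value New database size (count of sequences).
#' @export
`databaseSize<-` <- function(evd, value) {
  stopifnot(is(evd, "EValueModel"))
  evd@databaseSize <- as.numeric(value)
  evd
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' previous RNG state afterwards, so library code never perturbs the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Exhaustive-enumeration glocal score (reference oracle)
#'
#' Computes the optimal glocal score by explicitly enumerating every
#' gapped alignment of the full query against every contiguous target
#' substring. Exponential in sequence length — usable only for tiny
#' instances — and entirely independent of the dynamic program, which
#' makes it a reference oracle for testing [alignGlocal()].
#'
#' @param query,target Short residue strings (enumeration is
#'   exponential; keep the query under ~5 and the target under ~10).
#' @param scheme A [ScoringScheme-class].
#' @return Integer optimal score.
#' @export
enumerateGlocalScore <- function(query, target, scheme = buildScoring()) {
  qi <- .residueIndex(query)
  ti <- .residueIndex(target)
  if (length(qi) > 6L || length(ti) > 10L)
    stop("enumeration oracle is exponential; use alignGlocal for real inputs")
  .glocal_enum_cpp(qi, ti, substitutionMatrix(scheme),
                   scheme@gapOpen, scheme@gapExtend)
}
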