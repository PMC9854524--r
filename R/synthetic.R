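#' The packaged query peptides
#'
#' The two alpha-fetoprotein-derived query peptides the package ships
#' defaults for: the 7-mer AFP_14-20 (\code{LDSYQCT}) and the 9-mer
#' GIP-9 (\code{EMTPVNPGV}).
#'
#' @return Named character vector of length 2.
#' @export
#' @examples
#' packagedQueries()
packagedQueries <- function() {
  c(AFP_14_20 = "LDSYQCT", GIP_9 = "EMTPVNPGV")
}

## ---------------------------------------------------------------------------
## Motif profiles
## ---------------------------------------------------------------------------

#' Construct a motif profile
#'
#' A [MotifProfile-class] holds one categorical distribution over the
#' 20 residues per motif position; [drawMotifs()] samples motifs from
#' it position-independently.
#'
#' @param probs Numeric L x 20 matrix, columns named by [aminoAcids()],
#'   rows summing to 1.
#' @param name Profile name.
#' @return A [MotifProfile-class].
#' @seealso [afpMotifProfile()], [gipMotifProfile()],
#'   [benchmarkProfile()]
#' @export
motifProfile <- function(probs, name = "custom") {
  rownames(probs) <- as.character(seq_len(nrow(probs)))
  new("MotifProfile", name = name, probs = probs)
}

## build one profile row: named major/alternate masses, remainder spread
## uniformly over the unnamed residues
.profileRow <- function(...) {
  stated <- c(...)
  row <- setNames(rep(0, 20), aminoAcids())
  row[names(stated)] <- stated
  rest <- setdiff(aminoAcids(), names(stated))
  if (length(rest)) row[rest] <- (1 - sum(stated)) / length(rest)
  if (any(row < -1e-12)) stop("stated masses exceed 1")
  row / sum(row)
}

#' Packaged conservation profile for the AFP-derived 7-mer (LDSYQCT)
#'
#' Per-position residue probabilities encoding the observed
#' conservation of AFP_14-20-like motifs: cysteine is invariant at
#' position 6 (probability 1), aspartate dominates position 2 (82.9%)
#' with N/E alternates, leucine position 1 (57.3%) with M/I/V, serine
#' position 3 (54.8%) with T/K/E, tyrosine position 4 (70%, with F the
#' two aromatics total 83.9%), glutamine position 5 (67.8%) with K/D/R,
#' and the hydroxyl pair T/S shares position 7 (65.3%). Unstated
#' residual mass is spread uniformly below the 5% consensus threshold.
#'
#' @return A [MotifProfile-class] of length 7.
#' @export
#' @examples
#' frequencies(afpMotifProfile())["6", "C"]  # 1
afpMotifProfile <- function() {
  probs <- rbind(
    .profileRow(L = 0.573, M = 0.150, I = 0.120, V = 0.080),
    .profileRow(D = 0.829, N = 0.090, E = 0.060),
    .profileRow(S = 0.548, T = 0.120, K = 0.100, E = 0.080),
    .profileRow(Y = 0.700, F = 0.139),
    .profileRow(Q = 0.678, K = 0.120, D = 0.090, R = 0.060),
    .profileRow(C = 1.000),
    .profileRow(T = 0.400, S = 0.253))
  motifProfile(probs, "AFP_14-20")
}

#' Packaged conservation profile for the GIP-derived 9-mer (EMTPVNPGV)
#'
#' Per-position residue probabilities encoding the observed
#' conservation of GIP-9-like motifs: prolines near-invariant at
#' positions 4 (96%) and 7 (98%), glycine 92% at position 8, and the
#' stated major/alternate frequencies elsewhere (E 60.4% at 1, M 35.4%
#' at 2, T 51.8% / S 12.9% at 3, V 55.0% / I 20.4% / L 7.9% at 5,
#' N 56.8% at 6, V 47.1% / I 18.2% / L 12.1% at 9). Unstated residual
#' mass is spread uniformly below the 5% consensus threshold.
#'
#' @return A [MotifProfile-class] of length 9.
#' @export
gipMotifProfile <- function() {
  probs <- rbind(
    .profileRow(E = 0.604, D = 0.130, Q = 0.090, K = 0.045),
    .profileRow(M = 0.354, L = 0.200, I = 0.150, V = 0.100),
    .profileRow(T = 0.518, S = 0.129),
    .profileRow(P = 0.960),
    .profileRow(V = 0.550, I = 0.204, L = 0.079),
    .profileRow(N = 0.568, D = 0.100, S = 0.080),
    .profileRow(P = 0.980),
    .profileRow(G = 0.920),
    .profileRow(V = 0.471, I = 0.182, L = 0.121))
  motifProfile(probs, "GIP-9")
}

#' Benchmark profile with a guaranteed identity floor
#'
#' Builds a profile for recovery benchmarks in which a small set of
#' variable positions splits its mass between the query residue and
#' one conservative substitute while every other position is
#' degenerate on the query residue. Every draw therefore matches the
#' query in at least \eqn{L - |variable|} positions — for a 7-mer with
#' two variable positions, identity is at least 5/7 = 71.4% by
#' construction. This mirrors how natural motif variants behave:
#' replacements concentrate at the least conserved positions and are
#' physicochemically similar (for LDSYQCT the defaults vary positions
#' 1 and 7, the least conserved in the observed frequency profile,
#' with their most frequent natural alternates M and S).
#'
#' @param query Query peptide the profile is anchored on.
#' @param variable Integer positions allowed to vary. Default: the
#'   first and last position of the query.
#' @param substitutes Replacement residue per variable position;
#'   default the highest-scoring BLOSUM50 partner of the query residue
#'   (the most conservative substitution), ties alphabetical.
#' @param altMass Probability mass given to the substitute residue at a
#'   variable position. Default 0.5.
#' @return A [MotifProfile-class].
#' @export
benchmarkProfile <- function(query, variable = NULL, substitutes = NULL,
                             altMass = 0.5) {
  qres <- strsplit(query, "")[[1]]
  if (is.null(variable)) variable <- c(1L, length(qres))
  stopifnot(all(qres %in% aminoAcids()),
            all(variable %in% seq_along(qres)),
            length(variable) < length(qres),
            altMass > 0, altMass < 1)
  if (is.null(substitutes)) {
    m <- substitutionMatrix(buildScoring())
    substitutes <- vapply(variable, function(p) {
      row <- m[qres[p], setdiff(aminoAcids(), qres[p])]
      names(row)[order(-row, names(row))][1]
    }, character(1))
  }
  stopifnot(length(substitutes) == length(variable),
            all(substitutes %in% aminoAcids()))
  probs <- t(vapply(seq_along(qres), function(p) {
    row <- setNames(rep(0, 20), aminoAcids())
    if (p %in% variable) {
      row[qres[p]] <- 1 - altMass
      row[substitutes[match(p, variable)]] <- altMass
    } else {
      row[qres[p]] <- 1
    }
    row
  }, numeric(20)))
  colnames(probs) <- aminoAcids()
  motifProfile(probs, paste0("benchmark-", query))
}

#' Draw motifs from a profile
#'
#' Samples `n` motif strings i.i.d. from the profile, each position
#' independently from its categorical distribution. Deterministic
#' given the seed.
#'
#' @param profile A [MotifProfile-class].
#' @param n Number of motifs (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n` motifs.
#' @export
#' @examples
#' drawMotifs(afpMotifProfile(), 3, seed = 17)
drawMotifs <- function(profile, n, seed = 1L) {
  stopifnot(is(profile, "MotifProfile"), n >= 1)
  p <- frequencies(profile)
  withSeed(as.integer(seed), {
    cols <- lapply(seq_len(nrow(p)), function(pos) {
      sample(aminoAcids(), n, replace = TRUE, prob = p[pos, ])
    })
    do.call(paste0, cols)
  })
}

## ---------------------------------------------------------------------------
## Synthetic database generation
## ---------------------------------------------------------------------------

#' Swiss-Prot-like background residue composition
#'
#' Average amino-acid frequencies of well-annotated protein databases,
#' normalised to sum to 1; an optional alternative to the uniform 1/20
#' background of [syntheticConfig()].
#'
#' @return Named numeric vector over [aminoAcids()].
#' @export
swissprotComposition <- function() {
  pct <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
           H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
           P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.85,
           W = 1.10, Y = 2.92)
  pct <- pct[aminoAcids()]
  pct / sum(pct)
}

#' Default GO-term catalog for the generator
#'
#' A small flat catalog of MF/BP terms with background annotation
#' probabilities and one term planted at elevated frequency in planted
#' (study) proteins.
#'
#' @param plantedTerm Term receiving the planted enrichment.
#' @param plantedFold Fold elevation of its annotation probability in
#'   planted proteins. Default 4.
#' @return A `data.frame` with columns `term`, `namespace`,
#'   `backgroundProb`, `plantedFold`.
#' @export
defaultGoCatalog <- function(plantedTerm = "GO:0016491",
                             plantedFold = 4) {
  cat <- data.frame(
    term = c("GO:0016491", "GO:0046872", "GO:0003677", "GO:0003824",
             "GO:0005515", "GO:0009055", "GO:0006979", "GO:0006355",
             "GO:0006412", "GO:0055114", "GO:0006281", "GO:0006950"),
    namespace = c("MF", "MF", "MF", "MF", "MF", "MF",
                  "BP", "BP", "BP", "BP", "BP", "BP"),
    backgroundProb = c(0.06, 0.15, 0.10, 0.20, 0.12, 0.05,
                       0.08, 0.10, 0.12, 0.06, 0.07, 0.10),
    plantedFold = 1,
    stringsAsFactors = FALSE)
  cat$plantedFold[cat$term == plantedTerm] <- plantedFold
  cat
}

#' Configure the synthetic database generator
#'
#' Bundles every generator parameter into a validated
#' [SyntheticConfig-class]. Defaults describe a desk-scale stand-in
#' for a protein knowledgebase: 200 proteins with normally distributed
#' lengths (mean 300, sd 80, floored at 60), uniform background
#' composition, half the proteins carrying one planted motif drawn
#' from the AFP 7-mer profile, taxon labels drawn from a
#' bacteria-dominated mixture, and the [defaultGoCatalog()].
#'
#' @param nProteins Number of proteins. Default 200.
#' @param lengthMean,lengthSd Protein length distribution (normal,
#'   rounded, floored at `max(60, motif length)`). Defaults 300 / 80.
#' @param background Named composition over [aminoAcids()]; default
#'   uniform 1/20 (see [swissprotComposition()] for an alternative).
#' @param plantingRate Fraction of proteins receiving one motif.
#'   Default 0.5.
#' @param profile A [MotifProfile-class]. Default [afpMotifProfile()].
#' @param taxonMixture Named probabilities over [taxonCategories()];
#'   default bacteria-dominated per the observed taxonomic spread.
#' @param goCatalog See [defaultGoCatalog()].
#' @param seed Integer seed; the whole generation is deterministic
#'   given it.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nProteins = 200L, lengthMean = 300,
                            lengthSd = 80, background = NULL,
                            plantingRate = 0.5,
                            profile = afpMotifProfile(),
                            taxonMixture = NULL,
                            goCatalog = defaultGoCatalog(),
                            seed = 1L) {
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), aminoAcids())
  if (is.null(taxonMixture)) {
    taxonMixture <- c(
      bacteria = 0.60, viruses = 0.03, archaea = 0.03,
      human = 0.04, primates = 0.02, other_mammals = 0.05,
      birds = 0.02, fishes = 0.03, amphibia = 0.01,
      reptiles = 0.01, insects = 0.02, nematodes = 0.01,
      higher_plants = 0.05, algae = 0.02,
      yeast = 0.01, fungi = 0.03, other_eukaryotes = 0.02)
  }
  new("SyntheticConfig",
      nProteins = as.integer(nProteins),
      lengthMean = lengthMean, lengthSd = lengthSd,
      background = background[aminoAcids()],
      plantingRate = plantingRate, profile = profile,
      taxonMixture = taxonMixture, goCatalog = goCatalog,
      seed = as.integer(seed))
}

#' Generate a synthetic protein database with planted motifs
#'
#' Draws background sequences from the configured composition, splices
#' one profile-drawn motif into a uniform-random position of each
#' planted protein (replacing the residues there, so lengths are
#' preserved), assigns taxon labels from the mixture and GO terms from
#' the catalog — planted proteins receive each term with probability
#' `backgroundProb * plantedFold` (capped at 1) — and records an exact
#' truth table. Byte-identical output for equal seeds.
#'
#' @param config A [SyntheticConfig-class].
#' @return A list with elements `sequences` (`AAStringSet`, headers
#'   `sp<i> synthetic protein <i>`), `annotations`
#'   ([AnnotationTable-class]), and `truth` (a `data.frame` with
#'   columns `accession`, `planted`, `motif`, `insert_position`, plus
#'   attribute `"termFold"`, the configured per-term fold).
#' @export
generateDatabase <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  prof <- config@profile
  motifLen <- nrow(frequencies(prof))
  withSeed(config@seed, {
    n <- config@nProteins
    lens <- pmax(round(rnorm(n, config@lengthMean, config@lengthSd)),
                 max(60L, motifLen))
    if (any(lens < motifLen))
      stop("motif longer than generated protein length")
    seqs <- vapply(lens, function(L) {
      paste(sample(aminoAcids(), L, replace = TRUE,
                   prob = config@background), collapse = "")
    }, character(1))
    planted <- runif(n) < config@plantingRate
    motifSeq <- rep(NA_character_, n)
    insertPos <- rep(NA_integer_, n)
    if (any(planted)) {
      drawn <- .drawMotifsNoSeed(prof, sum(planted))
      idx <- which(planted)
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        pos <- sample.int(lens[i] - motifLen + 1L, 1L)
        substr(seqs[i], pos, pos + motifLen - 1L) <- drawn[ii]
        motifSeq[i] <- drawn[ii]
        insertPos[i] <- pos
      }
    }
    acc <- sprintf("sp%04d", seq_len(n))
    genes <- sprintf("gene_%04d", seq_len(n))
    taxa <- sample(names(config@taxonMixture), n, replace = TRUE,
                   prob = config@taxonMixture)
    gc <- config@goCatalog
    goTerms <- lapply(seq_len(n), function(i) {
      pr <- pmin(gc$backgroundProb *
                   (if (planted[i]) gc$plantedFold else 1), 1)
      hit <- runif(nrow(gc)) < pr
      data.frame(term = gc$term[hit], namespace = gc$namespace[hit],
                 stringsAsFactors = FALSE)
    })
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- paste0(acc, " synthetic protein ", seq_len(n))
    annotations <- new("AnnotationTable", accession = acc,
                       geneSymbol = genes, taxonCategory = taxa,
                       goTerms = goTerms)
    truth <- data.frame(accession = acc, planted = planted,
                        motif = motifSeq, insert_position = insertPos,
                        stringsAsFactors = FALSE)
    attr(truth, "termFold") <- setNames(gc$plantedFold, gc$term)
    list(sequences = sequences, annotations = annotations, truth = truth)
  })
}

## drawMotifs body without seed handling, for use inside a seeded block
.drawMotifsNoSeed <- function(profile, n) {
  p <- frequencies(profile)
  cols <- lapply(seq_len(nrow(p)), function(pos) {
    sample(aminoAcids(), n, replace = TRUE, prob = p[pos, ])
  })
  do.call(paste0, cols)
}
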