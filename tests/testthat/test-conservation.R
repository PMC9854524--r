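test_that("position frequencies implement percent counts over motifs", {
  pfm <- positionFrequencies(c("LDS", "LDT", "MDS", "LES"))
  f <- frequencies(pfm)
  expect_equal(motifCount(pfm), 4L)
  expect_equal(unname(f["1", c("L", "M")]), c(75, 25))
  expect_equal(unname(f["2", c("D", "E")]), c(75, 25))
  expect_equal(unname(f["3", c("S", "T")]), c(75, 25))
  expect_equal(rowSums(f), setNames(rep(100, 3), c("1", "2", "3")))

  single <- positionFrequencies("LDSYQCT")
  expect_true(all(frequencies(single)[cbind(1:7,
    strsplit("LDSYQCT", "")[[1]])] == 100))
})

test_that("ragged or X-containing motifs are handled per contract", {
  expect_error(positionFrequencies(c("LDS", "LDSY")), "equal length")
  expect_warning(pfm <- positionFrequencies(c("LDS", "LXS", "MDS")),
                 "excluded")
  expect_equal(motifCount(pfm), 2L)
  expect_error(positionFrequencies(character()), "empty")
})

test_that("a degenerate profile position yields exactly 100%", {
  m <- drawMotifs(afpMotifProfile(), 199, seed = 17)
  pfm <- positionFrequencies(m)
  expect_equal(unname(frequencies(pfm)["6", "C"]), 100)
})

test_that("consensus notation applies the inclusive 5% threshold", {
  # 1000 motifs with exact counts: L 573, M 200, I 120, V 80, A 27 (pos 1)
  pos1 <- c(rep("L", 573), rep("M", 200), rep("I", 120), rep("V", 80),
            rep("A", 27))
  pfm <- positionFrequencies(paste0(pos1, "D"))
  cons <- consensusNotation(pfm, altThreshold = 5)
  expect_equal(cons$major, c("L", "D"))
  expect_equal(cons$alternates[[1]], c("M", "I", "V"))
  expect_equal(cons$notation, "L[MIV]D")

  # residue at exactly the threshold is included
  atBoundary <- positionFrequencies(c(rep("A", 19), "C"))
  expect_equal(consensusNotation(atBoundary, 5)$notation, "A[C]")
  expect_equal(consensusNotation(atBoundary, 5.0001)$notation, "A")

  # single residue at 100% -> bare letter
  expect_equal(consensusNotation(positionFrequencies("C"))$notation, "C")
})

test_that("major-residue ties break alphabetically with a message", {
  pfm <- positionFrequencies(c("A", "C"))
  expect_message(cons <- consensusNotation(pfm), "tie")
  expect_equal(cons$major, "A")
  expect_equal(cons$alternates[[1]], "C")
})

test_that("notation round-trips and is invariant to motif permutation", {
  set.seed(19)
  for (i in 1:10) {
    m <- drawMotifs(gipMotifProfile(), 150, seed = 100 + i)
    pfm <- positionFrequencies(m)
    cons <- consensusNotation(pfm)
    back <- parseConsensus(cons$notation)
    expect_equal(back$major, cons$major)
    expect_equal(back$alternates, cons$alternates)
    perm <- positionFrequencies(sample(m))
    expect_equal(consensusNotation(perm)$notation, cons$notation)
  }
  expect_error(parseConsensus("L[MI"), "malformed")
})

test_that("logo information content matches closed forms", {
  # uniform over 20 residues: zero information
  uni <- positionFrequencies(paste0(aminoAcids()))
  lg <- logoColumns(uni, corrected = FALSE)
  expect_equal(attr(lg, "ic"), 0)
  expect_true(all(lg$height == 0))

  # single residue: log2(20) bits
  one <- positionFrequencies("C")
  expect_equal(attr(logoColumns(one, corrected = FALSE), "ic"), log2(20))

  # 50/50 split: log2(20) - 1
  half <- positionFrequencies(c("A", "C"))
  expect_equal(attr(logoColumns(half, corrected = FALSE), "ic"),
               log2(20) - 1)

  # heights partition the IC in proportion to frequency
  m <- drawMotifs(afpMotifProfile(), 100, seed = 3)
  pfm <- positionFrequencies(m)
  lg2 <- logoColumns(pfm, corrected = TRUE)
  ic <- attr(lg2, "ic")
  byPos <- tapply(lg2$height, lg2$position, sum)
  expect_equal(as.numeric(byPos), ic, tolerance = 1e-12)
  expect_true(all(ic <= log2(20) & ic >= 0))

  # small-sample correction lowers IC
  lgU <- logoColumns(pfm, corrected = FALSE)
  expect_true(all(attr(lg2, "ic") <= attr(lgU, "ic")))
})

test_that("IC decreases as a column mixes toward uniform", {
  ics <- vapply(seq(0, 1, by = 0.1), function(lambda) {
    row <- (1 - lambda) * c(100, rep(0, 19)) + lambda * rep(5, 20)
    f <- matrix(row, nrow = 1, dimnames = list("1", aminoAcids()))
    pfm <- new("PositionFrequencyMatrix", freq = f, motifCount = 100L)
    attr(logoColumns(pfm, corrected = FALSE), "ic")
  }, numeric(1))
  expect_true(all(diff(ics) <= 1e-12))
  expect_equal(ics[1], log2(20))
  expect_equal(ics[11], 0)
})
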