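test_that("scoring scheme packages BLOSUM50 with validated gap penalties", {
  sc <- buildScoring("BLOSUM50", -10, -2)
  m <- substitutionMatrix(sc)
  expect_equal(dim(m), c(21, 21))
  expect_true(isSymmetric(m))
  expect_identical(unname(gapPenalties(sc)), c(-10L, -2L))
  # canonical matrix: agree with the Biostrings copy of NCBI BLOSUM50
  ref <- local({
    e <- new.env(); data("BLOSUM50", package = "Biostrings", envir = e)
    e$BLOSUM50
  })
  expect_identical(m["C", "C"], ref["C", "C"])
  expect_equal(unname(m[rownames(m), colnames(m)]),
               unname(ref[rownames(m), colnames(m)]))
  expect_error(buildScoring("PAM250"), "unknown")
  expect_error(buildScoring(gapOpen = 1), "penalties")
  expect_error(buildScoring(gapOpen = -2, gapExtend = -10), "penalties")
})

test_that("worked 7-mer and 9-mer alignments reproduce printed identities", {
  cases <- list(
    list("LDSYQCT", "MDSYQCT", 85.7),
    list("LDSYQCT", "LDSYQCT", 100),
    list("EMTPVNPGV", "EMTPINPGL", 77.8),
    list("EMTPVNPGV", "ERTPVNPGV", 88.9),
    list("EMTPVNPGV", "KLGPVDPGV", 55.6),
    list("LDSYQCT", "IDTYQCS", 57.1))
  for (cs in cases) {
    aln <- alignGlocal(cs[[1]], cs[[2]])
    expect_equal(identityDegree(aln), cs[[3]],
                 label = paste(cs[[1]], "vs", cs[[2]]))
    expect_equal(unname(targetRange(aln)), c(1, nchar(cs[[2]])))
  }
})

test_that("glocal alignment is anchored at the motif inside a long target", {
  set.seed(11)
  flanks <- c(randSeq(133), randSeq(160))
  target <- paste0(flanks[1], "MDSYQCT", flanks[2])
  aln <- alignGlocal("LDSYQCT", target)
  expect_equal(unname(targetRange(aln)), c(134, 140))
  expect_equal(identityDegree(aln), 85.7)
})

test_that("self-alignment scores the diagonal sum and beats random targets", {
  q <- "LDSYQCT"
  sc <- buildScoring()
  m <- substitutionMatrix(sc)
  res <- strsplit(q, "")[[1]]
  selfScore <- sum(m[cbind(res, res)])
  expect_equal(alignmentScore(alignGlocal(q, q, sc)), selfScore)
  expect_equal(identityDegree(alignGlocal(q, q, sc)), 100)
  set.seed(3)
  for (i in 1:50) {
    t <- randSeq(nchar(q))
    expect_lte(alignmentScore(alignGlocal(q, t, sc)), selfScore)
  }
})

test_that("DP optimum equals exhaustive enumeration on small instances", {
  sc <- buildScoring()
  set.seed(101)
  sub4 <- c("A", "C", "D", "W")
  for (i in 1:150) {
    q <- randSeq(sample(2:4, 1), sub4)
    t <- randSeq(sample(2:7, 1), sub4)
    expect_identical(alignmentScore(alignGlocal(q, t, sc)),
                     enumerateGlocalScore(q, t, sc),
                     label = paste(q, "vs", t))
  }
  # and under a different (milder) gap regime
  sc2 <- buildScoring(gapOpen = -4L, gapExtend = -1L)
  for (i in 1:150) {
    q <- randSeq(sample(2:4, 1))
    t <- randSeq(sample(2:7, 1))
    expect_identical(alignmentScore(alignGlocal(q, t, sc2)),
                     enumerateGlocalScore(q, t, sc2),
                     label = paste(q, "vs", t))
  }
})

test_that("DP score agrees with an independent global-local implementation", {
  sc <- buildScoring()
  ref <- local({
    e <- new.env(); data("BLOSUM50", package = "Biostrings", envir = e)
    e$BLOSUM50
  })
  set.seed(23)
  for (i in 1:25) {
    q <- randSeq(sample(5:9, 1))
    t <- randSeq(sample(30:80, 1))
    # Biostrings costs a length-L gap gapOpening + L*gapExtension, so the
    # FastA convention open=-10/ext=-2 maps to gapOpening=8, gapExtension=2
    pa <- Biostrings::pairwiseAlignment(
      q, t, type = "global-local", substitutionMatrix = ref,
      gapOpening = 8, gapExtension = 2)
    expect_equal(alignmentScore(alignGlocal(q, t, sc)),
                 unname(Biostrings::score(pa)), label = paste(q, "vs", t))
  }
})

test_that("alignment invariants hold on random instances", {
  sc <- buildScoring()
  set.seed(5)
  for (i in 1:40) {
    q <- randSeq(sample(3:9, 1))
    t <- randSeq(sample(10:60, 1))
    aln <- alignGlocal(q, t, sc)
    qa <- strsplit(aln@queryAln, "")[[1]]
    ta <- strsplit(aln@targetAln, "")[[1]]
    expect_length(ta, length(qa))
    expect_false(any(qa == "-" & ta == "-"))
    expect_identical(paste(qa[qa != "-"], collapse = ""), q)
    rng <- targetRange(aln)
    expect_identical(paste(ta[ta != "-"], collapse = ""),
                     substr(t, rng[1], rng[2]))
    id <- identityDegree(aln)
    expect_gte(id, 0); expect_lte(id, 100)
    if (id == 100) expect_false(any(qa == "-" | ta == "-"))
  }
})

test_that("empty inputs and illegal residues are rejected", {
  expect_error(alignGlocal("", "ACD"), "query")
  expect_error(alignGlocal("ACD", ""), "target")
  expect_error(alignGlocal("AC1", "ACD"), "illegal residue")
})
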