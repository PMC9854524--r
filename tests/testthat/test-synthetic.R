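test_that("packaged profiles are valid and encode the stated conservation", {
  afp <- afpMotifProfile()
  p <- frequencies(afp)
  expect_equal(rowSums(p), setNames(rep(1, 7), as.character(1:7)))
  expect_equal(unname(p["6", "C"]), 1)
  expect_equal(unname(p["2", "D"]), 0.829)
  expect_equal(unname(p["1", "L"]), 0.573)

  gip <- gipMotifProfile()
  g <- frequencies(gip)
  expect_equal(nrow(g), 9)
  expect_equal(unname(g["4", "P"]), 0.96)
  expect_equal(unname(g["7", "P"]), 0.98)
  expect_equal(unname(g["8", "G"]), 0.92)
})

test_that("consensus of large profile draws reproduces the notation rule", {
  m <- drawMotifs(afpMotifProfile(), 5000, seed = 2)
  cons <- consensusNotation(positionFrequencies(m))
  expect_equal(cons$major, strsplit("LDSYQCT", "")[[1]])
  # invariant position has no alternates; D position carries N and E
  expect_equal(cons$alternates[[6]], character())
  expect_setequal(cons$alternates[[2]], c("N", "E"))
})

test_that("motif draws are deterministic and match profile frequencies", {
  prof <- afpMotifProfile()
  expect_identical(drawMotifs(prof, 50, seed = 17),
                   drawMotifs(prof, 50, seed = 17))
  expect_false(identical(drawMotifs(prof, 50, seed = 17),
                         drawMotifs(prof, 50, seed = 18)))

  # degenerate profile: all mass on one sequence
  probs <- frequencies(benchmarkProfile("LDSYQCT", variable = integer(0)))
  expect_equal(unique(drawMotifs(motifProfile(probs), 20, seed = 1)),
               "LDSYQCT")

  # empirical per-position frequencies within 3 SE at n = 10000
  n <- 10000
  m <- drawMotifs(prof, n, seed = 99)
  f <- frequencies(positionFrequencies(m)) / 100
  p <- frequencies(prof)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(f - p) <= 3 * se + 1e-12))
})

test_that("generated databases are deterministic and truth-consistent", {
  cfg <- syntheticConfig(nProteins = 60L, plantingRate = 0.5, seed = 7L)
  s1 <- generateDatabase(cfg)
  s2 <- generateDatabase(cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$annotations),
                   as.data.frame(s2$annotations))

  # on-disk artifacts byte-identical for equal seeds
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  dir.create(d1, recursive = TRUE); dir.create(d2, recursive = TRUE)
  for (d in c(d1, d2)) {
    sim <- generateDatabase(cfg)
    writeFasta(sim$sequences, file.path(d, "db.fasta"))
    writeAnnotations(sim$annotations, file.path(d, "ann.tsv"))
    writeTable(sim$truth, file.path(d, "truth.tsv"))
  }
  for (f in c("db.fasta", "ann.tsv", "truth.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  # every planted motif is literally a substring at its recorded position
  tr <- s1$truth
  seqs <- unname(as.character(s1$sequences))
  for (i in which(tr$planted)) {
    pos <- tr$insert_position[i]
    expect_identical(substr(seqs[i], pos, pos + nchar(tr$motif[i]) - 1L),
                     tr$motif[i])
  }
  expect_true(all(is.na(tr$motif[!tr$planted])))
})

test_that("planting rate boundaries behave as configured", {
  none <- generateDatabase(syntheticConfig(nProteins = 30L,
                                           plantingRate = 0, seed = 3L))
  expect_false(any(none$truth$planted))
  all50 <- generateDatabase(syntheticConfig(nProteins = 50L,
                                            plantingRate = 1, seed = 3L))
  expect_true(all(all50$truth$planted))
  lens <- nchar(as.character(all50$sequences))
  expect_true(all(all50$truth$insert_position >= 1 &
                  all50$truth$insert_position + 6 <= lens))
})

test_that("planted GO term frequency converges to the configured fold", {
  # pool 3 replicates; background prob 0.06 at fold 3 -> planted prob 0.18
  nP <- 0L; kP <- 0L; nO <- 0L; kO <- 0L
  for (r in 1:3) {
    cfg <- syntheticConfig(nProteins = 600L, plantingRate = 0.5,
                           goCatalog = defaultGoCatalog(plantedFold = 3),
                           seed = 40L + r)
    sim <- generateDatabase(cfg)
    long <- goLong(sim$annotations)
    planted <- sim$truth$accession[sim$truth$planted]
    others <- setdiff(sim$truth$accession, planted)
    has <- long$accession[long$term == "GO:0016491"]
    nP <- nP + length(planted); kP <- kP + sum(planted %in% has)
    nO <- nO + length(others); kO <- kO + sum(others %in% has)
  }
  pStudy <- kP / nP; pOther <- kO / nO
  expect_lt(abs(pStudy - 0.18), 3 * sqrt(0.18 * 0.82 / nP))
  expect_lt(abs(pOther - 0.06), 3 * sqrt(0.06 * 0.94 / nO))
})

test_that("end-to-end planted recovery reaches precision and recall 0.9", {
  prof <- benchmarkProfile("LDSYQCT")
  cfg <- syntheticConfig(nProteins = 200L, plantingRate = 0.5,
                         profile = prof, seed = 101L)
  sim <- generateDatabase(cfg)
  sc <- buildScoring()
  evd <- calibrateEvd("LDSYQCT", sc, lengths = 300L, nSamples = 300L,
                      seed = 102L)
  hits <- scanDatabase("LDSYQCT", sim$sequences, sc, evd)
  planted <- sim$truth$accession[sim$truth$planted]
  called <- hits$accession
  precision <- mean(called %in% planted)
  recall <- mean(planted %in% called)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})
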