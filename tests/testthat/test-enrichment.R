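test_that("term classification counts distinct genes, ranked", {
  ann <- makeAnnotations(list(
    g1 = c("T1", "T2"), g2 = "T1", g3 = c("T3", "T3"), g4 = character()))
  res <- classifyTerms(c("g1", "g2", "g3"), ann)
  expect_equal(res$term, c("T1", "T2", "T3"))
  expect_equal(res$count, c(2L, 1L, 1L))
  # gene annotated twice with one term counts once
  expect_equal(res$count[res$term == "T3"], 1L)
  # missing study genes are skipped with a message
  expect_message(classifyTerms(c("g1", "ghost"), ann), "missing")
  expect_error(classifyTerms(character(), ann), "empty")
})

test_that("hypergeometric p and fold enrichment match the worked example", {
  # N=20 background genes, K=5 with the term, study n=6 with k=4:
  # p = [C(5,4)C(15,2) + C(5,5)C(15,1)] / C(20,6) = 540/38760
  genes <- paste0("g", 1:20)
  terms <- c(rep(list("T1"), 5), rep(list(character()), 15))
  ann <- makeAnnotations(setNames(terms, genes))
  study <- c(genes[1:4], genes[6:7]) # 4 of 5 marked + 2 unmarked
  res <- enrichTerms(study, genes, ann)
  expect_equal(nrow(res), 1)
  expect_equal(res$k, 4L); expect_equal(res$K, 5L)
  expect_equal(res$n, 6L); expect_equal(res$N_bg, 20L)
  expect_equal(res$p_value, 540 / 38760)
  expect_equal(res$fold_enrichment, (4 / 6) / (5 / 20))
  # saturation: every study gene and every background gene carries it
  annAll <- makeAnnotations(setNames(rep(list("T1"), 20), genes))
  sat <- enrichTerms(genes, genes, annAll)
  expect_equal(sat$p_value, 1)
  expect_equal(sat$fold_enrichment, 1)
})

test_that("hypergeometric p equals subset-enumeration for N_bg <= 25", {
  set.seed(55)
  for (rep in 1:12) {
    N <- sample(8:25, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:min(6, N - 1), 1)
    genes <- paste0("g", seq_len(N))
    terms <- c(rep(list("T1"), K), rep(list(character()), N - K))
    ann <- makeAnnotations(setNames(terms, genes))
    # study of size n with a random number of marked genes (at least 1,
    # and enough unmarked genes left to fill the rest of the study)
    ks <- seq(max(1, n - (N - K)), min(n, K))
    kTrue <- if (length(ks) == 1) ks else sample(ks, 1)
    study <- c(genes[seq_len(kTrue)],
               if (n > kTrue) genes[K + seq_len(n - kTrue)])
    res <- enrichTerms(study, genes, ann)
    expect_equal(res$p_value, enumHyperTail(N, K, n, kTrue),
                 tolerance = 1e-12,
                 label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, kTrue))
  }
})

test_that("BH adjustment matches the closed form and its properties", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  set.seed(6)
  p <- runif(50)
  q <- bhFdr(p)
  expect_true(all(q >= p) && all(q <= 1))
  # permutation invariance
  perm <- sample(50)
  expect_equal(bhFdr(p[perm]), q[perm])
  # monotone along sorted p
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bhFdr(c(0.5, 1.2)), "p-values")
})

test_that("enrichment contract: subsets, k>=1 terms only, sorting", {
  ann <- makeAnnotations(list(g1 = "T1", g2 = "T2", g3 = character()))
  expect_error(enrichTerms("gX", c("g1", "g2", "g3"), ann), "subset")
  res <- enrichTerms("g1", annotations = ann)
  expect_equal(res$term, "T1") # T2 has k = 0: not tested
  expect_true(all(res$fdr >= res$p_value))
})

test_that("a term planted at fold 4 attains the smallest FDR", {
  cfg <- syntheticConfig(nProteins = 1000L, plantingRate = 0.05,
                         goCatalog = defaultGoCatalog(plantedFold = 4),
                         seed = 33L)
  sim <- generateDatabase(cfg)
  ann <- sim$annotations
  study <- ann@geneSymbol[match(sim$truth$accession[sim$truth$planted],
                                ann@accession)]
  res <- enrichTerms(study, annotations = ann)
  best <- res$term[which.min(res$fdr)]
  expect_equal(best, "GO:0016491")
  expect_equal(res$term[1], "GO:0016491") # also top fold enrichment
})

test_that("taxonomy profile counts unique genes per category", {
  hits <- data.frame(
    gene_symbol = c("a", "a", "b", "c", "d", "d"),
    taxon_category = c("bacteria", "bacteria", "bacteria", "archaea",
                       "human", "bacteria"),
    stringsAsFactors = FALSE)
  tp <- taxonProfile(hits)
  expect_setequal(tp$taxon_category, taxonCategories())
  expect_equal(tp$unique_genes[tp$taxon_category == "bacteria"], 3L)
  expect_equal(tp$unique_genes[tp$taxon_category == "archaea"], 1L)
  expect_equal(sum(tp$unique_genes), 5L) # gene d counts in two categories
  expect_equal(sum(tp$percent), 100)
  expect_equal(tp$percent[tp$taxon_category == "bacteria"], 60)
  expect_equal(tp$unique_genes[tp$taxon_category == "fungi"], 0L)

  one <- taxonProfile(data.frame(gene_symbol = "x",
                                 taxon_category = "viruses"))
  expect_equal(one$percent[one$taxon_category == "viruses"], 100)

  expect_error(taxonProfile(data.frame(gene_symbol = "x",
                                       taxon_category = "martian")),
               "unknown taxon")
})
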