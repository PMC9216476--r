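mkStore <- function(...) AnnotationStore(...)

test_that("statistical knowledge score distinguishes its four outcomes", {
  store <- mkStore(
    populationPresence = c(OLIin = TRUE, OLIout = FALSE, OLImiss = FALSE),
    clinicalRelevance = c(v1 = TRUE, v2 = TRUE, v3 = FALSE))
  expect_equal(scoreStatKnowledge("OLIin", c("v1", "v2"), store),
               list(value = 0L, reason = "present_in_population_panel"))
  expect_equal(scoreStatKnowledge("OLIout", c("v1", "v2"), store),
               list(value = 1L, reason = "assigned"))
  expect_equal(scoreStatKnowledge("OLImiss", c("v1", "v3"), store),
               list(value = 0L, reason = "clinical_relevance_missing"))
  # no panel entry, or a variant with no relevance entry
  expect_equal(scoreStatKnowledge("OLIunknown", c("v1", "v2"), store)$reason,
               "insufficient_information")
  expect_equal(scoreStatKnowledge("OLIout", c("v1", "vX"), store)$reason,
               "insufficient_information")
})

test_that("predictor call thresholds behave at their boundaries", {
  cfg <- scoringConfig()
  expect_true(isPathogenicCall("cadd", 15, cfg))     # inclusive bound
  expect_false(isPathogenicCall("cadd", 14.999, cfg))
  expect_true(isPathogenicCall("cadd", 15.001, cfg))
  expect_false(isPathogenicCall("cadd", NA_real_, cfg))
  expect_true(isPathogenicCall("sift", "deleterious", cfg))
  expect_false(isPathogenicCall("sift", "tolerated", cfg))
  expect_true(isPathogenicCall("mutation_taster", "disease_causing", cfg))
  expect_true(isPathogenicCall("polyphen", "possibly_damaging", cfg))
  expect_true(isPathogenicCall("polyphen", "probably_damaging", cfg))
  expect_false(isPathogenicCall("polyphen", "benign", cfg))
  expect_false(isPathogenicCall("polyphen", "absent", cfg))
  expect_error(isPathogenicCall("revel", 0.9, cfg), "unknown predictor")
})

test_that("gene knowledge score uses strict PPI bound, pathway sharing and completeness", {
  cfg <- scoringConfig()
  # qualifying edge -> connected pair -> 2
  s <- mkStore(ppiEdges = data.frame(geneA = "A", geneB = "B",
                                     confidence = 0.9))
  expect_equal(scoreGeneKnowledge(c("A", "B"), s, cfg), 2L)
  # confidence exactly at the threshold does not qualify; per-gene
  # relevant pathways keep the score at 1
  s <- mkStore(
    ppiEdges = data.frame(geneA = "A", geneB = "B", confidence = 0.8),
    pathways = data.frame(gene = c("A", "B"), pathwayId = c("p1", "p2"),
                          phenotypeRelevant = TRUE))
  expect_equal(scoreGeneKnowledge(c("A", "B"), s, cfg), 1L)
  # chain of qualifying edges connects a triplet
  s <- mkStore(ppiEdges = data.frame(geneA = c("A", "B"),
                                     geneB = c("B", "C"),
                                     confidence = c(0.85, 0.9)))
  expect_equal(scoreGeneKnowledge(c("A", "B", "C"), s, cfg), 2L)
  # a common phenotype-relevant pathway across all genes also gives 2
  s <- mkStore(pathways = data.frame(gene = c("A", "B", "C"),
                                     pathwayId = "shared",
                                     phenotypeRelevant = TRUE))
  expect_equal(scoreGeneKnowledge(c("A", "B", "C"), s, cfg), 2L)
  # known genes without relevant pathways or qualifying edges -> 0
  s <- mkStore(pathways = data.frame(gene = c("A", "B"),
                                     pathwayId = c("p1", "p2"),
                                     phenotypeRelevant = FALSE))
  expect_equal(scoreGeneKnowledge(c("A", "B"), s, cfg), 0L)
  # any gene absent from every table -> unassigned
  s <- mkStore(pathways = data.frame(gene = "A", pathwayId = "p1",
                                     phenotypeRelevant = TRUE))
  expect_true(is.na(scoreGeneKnowledge(c("A", "B"), s, cfg)))
  expect_error(scoreGeneKnowledge("A", s, cfg), "at least 2 genes")
})

test_that("high-confidence edges must connect ALL genes, not just some", {
  cfg <- scoringConfig()
  s <- connectivityStore(c("A", "B", "C"),
                         data.frame(geneA = "A", geneB = "B",
                                    confidence = 0.95))
  expect_equal(scoreGeneKnowledge(c("A", "B", "C"), s, cfg), 0L)
})

test_that("gene knowledge connectivity agrees with brute-force reachability on random graphs", {
  cfg <- scoringConfig()
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(2:6, 1L)
    genes <- paste0("G", seq_len(n))
    pairs <- t(combn(genes, 2L))
    keep <- runif(nrow(pairs)) < 0.4
    conf <- runif(nrow(pairs), 0.5, 1.0)
    edges <- data.frame(geneA = pairs[keep, 1], geneB = pairs[keep, 2],
                        confidence = conf[keep],
                        stringsAsFactors = FALSE)
    s <- connectivityStore(genes, edges)
    qualifying <- edges[edges$confidence > cfg@ppiThreshold, , drop = FALSE]
    expected <- if (oracleConnected(genes, qualifying$geneA,
                                    qualifying$geneB)) 2L else 0L
    expect_identical(scoreGeneKnowledge(genes, s, cfg), expected,
                     info = paste("rep", rep))
  }
})

test_that("variant knowledge score requires a pathogenic call everywhere and predictions for all", {
  cfg <- scoringConfig()
  pred <- data.frame(
    variantKey = c("v1", "v2", "v3", "v4"),
    caddPhred = c(20, 10, NA, NA),
    sift = c("absent", "tolerated", "absent", "absent"),
    mutationTaster = c("absent", "polymorphism", "absent", "absent"),
    polyphen = c("absent", "benign", "possibly_damaging", "absent"),
    stringsAsFactors = FALSE)
  s <- mkStore(predictions = pred)
  expect_equal(scoreVariantKnowledge(c("v1", "v3"), s, cfg), 1L)
  expect_equal(scoreVariantKnowledge(c("v1", "v2"), s, cfg), 0L)
  # v4 has a row but no value from any tool -> unassigned
  expect_true(is.na(scoreVariantKnowledge(c("v1", "v4"), s, cfg)))
  # missing row -> unassigned
  expect_true(is.na(scoreVariantKnowledge(c("v1", "v9"), s, cfg)))
})

test_that("knowledge scores respect their ceilings over generated stores", {
  set.seed(23)
  gen <- generateCorpus(generatorConfig(nCombinations = 40L, seed = 23L))
  store <- generateStore(gen$entries, gen$truth, seed = 24L)
  for (e in gen$entries) {
    k <- scoreKnowledge(e, store)
    expect_lte(k@stat, 1L)
    if (!is.na(k@gene)) expect_lte(k@gene, 2L)
    if (!is.na(k@var)) expect_lte(k@var, 1L)
  }
})

test_that("identical store and config give identical knowledge scores", {
  gen <- generateCorpus(generatorConfig(nCombinations = 10L, seed = 5L))
  store <- generateStore(gen$entries, gen$truth, seed = 6L)
  k1 <- lapply(gen$entries, scoreKnowledge, store = store)
  k2 <- lapply(gen$entries, scoreKnowledge, store = store)
  expect_equal(k1, k2)
})

test_that("the annotation store round-trips through its TSV directory form", {
  gen <- generateCorpus(generatorConfig(nCombinations = 15L, seed = 31L))
  store <- generateStore(gen$entries, gen$truth, seed = 32L)
  dir <- withr::local_tempdir()
  writeAnnotationStore(store, dir)
  back <- readAnnotationStore(dir)
  for (e in gen$entries)
    expect_equal(scoreKnowledge(e, back), scoreKnowledge(e, store))
})
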