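test_that("generator configs validate their probability tables", {
  expect_error(generatorConfig(famLevels = c("0" = 0.5, "1" = 0.4)),
               "sum to 1")
  expect_error(generatorConfig(statLevels = c("0" = 0.5, "3" = 0.5)),
               "unreachable")
  expect_error(generatorConfig(genesPerCombination = c("1" = 1)),
               "at least 2 genes")
  expect_s3_class(generatorConfig(), "generatorConfig")
})

test_that("level realizers invert the manual scoring rules for every level and branch", {
  set.seed(61)
  for (rep in 1:25) {
    for (lvl in 0:3)
      expect_identical(scoreFamilial(pedigreeForLevel(lvl)), lvl)
    for (lvl in 0:2)
      expect_identical(scoreStatistical(controlForLevel(lvl)), lvl)
    for (lvl in 0:3)
      expect_identical(scoreGeneManual(geneEvidenceForLevel(lvl)), lvl)
    for (lvl in 0:3)
      expect_identical(scoreVariantManual(variantEvidenceForLevel(lvl)), lvl)
  }
  # every explicit branch too
  for (form in 1:2) expect_identical(
    scoreFamilial(pedigreeForLevel(2L, form)), 2L)
  for (form in 1:3) expect_identical(
    scoreGeneManual(geneEvidenceForLevel(1L, form)), 1L)
  for (form in 1:4) expect_identical(
    scoreVariantManual(variantEvidenceForLevel(1L, form)), 1L)
})

test_that("generation is deterministic given the seed", {
  cfg <- generatorConfig(nCombinations = 20L, seed = 7L)
  g1 <- generateCorpus(cfg)
  g2 <- generateCorpus(cfg)
  expect_equal(g1$truth, g2$truth)
  p1 <- file.path(withr::local_tempdir(), "c1.json")
  p2 <- file.path(withr::local_tempdir(), "c2.json")
  writeCorpus(g1$records, g1$entries, p1)
  writeCorpus(g2$records, g2$entries, p2)
  expect_identical(readBin(p1, "raw", 5e6), readBin(p2, "raw", 5e6))
  s1 <- generateStore(g1$entries, g1$truth, seed = 8L)
  s2 <- generateStore(g2$entries, g2$truth, seed = 8L)
  expect_equal(s1, s2)
})

test_that("an all-zero target configuration yields an all-zero corpus", {
  cfg <- generatorConfig(
    nCombinations = 8L,
    famLevels = c("0" = 1), statLevels = c("0" = 1),
    geneLevels = c("0" = 1), varLevels = c("0" = 1),
    kstatOutcomes = c(insufficient_information = 1),
    kgeneLevels = c(unassigned = 1), kvarLevels = c(unassigned = 1),
    seed = 2L)
  gen <- generateCorpus(cfg)
  store <- generateStore(gen$entries, gen$truth, seed = 3L)
  scores <- scorePipeline(gen$records, gen$entries, store)
  for (s in scores) {
    v <- scoreVector(s)
    expect_true(all(v[c("fam", "stat", "gene", "var", "final_meta")] == 0L))
  }
})

test_that("the pipeline recovers every planted score exactly", {
  cfg <- generatorConfig(nCombinations = 200L, seed = 101L,
                         boundaryRate = 0.3)
  gen <- generateCorpus(cfg)
  store <- generateStore(gen$entries, gen$truth, seed = 102L,
                         boundaryRate = 0.3)
  got <- scoresTable(scorePipeline(gen$records, gen$entries, store))
  truth <- gen$truth
  got <- got[match(truth$combination_id, got$combination_id), ]
  for (col in c("fam", "stat", "gene", "var", "gene_harmonized",
                "fun_manual", "final_manual", "kstat", "kgene", "kvar",
                "stat_meta", "gene_meta", "var_meta", "fun_meta",
                "final_meta"))
    expect_identical(got[[col]], truth[[col]],
                     info = paste("column", col))
  expect_identical(got$kstat_reason, truth$kstat_outcome)
})

test_that("planted knowledge outcomes survive the store's TSV round-trip", {
  gen <- generateCorpus(generatorConfig(nCombinations = 30L, seed = 71L,
                                        boundaryRate = 1))
  store <- generateStore(gen$entries, gen$truth, seed = 72L,
                         boundaryRate = 1)
  dir <- withr::local_tempdir()
  writeAnnotationStore(store, dir)
  got <- scoresTable(scorePipeline(gen$records, gen$entries,
                                   readAnnotationStore(dir)))
  got <- got[match(gen$truth$combination_id, got$combination_id), ]
  expect_identical(got$kgene, gen$truth$kgene)
  expect_identical(got$kvar, gen$truth$kvar)
  expect_identical(got$kstat, gen$truth$kstat)
})

test_that("empirical level frequencies match the target distribution", {
  cfg <- generatorConfig(nCombinations = 5000L, seed = 113L)
  gen <- generateCorpus(cfg)
  for (pair in list(list("fam", cfg$famLevels),
                    list("stat", cfg$statLevels),
                    list("gene", cfg$geneLevels),
                    list("var", cfg$varLevels))) {
    counts <- table(factor(gen$truth[[pair[[1]]]],
                           levels = names(pair[[2]])))
    p <- suppressWarnings(
      stats::chisq.test(as.integer(counts), p = pair[[2]]))$p.value
    expect_gt(p, 1e-3)
  }
})
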