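test_that("both decision trees equal the hand-transcribed lookup tables on every input tuple", {
  cfg <- scoringConfig()
  for (g in 0:3)
    for (v in 0:3)
      expect_identical(funTree(g, v, cfg),
                       as.integer(FUN_TABLE_ORACLE[g + 1L, v + 1L]),
                       info = paste("fun", g, v))
  for (fam in 0:3)
    for (stat in 0:2)
      for (fun in 0:3)
        expect_identical(
          finalTree(fam, stat, fun, cfg),
          as.integer(FINAL_TABLE_ORACLE[max(fam, stat) + 1L, fun + 1L]),
          info = paste("final", fam, stat, fun))
})

test_that("decision trees are monotone non-decreasing in each argument", {
  cfg <- scoringConfig()
  for (g in 0:3)
    for (v in 0:3) {
      if (g < 3) expect_gte(funTree(g + 1L, v, cfg), funTree(g, v, cfg))
      if (v < 3) expect_gte(funTree(g, v + 1L, cfg), funTree(g, v, cfg))
    }
  for (fam in 0:3)
    for (stat in 0:2)
      for (fun in 0:3) {
        here <- finalTree(fam, stat, fun, cfg)
        if (fam < 3) expect_gte(finalTree(fam + 1L, stat, fun, cfg), here)
        if (stat < 2) expect_gte(finalTree(fam, stat + 1L, fun, cfg), here)
        if (fun < 3) expect_gte(finalTree(fam, stat, fun + 1L, cfg), here)
      }
})

test_that("trees reject out-of-range levels", {
  expect_error(funTree(4, 0), "0..3")
  expect_error(funTree(-1, 0), "0..3")
  expect_error(finalTree(0, 3, 0), "0..2")
  expect_error(finalTree(0, 0, 5), "0..3")
})

test_that("cross-article merge takes the per-evidence maximum", {
  set.seed(3)
  r1 <- recordFromLevels("OLIm", "a1", fam = 1L, var = 0L)
  r2 <- recordFromLevels("OLIm", "a2", fam = 2L, var = 1L)
  r3 <- recordFromLevels("OLIm", "a3", fam = 0L, var = 3L)
  merged <- mergeCrossArticle(list(r1, r2, r3))
  expect_equal(merged@fam, 2L)
  expect_equal(merged@var, 3L)
  single <- mergeCrossArticle(list(r1))
  expect_equal(c(single@fam, single@var), c(1L, 0L))
  expect_error(mergeCrossArticle(list()), "at least one")
  expect_error(mergeCrossArticle(list(r1, recordFromLevels("OTHER", "a"))),
               "multiple combinations")
})

test_that("merging obeys the max-semilattice laws", {
  set.seed(13)
  asVec <- function(m) c(m@fam, m@stat, m@gene, m@var)
  for (i in 1:20) {
    rs <- lapply(1:3, function(j)
      recordFromLevels("OLIs", paste0("a", j),
                       fam = sample(0:3, 1), stat = sample(0:2, 1),
                       gene = sample(0:3, 1), var = sample(0:3, 1)))
    # idempotent
    expect_equal(asVec(mergeCrossArticle(rs[c(1, 1)])),
                 asVec(mergeCrossArticle(rs[1])))
    # commutative
    expect_equal(asVec(mergeCrossArticle(rs[c(1, 2)])),
                 asVec(mergeCrossArticle(rs[c(2, 1)])))
    # associative: max over any grouping equals max over the flat list
    ab <- mergeCrossArticle(rs[c(1, 2)])
    abc1 <- pmax(asVec(ab), asVec(mergeCrossArticle(rs[3])))
    expect_equal(abc1, asVec(mergeCrossArticle(rs)))
  }
})

test_that("gene harmonization assigns the corpus-wide maximum per canonical gene set", {
  set.seed(17)
  e1 <- digenicEntry("OLIh1", c("ABC1", "XYZ2"))
  e2 <- digenicEntry("OLIh2", c("xyz2", "abc1"))  # same genes, other order
  r1 <- recordFromLevels("OLIh1", "a1", gene = 1L)
  r2 <- recordFromLevels("OLIh2", "a2", gene = 3L)
  h <- harmonizeGeneScores(list(r1, r2), list(e1, e2))
  expect_length(h, 1L)  # order-swapped symbols collapse to one key
  expect_equal(unname(h[canonicalGeneKey(c("ABC1", "XYZ2"))]), 3L)
  # a pair seen in a single article keeps its own score
  single <- harmonizeGeneScores(list(r1), list(e1))
  expect_equal(unname(single), 1L)
})

test_that("metascores take the manual/knowledge maximum with unassigned fallback and panel override", {
  cfg <- scoringConfig()
  # the population-panel override beats even a moderate manual score
  s <- computeMetascores(ManualScores(stat = 2L), 0L,
                         KnowledgeScores(0L, "present_in_population_panel"),
                         cfg)
  expect_equal(s@statMeta, 0L)
  # knowledge gene raises a weak harmonized score
  s <- computeMetascores(ManualScores(gene = 1L), 1L,
                         KnowledgeScores(0L, "clinical_relevance_missing",
                                         gene = 2L), cfg)
  expect_equal(s@geneMeta, 2L)
  # unassigned knowledge falls back to the manual value
  s <- computeMetascores(ManualScores(var = 1L), 0L,
                         KnowledgeScores(0L, "insufficient_information"),
                         cfg)
  expect_equal(s@varMeta, 1L)
  # knowledge statistical 1 raises an absent manual score
  s <- computeMetascores(ManualScores(), 0L,
                         KnowledgeScores(1L, "assigned"), cfg)
  expect_equal(s@statMeta, 1L)
})

test_that("metascores dominate manual scores except under the panel override", {
  cfg <- scoringConfig()
  set.seed(29)
  reasons <- c("assigned", "present_in_population_panel",
               "clinical_relevance_missing", "insufficient_information")
  for (i in 1:200) {
    manual <- ManualScores(sample(0:3, 1), sample(0:2, 1), sample(0:3, 1),
                           sample(0:3, 1))
    harmonized <- manual@gene + sample.int(4L - manual@gene, 1L) - 1L
    reason <- sample(reasons, 1)
    kn <- KnowledgeScores(
      stat = if (reason == "assigned") 1L else 0L, statReason = reason,
      gene = sample(c(NA_integer_, 0:2), 1),
      var = sample(c(NA_integer_, 0:1), 1))
    s <- computeMetascores(manual, harmonized, kn, cfg)
    expect_gte(s@geneMeta, harmonized)
    expect_gte(s@geneMeta, manual@gene)
    expect_gte(s@varMeta, manual@var)
    if (reason == "present_in_population_panel")
      expect_identical(s@statMeta, 0L)
    else
      expect_gte(s@statMeta, manual@stat)
  }
})

test_that("the pipeline scores an empty-evidence corpus to all zeros", {
  e <- digenicEntry("OLIz", c("AA1", "BB2"))
  r <- EvidenceRecord("OLIz", "a1")
  store <- AnnotationStore()
  s <- scorePipeline(list(r), list(e), store)[["OLIz"]]
  v <- scoreVector(s)
  expect_true(all(v[c("fam", "stat", "gene", "var", "fun_manual",
                      "final_manual", "stat_meta", "gene_meta", "var_meta",
                      "fun_meta", "final_meta")] == 0L))
})

test_that("the pipeline propagates cross-article gene maxima to sharing combinations", {
  set.seed(37)
  # two distinct combinations over the same gene pair, different articles
  mkEntry <- function(cid) CombinationEntry(
    cid, list(Variant(paste0(cid, "_v1"), "PAX1"),
              Variant(paste0(cid, "_v2"), "MYC2")),
    diseaseName = "shared-pair disease",
    references = data.frame(articleId = paste0(cid, "_a"), year = 2018L))
  eA <- mkEntry("OLIa"); eB <- mkEntry("OLIb")
  rA <- recordFromLevels("OLIa", "OLIa_a", gene = 1L)
  rB <- recordFromLevels("OLIb", "OLIb_a", gene = 3L)
  scores <- scorePipeline(list(rA, rB), list(eA, eB), AnnotationStore())
  expect_equal(scores$OLIa@geneManualHarmonized, 3L)
  expect_equal(scores$OLIa@manual@gene, 1L)  # own manual score untouched
  expect_equal(scores$OLIb@geneManualHarmonized, 3L)
})

test_that("the pipeline rejects invalid corpora", {
  oneGene <- CombinationEntry(
    "OLIbad", list(Variant("b_v1", "ONLY1"), Variant("b_v2", "only1")),
    references = data.frame(articleId = "x", year = 2000L))
  expect_error(scorePipeline(list(), list(oneGene)), "invalid entry")
  e <- digenicEntry("OLIok", c("A1", "B1"))
  stray <- EvidenceRecord("OLInotthere", "a")
  expect_error(scorePipeline(list(stray), list(e)), "without a matching")
})
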