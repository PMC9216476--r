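test_that("familial score follows the pedigree rule table", {
  # perfect segregation with healthy informative relatives at both degrees
  expect_equal(scoreFamilial(PedigreeEvidence(
    c("first", "first", "second"),
    c("affected", "healthy", "healthy"),
    c("full_carrier", "non_carrier", "non_carrier"))), 3L)
  # no relatives at all
  expect_equal(scoreFamilial(PedigreeEvidence()), 0L)
  # both degrees informative but segregation broken -> moderate
  expect_equal(scoreFamilial(PedigreeEvidence(
    c("first", "second"),
    c("affected", "affected"),
    c("full_carrier", "partial_carrier"))), 2L)
  # two first-degree relatives segregating perfectly -> moderate
  expect_equal(scoreFamilial(PedigreeEvidence(
    c("first", "first"),
    c("affected", "healthy"),
    c("full_carrier", "non_carrier"))), 2L)
  # exactly one healthy genotyped first-degree relative -> weak
  expect_equal(scoreFamilial(PedigreeEvidence(
    "first", "healthy", "non_carrier")), 1L)
  # imperfect segregation across two first-degree relatives -> weak
  expect_equal(scoreFamilial(PedigreeEvidence(
    c("first", "first"),
    c("affected", "affected"),
    c("full_carrier", "non_carrier"))), 1L)
  # a single affected genotyped relative alone is not scoreable
  expect_equal(scoreFamilial(PedigreeEvidence(
    "first", "affected", "full_carrier")), 0L)
  # uninformative relatives (unknowns) contribute nothing
  expect_equal(scoreFamilial(PedigreeEvidence(
    c("first", "second"),
    c("unknown", "healthy"),
    c("full_carrier", "unknown"))), 0L)
})

test_that("healthy partial carriers are consistent with oligogenic segregation, affected ones are not", {
  base <- PedigreeEvidence(
    c("first", "first", "second"),
    c("affected", "healthy", "healthy"),
    c("full_carrier", "non_carrier", "partial_carrier"))
  expect_equal(scoreFamilial(base), 3L)
  broken <- PedigreeEvidence(
    c("first", "first", "second"),
    c("affected", "healthy", "affected"),
    c("full_carrier", "non_carrier", "partial_carrier"))
  expect_equal(scoreFamilial(broken), 2L)
})

test_that("adding a consistent informative relative never lowers the familial score", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(0:5, 1L)
    p <- PedigreeEvidence(
      sample(c("first", "second"), n, replace = TRUE),
      sample(c("affected", "healthy", "unknown"), n, replace = TRUE),
      sample(c("full_carrier", "partial_carrier", "non_carrier", "unknown"),
             n, replace = TRUE))
    before <- scoreFamilial(p)
    extra <- if (runif(1) < 0.5)
      data.frame(degree = sample(c("first", "second"), 1L),
                 phenotype = "affected", genotype = "full_carrier")
    else
      data.frame(degree = sample(c("first", "second"), 1L),
                 phenotype = "healthy", genotype = "non_carrier")
    p2 <- new("PedigreeEvidence", relatives = rbind(p@relatives, extra))
    # the added relative is consistent, so perfection cannot be broken
    expect_gte(scoreFamilial(p2), before)
  }
})

test_that("statistical score matches the independent rule transcription over every state", {
  states <- enumerateControlStates()
  scores <- integer(nrow(states))
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    got <- scoreStatistical(controlFromState(st))
    expect_identical(got, oracleStatistical(
      st$source, st$explicit, st$sizeSufficient, st$ethnicityMatched,
      st$phenotypesKnown, st$combinationAbsent))
    scores[i] <- got
  }
  # the ceiling of article-level statistical evidence is moderate
  expect_equal(max(scores), 2L)
  # similar sequencing technology never changes the score
  expect_equal(scoreStatistical(ControlEvidence(
    "cohort", explicit = TRUE, sizeSufficient = TRUE,
    ethnicityMatched = TRUE, phenotypesKnown = TRUE,
    sequencingSimilar = FALSE, combinationAbsent = TRUE)), 2L)
})

test_that("shared-variant context never raises the statistical score on its own", {
  withContext <- ControlEvidence(
    "cohort", sizeSufficient = TRUE, ethnicityMatched = TRUE,
    phenotypesKnown = TRUE, combinationAbsent = FALSE,
    sharedVariantSupport = c("modifier_role", "dominant_role"))
  expect_equal(scoreStatistical(withContext), 0L)
})

test_that("gene functional score matches the independent rule transcription over the evidence space", {
  relPool <- c("same_pathway", "directly_interacting",
               "same_protein_complex", "relevant_pathways_for_phenotype",
               "affecting_same_tissue", "co_expression",
               "monogenic_experiments_only")
  relSubsets <- c(list(character(0)), as.list(relPool),
                  list(c("same_pathway", "affecting_same_tissue")),
                  list(c("relevant_pathways_for_phenotype",
                         "co_expression")))
  for (design in c("none", "single_units_only", "joint_only",
                   "single_and_joint"))
    for (outcome in c("none", "synergistic_or_additive", "effect_shown",
                      "promising_inconclusive", "negative"))
      for (rels in relSubsets)
        for (relevance in c(FALSE, TRUE)) {
          if (design == "none" && outcome != "none") next
          g <- GeneFunctionalEvidence(design, outcome, rels, relevance)
          expect_identical(scoreGeneManual(g),
                           oracleGeneManual(design, outcome, rels,
                                            relevance),
                           info = paste(design, outcome,
                                        paste(rels, collapse = "/"),
                                        relevance))
        }
})

test_that("variant functional score matches the independent rule transcription over the evidence space", {
  for (design in c("none", "single_units_only", "joint_only",
                   "single_and_joint"))
    for (outcome in c("none", "synergistic_or_additive", "effect_shown",
                      "promising_inconclusive", "negative"))
      for (allPred in c(FALSE, TRUE))
        for (mixed in c(FALSE, TRUE))
          for (insilico in c(FALSE, TRUE))
            for (negative in c(FALSE, TRUE)) {
              if (design == "none" && outcome != "none") next
              v <- VariantFunctionalEvidence(design, outcome, allPred,
                                             mixed, insilico, negative)
              expect_identical(
                scoreVariantManual(v),
                oracleVariantManual(design, outcome, allPred, mixed,
                                    insilico, negative))
            }
})

test_that("negative outcomes cap functional scores at weak", {
  g <- GeneFunctionalEvidence("joint_only", "negative",
                              relationshipTypes = "same_pathway",
                              phenotypeRelevanceShown = TRUE)
  expect_equal(scoreGeneManual(g), 1L)
  v <- VariantFunctionalEvidence(insilicoJointEffectClear = TRUE,
                                 negativeResultPresent = TRUE)
  expect_equal(scoreVariantManual(v), 1L)
})

test_that("upgrading the experiment design never lowers functional scores", {
  for (outcome in c("synergistic_or_additive", "effect_shown")) {
    gJoint <- scoreGeneManual(GeneFunctionalEvidence("joint_only", outcome))
    gBoth <- scoreGeneManual(GeneFunctionalEvidence("single_and_joint",
                                                    outcome))
    expect_gte(gBoth, gJoint)
    vJoint <- scoreVariantManual(
      VariantFunctionalEvidence("joint_only", outcome))
    vBoth <- scoreVariantManual(
      VariantFunctionalEvidence("single_and_joint", outcome))
    expect_gte(vBoth, vJoint)
  }
})

test_that("scoreManual is the component-wise application of the four scorers", {
  empty <- EvidenceRecord("OLIx", "a1")
  expect_equal(unname(c(scoreManual(empty)@fam, scoreManual(empty)@stat,
                        scoreManual(empty)@gene, scoreManual(empty)@var)),
               c(0L, 0L, 0L, 0L))
  set.seed(11)
  rec <- recordFromLevels("OLIy", "a1", fam = 2L, stat = 1L, gene = 3L,
                          var = 1L)
  s <- scoreManual(rec)
  expect_equal(c(s@fam, s@stat, s@gene, s@var), c(2L, 1L, 3L, 1L))
})
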