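test_that("validateEntry reports structural violations and accepts well-formed entries", {
  good <- digenicEntry("OLI1", c("GJB2", "GJB6"), disease = "hearing loss")
  expect_length(validateEntry(good), 0L)

  onegene <- CombinationEntry(
    "OLI2",
    list(Variant("v1", "GJB2"), Variant("v2", "gjb2")),
    references = data.frame(articleId = "a", year = 2000L))
  expect_match(validateEntry(onegene), "fewer than 2 distinct genes",
               all = FALSE)

  bad <- digenicEntry("OLI3", c("A1", "B1"))
  bad@variants[[1]]@variantClass <- "cnv"  # bypasses constructor check
  expect_match(validateEntry(bad), "cnvDetail", all = FALSE)
})

test_that("CNV variants require a coherent detail block", {
  v <- Variant("v1", "A1", variantClass = "cnv",
               cnvDetail = list(start = 100L, end = 5000L,
                                change = "deletion"))
  expect_s4_class(v, "Variant")
  expect_error(Variant("v2", "A1", variantClass = "cnv",
                       cnvDetail = list(start = 5000L, end = 100L,
                                        change = "deletion")),
               "end must be greater than start")
  expect_error(Variant("v3", "A1", variantClass = "cnv"), "cnvDetail")
})

test_that("normalizeSymbols maps symbols and diseases, passes unmapped through, and is idempotent", {
  e <- digenicEntry("OLI606", c("MKL2", "MYH7"), disease = "LVNC")
  gmap <- c(MKL2 = "MRTFB")
  dmap <- data.frame(raw = "LVNC", name = "Left ventricular noncompaction",
                     id = "ORPHA:54260")
  e1 <- normalizeSymbols(e, gmap, dmap)
  expect_setequal(geneSymbols(e1), c("MRTFB", "MYH7"))
  expect_equal(e1@variants[[1]]@rawSymbol, "MKL2")
  expect_equal(e1@diseaseName, "Left ventricular noncompaction")
  expect_equal(e1@diseaseId, "ORPHA:54260")
  report <- attr(e1, "normalizationReport")
  expect_true(is.na(report$mapped[report$raw == "MYH7"]))

  # idempotence: a second application changes nothing
  e2 <- normalizeSymbols(e1, gmap, dmap)
  expect_equal(geneSymbols(e2), geneSymbols(e1))
  expect_equal(e2@diseaseName, e1@diseaseName)

  # empty maps are the identity
  e0 <- normalizeSymbols(e)
  expect_equal(geneSymbols(e0), geneSymbols(e))
})

test_that("flagCoordinates tracks coordinate presence and preserves curator override", {
  withCoords <- Variant("v1", "A1", coordinates = list(
    genomeBuild = "GRCh38", chromosome = "7", start = 1200L, ref = "A",
    alt = "G"))
  expect_equal(flagCoordinates(withCoords)@coordinateFlag, "mapped")
  expect_equal(flagCoordinates(Variant("v2", "A1"))@coordinateFlag,
               "unmapped")
  override <- Variant("v3", "A1", coordinateFlag = "manual_review")
  expect_equal(flagCoordinates(override)@coordinateFlag, "manual_review")
})

test_that("reconcileCurations returns consensus for identical payloads and symmetric conflicts otherwise", {
  mk <- function(curator, nRelatives) EvidenceRecord(
    "OLI9", "art1", curatorId = curator,
    pedigree = PedigreeEvidence(rep("first", nRelatives),
                                rep("healthy", nRelatives),
                                rep("non_carrier", nRelatives)))
  same <- reconcileCurations(mk("c1", 2L), mk("c2", 2L))
  expect_s4_class(same$consensus, "EvidenceRecord")
  expect_length(same$conflicts, 0L)

  a <- mk("c1", 2L); b <- mk("c2", 3L)
  ab <- reconcileCurations(a, b)
  expect_null(ab$consensus)
  expect_true("pedigree.relatives" %in% ab$conflicts)
  expect_setequal(ab$conflicts, reconcileCurations(b, a)$conflicts)

  other <- EvidenceRecord("OLI10", "art1")
  expect_error(reconcileCurations(a, other), "non-comparable")
})

test_that("canonical gene keys are order- and case-independent", {
  expect_equal(canonicalGeneKey(c("b2", "A1")), canonicalGeneKey(c("A1", "B2")))
  e1 <- digenicEntry("OLIa", c("TPO", "TG"))
  e2 <- digenicEntry("OLIb", c("tg", "TPO"))
  expect_equal(geneCombinationId(e1), geneCombinationId(e2))
})

test_that("valid entries never make the scoring pipeline raise", {
  set.seed(41)
  for (i in 1:10) {
    gen <- generateCorpus(generatorConfig(nCombinations = 3L, seed = i))
    for (e in gen$entries) expect_length(validateEntry(e), 0L)
    expect_no_error(scorePipeline(gen$records, gen$entries))
  }
})
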