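#' @include aggregation.R
NULL

#' Packaged worked-example fixtures
#'
#' Three small fixtures spanning the main scoring situations, with their
#' annotation tables shipped as plain TSV under
#' `inst/extdata/worked_examples/`:
#'
#' * `OLI606` — a trigenic left-ventricular-noncompaction combination
#'   (MYH7, MRTFB — curated as MKL2 in its source article — and NKX2-5).
#'   Two affected sibs carry all three variants; healthy second-degree
#'   relatives carry single variants; the father's carrier status is
#'   ambiguous (the MYH7 variant is reported de novo), so segregation is
#'   supported but not complete: familial score 2. An in vivo mouse model
#'   shows reduced cardiac function only in the triple mutant versus
#'   double, single and wild-type animals: gene and variant functional
#'   scores 3, functional metascore 3, final metascore 3.
#' * `OLI474` — a trigenic congenital-hypothyroidism combination (DUOX2,
#'   TG, TPO) from a cohort study. Parental genotypes/phenotypes unclear
#'   (familial 0); implicit absence from a matched 100-control cohort
#'   (statistical 1); the genes share the thyroid-hormone-synthesis
#'   process without synergy experiments (gene level 2); all variants
#'   carry at least one pathogenic prediction but one was reported benign
#'   (variant level 1). Statistical metascore 1, functional metascore 2,
#'   final metascore 1.
#' * `OLI302` — a digenic combination with weak familial evidence (one
#'   healthy genotyped first-degree relative: familial 1), no article
#'   statistics but panel absence plus clinical relevance of both
#'   variants (statistical metascore 1), and single-plus-joint mutant
#'   experiments showing synergy (functional metascore 3). Gene symbols
#'   are synthetic placeholders (`G302A`, `G302B`) as the source
#'   identities are not part of the fixture.
#'
#' @return list with `records`, `entries` and `store`, ready for
#'   [scorePipeline()].
#' @examples
#' wx <- workedExamples()
#' scores <- scorePipeline(wx$records, wx$entries, wx$store)
#' scoreVector(scores$OLI606)[["final_meta"]]  # 3
#' @export
workedExamples <- function() {
  oli606 <- CombinationEntry(
    "OLI606",
    list(
      Variant("OLI606_v1", "MYH7", "c.842G>C", zygosity = "heterozygous"),
      Variant("OLI606_v2", "MRTFB", "c.715G>A", rawSymbol = "MKL2",
              zygosity = "heterozygous"),
      Variant("OLI606_v3", "NKX2-5", "c.73C>T", zygosity = "heterozygous")),
    diseaseName = "Left ventricular noncompaction",
    references = data.frame(articleId = "PMID_oli606", year = 2016L))
  rec606 <- EvidenceRecord(
    "OLI606", "PMID_oli606", 2016L,
    pedigree = PedigreeEvidence(
      degree = c("first", "first", "first", "second", "second"),
      phenotype = c("affected", "affected", "healthy", "healthy", "healthy"),
      genotype = c("full_carrier", "full_carrier", "unknown",
                   "partial_carrier", "partial_carrier")),
    geneFunctional = GeneFunctionalEvidence(
      "single_and_joint", "synergistic_or_additive",
      relationshipTypes = c("involved_in_same_disease",
                            "affecting_same_tissue"),
      phenotypeRelevanceShown = TRUE),
    variantFunctional = VariantFunctionalEvidence(
      "single_and_joint", "synergistic_or_additive"))

  oli474 <- CombinationEntry(
    "OLI474",
    list(
      Variant("OLI474_v1", "DUOX2", "c.2654G>T", zygosity = "heterozygous"),
      Variant("OLI474_v2", "TG", "c.274+2T>G", zygosity = "heterozygous"),
      Variant("OLI474_v3", "TPO", "c.1117G>T", zygosity = "heterozygous")),
    diseaseName = "Congenital hypothyroidism",
    references = data.frame(articleId = "PMID_oli474", year = 2016L))
  rec474 <- EvidenceRecord(
    "OLI474", "PMID_oli474", 2016L,
    pedigree = PedigreeEvidence(
      degree = c("first", "first"),
      phenotype = c("unknown", "unknown"),
      genotype = c("unknown", "unknown")),
    statistical = ControlEvidence(
      "cohort", explicit = FALSE, sizeSufficient = TRUE,
      ethnicityMatched = TRUE, phenotypesKnown = TRUE,
      combinationAbsent = TRUE),
    geneFunctional = GeneFunctionalEvidence(
      relationshipTypes = c("same_pathway",
                            "relevant_pathways_for_phenotype"),
      phenotypeRelevanceShown = TRUE),
    variantFunctional = VariantFunctionalEvidence(
      allPredictedPathogenic = TRUE, negativeResultPresent = TRUE))

  oli302 <- CombinationEntry(
    "OLI302",
    list(
      Variant("OLI302_v1", "G302A", "c.1001C>T", zygosity = "heterozygous"),
      Variant("OLI302_v2", "G302B", "c.352G>A", zygosity = "heterozygous")),
    diseaseName = "Synthetic digenic disorder",
    references = data.frame(articleId = "PMID_oli302", year = 2010L))
  rec302 <- EvidenceRecord(
    "OLI302", "PMID_oli302", 2010L,
    pedigree = PedigreeEvidence("first", "healthy", "non_carrier"),
    geneFunctional = GeneFunctionalEvidence(
      "single_and_joint", "synergistic_or_additive",
      relationshipTypes = "relevant_pathways_for_phenotype",
      phenotypeRelevanceShown = TRUE),
    variantFunctional = VariantFunctionalEvidence(
      "single_and_joint", "synergistic_or_additive"))

  storeDir <- system.file("extdata", "worked_examples",
                          package = "oligoscore")
  list(records = list(rec606, rec474, rec302),
       entries = list(oli606, oli474, oli302),
       store = readAnnotationStore(storeDir))
}
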