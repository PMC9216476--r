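#' @include AllClasses.R
NULL

#' Construct a Variant
#'
#' @param localId opaque variant key, unique within a corpus.
#' @param geneSymbol gene symbol (normalized form; see [normalizeSymbols()]).
#' @param notation free-text cDNA/protein description.
#' @param rawSymbol symbol as written in the source article (defaults to
#'   `geneSymbol`).
#' @param coordinates `NULL`, or a list with `genomeBuild`, `chromosome`,
#'   `start`, `ref`, `alt`.
#' @param variantClass `"snv"`, `"indel"` or `"cnv"`.
#' @param cnvDetail for CNVs, a list with `start`, `end`, `change`
#'   (1-based inclusive coordinates; `change` is `"deletion"` or
#'   `"duplication"`).
#' @param zygosity `"heterozygous"`, `"homozygous"`, `"hemizygous"` or
#'   `"unknown"`.
#' @param coordinateFlag defaults to `"mapped"` iff coordinates are given;
#'   pass `"manual_review"` to record a curator override.
#' @return a [Variant-class].
#' @examples
#' Variant("v1", "MYH7", "c.2770G>A", zygosity = "heterozygous")
#' @export
Variant <- function(localId, geneSymbol, notation = "", rawSymbol = geneSymbol,
                    coordinates = NULL, variantClass = "snv",
                    cnvDetail = NULL, zygosity = "unknown",
                    coordinateFlag = NULL) {
  if (is.null(coordinateFlag))
    coordinateFlag <- if (is.null(coordinates)) "unmapped" else "mapped"
  new("Variant", localId = as.character(localId),
      geneSymbol = as.character(geneSymbol),
      rawSymbol = as.character(rawSymbol), notation = as.character(notation),
      coordinates = if (is.null(coordinates)) list() else coordinates,
      variantClass = variantClass,
      cnvDetail = if (is.null(cnvDetail)) list() else cnvDetail,
      zygosity = zygosity, coordinateFlag = coordinateFlag)
}

#' Construct pedigree evidence
#'
#' @param degree,phenotype,genotype character vectors of equal length, one
#'   element per relative (see [PedigreeEvidence-class] for the allowed
#'   values). All empty = no pedigree information.
#' @return a [PedigreeEvidence-class].
#' @examples
#' PedigreeEvidence(degree = c("first", "second"),
#'                  phenotype = c("affected", "healthy"),
#'                  genotype = c("full_carrier", "non_carrier"))
#' @export
PedigreeEvidence <- function(degree = character(), phenotype = character(),
                             genotype = character()) {
  new("PedigreeEvidence", relatives = data.frame(
    degree = as.character(degree), phenotype = as.character(phenotype),
    genotype = as.character(genotype), stringsAsFactors = FALSE))
}

#' Construct control-cohort statistical evidence
#'
#' @param source `"none"`, `"public_db"` or `"cohort"`.
#' @param explicit,sizeSufficient,ethnicityMatched,phenotypesKnown,
#'   sequencingSimilar,combinationAbsent logical flags (see
#'   [ControlEvidence-class]).
#' @param sharedVariantSupport character subset of `"modifier_role"`,
#'   `"dominant_role"`, `"severity_modifier"`.
#' @return a [ControlEvidence-class].
#' @export
ControlEvidence <- function(source = "none", explicit = FALSE,
                            sizeSufficient = FALSE, ethnicityMatched = FALSE,
                            phenotypesKnown = FALSE, sequencingSimilar = FALSE,
                            combinationAbsent = FALSE,
                            sharedVariantSupport = character()) {
  new("ControlEvidence", source = source, explicit = explicit,
      sizeSufficient = sizeSufficient, ethnicityMatched = ethnicityMatched,
      phenotypesKnown = phenotypesKnown, sequencingSimilar = sequencingSimilar,
      combinationAbsent = combinationAbsent,
      sharedVariantSupport = sharedVariantSupport)
}

#' Construct gene-level functional evidence
#'
#' @param experimentDesign,experimentOutcome experiment descriptors (see
#'   [GeneFunctionalEvidence-class]).
#' @param relationshipTypes character subset of [relationshipTypes()].
#' @param phenotypeRelevanceShown logical.
#' @return a [GeneFunctionalEvidence-class].
#' @export
GeneFunctionalEvidence <- function(experimentDesign = "none",
                                   experimentOutcome = "none",
                                   relationshipTypes = character(),
                                   phenotypeRelevanceShown = FALSE) {
  new("GeneFunctionalEvidence", experimentDesign = experimentDesign,
      experimentOutcome = experimentOutcome,
      relationshipTypes = relationshipTypes,
      phenotypeRelevanceShown = phenotypeRelevanceShown)
}

#' Construct variant-level functional evidence
#'
#' @param experimentDesign,experimentOutcome experiment descriptors.
#' @param allPredictedPathogenic,mixedExperimentAndPrediction,
#'   insilicoJointEffectClear,negativeResultPresent logical flags (see
#'   [VariantFunctionalEvidence-class]).
#' @return a [VariantFunctionalEvidence-class].
#' @export
VariantFunctionalEvidence <- function(experimentDesign = "none",
                                      experimentOutcome = "none",
                                      allPredictedPathogenic = FALSE,
                                      mixedExperimentAndPrediction = FALSE,
                                      insilicoJointEffectClear = FALSE,
                                      negativeResultPresent = FALSE) {
  new("VariantFunctionalEvidence", experimentDesign = experimentDesign,
      experimentOutcome = experimentOutcome,
      allPredictedPathogenic = allPredictedPathogenic,
      mixedExperimentAndPrediction = mixedExperimentAndPrediction,
      insilicoJointEffectClear = insilicoJointEffectClear,
      negativeResultPresent = negativeResultPresent)
}

#' Construct an evidence record
#'
#' One curator's structured evidence for one combination from one article.
#'
#' @param combinationId combination accession.
#' @param articleId publication identifier.
#' @param articleYear publication year.
#' @param curatorId curator token.
#' @param pedigree a [PedigreeEvidence-class] (default: empty).
#' @param statistical a [ControlEvidence-class] (default: none).
#' @param geneFunctional a [GeneFunctionalEvidence-class] (default: none).
#' @param variantFunctional a [VariantFunctionalEvidence-class]
#'   (default: none).
#' @return an [EvidenceRecord-class].
#' @export
EvidenceRecord <- function(combinationId, articleId, articleYear = NA_integer_,
                           curatorId = "curator1",
                           pedigree = PedigreeEvidence(),
                           statistical = ControlEvidence(),
                           geneFunctional = GeneFunctionalEvidence(),
                           variantFunctional = VariantFunctionalEvidence()) {
  new("EvidenceRecord", combinationId = as.character(combinationId),
      articleId = as.character(articleId),
      articleYear = as.integer(articleYear),
      curatorId = as.character(curatorId), pedigree = pedigree,
      statistical = statistical, geneFunctional = geneFunctional,
      variantFunctional = variantFunctional)
}

#' Construct a combination entry
#'
#' @param combinationId combination accession.
#' @param variants list of [Variant-class] objects.
#' @param diseaseName disease name (normalized form).
#' @param diseaseId optional disease ontology identifier.
#' @param references data.frame with columns `articleId`, `year`.
#' @return a [CombinationEntry-class].
#' @export
CombinationEntry <- function(combinationId, variants, diseaseName = "",
                             diseaseId = NA_character_,
                             references = data.frame(
                               articleId = character(), year = integer())) {
  new("CombinationEntry", combinationId = as.character(combinationId),
      variants = variants, diseaseName = as.character(diseaseName),
      diseaseId = as.character(diseaseId), references = references)
}

#' Minimal digenic entry for examples and tests
#'
#' Builds a two-variant entry with one SNV per gene and a single reference.
#'
#' @param combinationId combination accession.
#' @param genes character vector of two (or more) gene symbols; one variant
#'   is created per gene with key `<combinationId>_v<i>`.
#' @param disease disease name.
#' @param articleId reference article identifier.
#' @param year reference year.
#' @return a [CombinationEntry-class].
#' @export
digenicEntry <- function(combinationId, genes, disease = "unspecified",
                         articleId = paste0(combinationId, "_ref"),
                         year = 2020L) {
  variants <- lapply(seq_along(genes), function(i)
    Variant(paste0(combinationId, "_v", i), genes[i],
            zygosity = "heterozygous"))
  CombinationEntry(combinationId, variants, diseaseName = disease,
                   references = data.frame(articleId = articleId,
                                           year = as.integer(year)))
}

#' Construct manual / knowledge score vectors
#'
#' Direct constructors used when scores are supplied rather than computed;
#' [scoreManual()] and [scoreKnowledge()] are the computing counterparts.
#'
#' @param fam,stat,gene,var integer levels (see [ManualScores-class]).
#' @return a [ManualScores-class].
#' @export
ManualScores <- function(fam = 0L, stat = 0L, gene = 0L, var = 0L) {
  new("ManualScores", fam = as.integer(fam), stat = as.integer(stat),
      gene = as.integer(gene), var = as.integer(var))
}

#' @rdname ManualScores
#' @param statReason reason code for the statistical knowledge score.
#' @return a [KnowledgeScores-class].
#' @export
KnowledgeScores <- function(stat = 0L, statReason = "insufficient_information",
                            gene = NA_integer_, var = NA_integer_) {
  new("KnowledgeScores", stat = as.integer(stat), statReason = statReason,
      gene = as.integer(gene), var = as.integer(var))
}

#' Construct an annotation store
#'
#' @param populationPresence named logical vector (names = combination ids):
#'   is the combination present in the reference population panel?
#' @param clinicalRelevance named logical vector (names = variant keys):
#'   does the variant have disease-relevant clinical citations?
#' @param ppiEdges data.frame `geneA`, `geneB`, `confidence` (in \[0, 1\]).
#' @param pathways data.frame `gene`, `pathwayId`, `phenotypeRelevant`.
#' @param predictions data.frame `variantKey`, `caddPhred`, `sift`,
#'   `mutationTaster`, `polyphen`.
#' @return an [AnnotationStore-class].
#' @seealso [readAnnotationStore()] / [writeAnnotationStore()] for the TSV
#'   representation.
#' @export
AnnotationStore <- function(populationPresence = logical(),
                            clinicalRelevance = logical(),
                            ppiEdges = data.frame(
                              geneA = character(), geneB = character(),
                              confidence = numeric()),
                            pathways = data.frame(
                              gene = character(), pathwayId = character(),
                              phenotypeRelevant = logical()),
                            predictions = data.frame(
                              variantKey = character(), caddPhred = numeric(),
                              sift = character(), mutationTaster = character(),
                              polyphen = character())) {
  new("AnnotationStore", populationPresence = populationPresence,
      clinicalRelevance = clinicalRelevance, ppiEdges = ppiEdges,
      pathways = pathways, predictions = predictions)
}
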