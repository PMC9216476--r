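# Controlled vocabularies used throughout the evidence model. Scores are
# integer levels 0-3: Absent (0), Weak (1), Moderate (2), Strong (3).

.VARIANT_CLASSES <- c("snv", "indel", "cnv")
.ZYGOSITIES <- c("heterozygous", "homozygous", "hemizygous", "unknown")
.COORD_FLAGS <- c("mapped", "unmapped", "manual_review")
.CNV_CHANGES <- c("deletion", "duplication")

.DEGREES <- c("first", "second")
.PHENOTYPES <- c("affected", "healthy", "unknown")
.GENOTYPES <- c("full_carrier", "partial_carrier", "non_carrier", "unknown")

.STAT_SOURCES <- c("none", "public_db", "cohort")
.SHARED_SUPPORT <- c("modifier_role", "dominant_role", "severity_modifier")

.EXP_DESIGNS <- c("none", "single_units_only", "joint_only", "single_and_joint")
.EXP_OUTCOMES <- c("none", "synergistic_or_additive", "effect_shown",
                   "promising_inconclusive", "negative")

# The ten recognised gene-relationship categories, plus the marker that the
# article only reports monogenic (single-gene) experiments.
.RELATIONSHIP_TYPES <- c(
  "involved_in_same_disease", "relevant_pathways_for_phenotype",
  "same_pathway", "affecting_same_tissue", "directly_interacting",
  "same_protein_complex", "indirectly_interacting", "similar_function",
  "co_localization_or_same_organelle", "co_expression",
  "monogenic_experiments_only")

.STATK_REASONS <- c("assigned", "present_in_population_panel",
                    "clinical_relevance_missing", "insufficient_information")

.PREDICTOR_TOOLS <- c("cadd", "sift", "mutation_taster", "polyphen")
.SIFT_CALLS <- c("deleterious", "tolerated", "absent")
.MT_CALLS <- c("disease_causing", "polymorphism", "absent")
.POLYPHEN_CALLS <- c("probably_damaging", "possibly_damaging", "benign",
                     "absent")

.checkEnum <- function(x, what, allowed, len1 = TRUE) {
  if (len1 && length(x) != 1L)
    return(sprintf("%s must have length 1", what))
  if (anyNA(x) || !all(x %in% allowed))
    return(sprintf("%s must be one of: %s", what,
                   paste(allowed, collapse = ", ")))
  NULL
}

.checkFlag <- function(x, what) {
  if (length(x) != 1L || is.na(x))
    return(sprintf("%s must be TRUE or FALSE", what))
  NULL
}

#' Variant in an oligogenic combination
#'
#' One variant as curated from a publication: gene assignment, the free-text
#' cDNA/protein notation used by the source article, optional genomic
#' coordinates, and for copy-number variants an explicit
#' (start, end, deletion/duplication) description with 1-based inclusive
#' coordinates.
#'
#' @slot localId opaque variant key, unique within a corpus; used to join
#'   annotation tables.
#' @slot geneSymbol normalized gene symbol.
#' @slot rawSymbol symbol as written in the source article.
#' @slot notation free-text variant description.
#' @slot coordinates empty list, or a list with elements `genomeBuild`,
#'   `chromosome`, `start` (integer >= 1), `ref`, `alt`.
#' @slot variantClass one of `"snv"`, `"indel"`, `"cnv"`.
#' @slot cnvDetail empty list, or (for CNVs only) a list with `start`, `end`
#'   (`end > start`) and `change` (`"deletion"` or `"duplication"`).
#' @slot zygosity one of `"heterozygous"`, `"homozygous"`, `"hemizygous"`,
#'   `"unknown"`.
#' @slot coordinateFlag `"mapped"` iff coordinates are present, `"unmapped"`
#'   otherwise; `"manual_review"` is reserved for curator override.
#' @seealso [Variant()] for the user-facing constructor.
#' @export
setClass("Variant", representation(
  localId = "character",
  geneSymbol = "character",
  rawSymbol = "character",
  notation = "character",
  coordinates = "list",
  variantClass = "character",
  cnvDetail = "list",
  zygosity = "character",
  coordinateFlag = "character"))

setValidity("Variant", function(object) {
  msgs <- c(
    .checkEnum(object@variantClass, "variantClass", .VARIANT_CLASSES),
    .checkEnum(object@zygosity, "zygosity", .ZYGOSITIES),
    .checkEnum(object@coordinateFlag, "coordinateFlag", .COORD_FLAGS))
  if (object@variantClass == "cnv" && length(object@cnvDetail) == 0L)
    msgs <- c(msgs, "cnvDetail is required when variantClass is 'cnv'")
  if (object@variantClass != "cnv" && length(object@cnvDetail) > 0L)
    msgs <- c(msgs, "cnvDetail is only allowed when variantClass is 'cnv'")
  if (length(object@cnvDetail) > 0L) {
    d <- object@cnvDetail
    if (!all(c("start", "end", "change") %in% names(d)))
      msgs <- c(msgs, "cnvDetail needs elements start, end, change")
    else {
      if (!(is.numeric(d$start) && is.numeric(d$end) && d$end > d$start))
        msgs <- c(msgs, "cnvDetail: end must be greater than start")
      msgs <- c(msgs, .checkEnum(d$change, "cnvDetail$change", .CNV_CHANGES))
    }
  }
  if (length(object@coordinates) > 0L) {
    co <- object@coordinates
    need <- c("genomeBuild", "chromosome", "start", "ref", "alt")
    if (!all(need %in% names(co)))
      msgs <- c(msgs, sprintf("coordinates needs elements: %s",
                              paste(need, collapse = ", ")))
    else if (!(is.numeric(co$start) && co$start >= 1))
      msgs <- c(msgs, "coordinates$start must be an integer >= 1")
  }
  # unmapped <=> coordinates absent (manual_review is a curator override)
  if (object@coordinateFlag == "mapped" && length(object@coordinates) == 0L)
    msgs <- c(msgs, "coordinateFlag 'mapped' requires coordinates")
  if (object@coordinateFlag == "unmapped" && length(object@coordinates) > 0L)
    msgs <- c(msgs, "coordinateFlag 'unmapped' forbids coordinates")
  if (length(msgs)) msgs else TRUE
})

#' Pedigree segregation evidence
#'
#' Genotype/phenotype observations on the proband's relatives, used to grade
#' familial evidence. A relative is *informative* iff both phenotype and
#' genotype are known. Segregation is *perfect* iff every informative full
#' carrier of the combination is affected and every informative non-carrier
#' or partial carrier is healthy (a healthy partial carrier is consistent
#' with the oligogenic model and does not break perfection; an affected one
#' does).
#'
#' @slot relatives data.frame with character columns `degree`
#'   (`"first"`/`"second"`), `phenotype` (`"affected"`/`"healthy"`/`"unknown"`)
#'   and `genotype` (`"full_carrier"`/`"partial_carrier"`/`"non_carrier"`/
#'   `"unknown"`), one row per relative.
#' @export
setClass("PedigreeEvidence", representation(relatives = "data.frame"))

setValidity("PedigreeEvidence", function(object) {
  rel <- object@relatives
  if (!all(c("degree", "phenotype", "genotype") %in% names(rel)))
    return("relatives needs columns degree, phenotype, genotype")
  msgs <- c(
    .checkEnum(rel$degree, "degree", .DEGREES, len1 = FALSE),
    .checkEnum(rel$phenotype, "phenotype", .PHENOTYPES, len1 = FALSE),
    .checkEnum(rel$genotype, "genotype", .GENOTYPES, len1 = FALSE))
  if (length(msgs)) msgs else TRUE
})

#' Control-cohort / database statistical evidence
#'
#' Article-level statistical evidence that the variant combination does not
#' occur by chance in affected individuals: absence of the combination from
#' a control cohort or public database, together with quality descriptors of
#' that control set. `sharedVariantSupport` records admissible context from
#' variants shared with other combinations (modifier role, dominant role,
#' severity modifier); it never raises the score on its own.
#'
#' @slot source `"none"`, `"public_db"` or `"cohort"`.
#' @slot explicit absence of the combination was explicitly checked (TRUE)
#'   rather than implied (FALSE).
#' @slot sizeSufficient,ethnicityMatched,phenotypesKnown curator-judged
#'   quality flags for the control set.
#' @slot sequencingSimilar similar sequencing technology was used
#'   (recorded for reporting; does not gate the score).
#' @slot combinationAbsent the combination was absent from the controls.
#' @slot sharedVariantSupport character subset of `"modifier_role"`,
#'   `"dominant_role"`, `"severity_modifier"`.
#' @export
setClass("ControlEvidence", representation(
  source = "character",
  explicit = "logical",
  sizeSufficient = "logical",
  ethnicityMatched = "logical",
  phenotypesKnown = "logical",
  sequencingSimilar = "logical",
  combinationAbsent = "logical",
  sharedVariantSupport = "character"))

setValidity("ControlEvidence", function(object) {
  msgs <- c(
    .checkEnum(object@source, "source", .STAT_SOURCES),
    .checkFlag(object@explicit, "explicit"),
    .checkFlag(object@sizeSufficient, "sizeSufficient"),
    .checkFlag(object@ethnicityMatched, "ethnicityMatched"),
    .checkFlag(object@phenotypesKnown, "phenotypesKnown"),
    .checkFlag(object@sequencingSimilar, "sequencingSimilar"),
    .checkFlag(object@combinationAbsent, "combinationAbsent"))
  if (!all(object@sharedVariantSupport %in% .SHARED_SUPPORT))
    msgs <- c(msgs, sprintf("sharedVariantSupport must be a subset of: %s",
                            paste(.SHARED_SUPPORT, collapse = ", ")))
  if (is.null(msgs) && object@source == "none") {
    flags <- c(object@explicit, object@sizeSufficient,
               object@ethnicityMatched, object@phenotypesKnown,
               object@sequencingSimilar, object@combinationAbsent)
    if (any(flags) || length(object@sharedVariantSupport) > 0L)
      msgs <- c(msgs, paste("source 'none' requires all flags FALSE and",
                            "empty sharedVariantSupport"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene-level functional evidence from the article
#'
#' @slot experimentDesign `"none"`, `"single_units_only"` (only single-gene
#'   knockouts), `"joint_only"` (only a joint knockout) or
#'   `"single_and_joint"`.
#' @slot experimentOutcome `"none"`, `"synergistic_or_additive"`,
#'   `"effect_shown"`, `"promising_inconclusive"` or `"negative"`.
#' @slot relationshipTypes character subset of the ten gene-relationship
#'   categories (see [relationshipTypes()]).
#' @slot phenotypeRelevanceShown the reported relationship/pathway is shown
#'   relevant for the studied phenotype.
#' @export
setClass("GeneFunctionalEvidence", representation(
  experimentDesign = "character",
  experimentOutcome = "character",
  relationshipTypes = "character",
  phenotypeRelevanceShown = "logical"))

setValidity("GeneFunctionalEvidence", function(object) {
  msgs <- c(
    .checkEnum(object@experimentDesign, "experimentDesign", .EXP_DESIGNS),
    .checkEnum(object@experimentOutcome, "experimentOutcome", .EXP_OUTCOMES),
    .checkFlag(object@phenotypeRelevanceShown, "phenotypeRelevanceShown"))
  if (!all(object@relationshipTypes %in% .RELATIONSHIP_TYPES))
    msgs <- c(msgs, "relationshipTypes contains unknown categories")
  if (is.null(msgs) && object@experimentDesign == "none" &&
      object@experimentOutcome != "none")
    msgs <- c(msgs, "experimentOutcome must be 'none' when no experiment")
  if (length(msgs)) msgs else TRUE
})

#' Variant-level functional evidence from the article
#'
#' @slot experimentDesign,experimentOutcome as in
#'   [GeneFunctionalEvidence-class], for single/joint variant mutants.
#' @slot allPredictedPathogenic all variants of the combination predicted
#'   pathogenic in the article.
#' @slot mixedExperimentAndPrediction functional experiments for some
#'   variants, pathogenic predictions for the rest.
#' @slot insilicoJointEffectClear clear pathogenic joint effect in an in
#'   silico analysis.
#' @slot negativeResultPresent a negative functional result was reported
#'   (caps the score at Weak).
#' @export
setClass("VariantFunctionalEvidence", representation(
  experimentDesign = "character",
  experimentOutcome = "character",
  allPredictedPathogenic = "logical",
  mixedExperimentAndPrediction = "logical",
  insilicoJointEffectClear = "logical",
  negativeResultPresent = "logical"))

setValidity("VariantFunctionalEvidence", function(object) {
  msgs <- c(
    .checkEnum(object@experimentDesign, "experimentDesign", .EXP_DESIGNS),
    .checkEnum(object@experimentOutcome, "experimentOutcome", .EXP_OUTCOMES),
    .checkFlag(object@allPredictedPathogenic, "allPredictedPathogenic"),
    .checkFlag(object@mixedExperimentAndPrediction,
               "mixedExperimentAndPrediction"),
    .checkFlag(object@insilicoJointEffectClear, "insilicoJointEffectClear"),
    .checkFlag(object@negativeResultPresent, "negativeResultPresent"))
  if (is.null(msgs) && object@experimentDesign == "none" &&
      object@experimentOutcome != "none")
    msgs <- c(msgs, "experimentOutcome must be 'none' when no experiment")
  if (length(msgs)) msgs else TRUE
})

#' One curator's structured evidence for one combination from one article
#'
#' @slot combinationId opaque combination accession (style `"OLI"` + integer
#'   or similar).
#' @slot articleId opaque publication identifier.
#' @slot articleYear publication year.
#' @slot curatorId curator token; two independent curations of the same
#'   (combination, article) pair are reconciled with [reconcileCurations()].
#' @slot pedigree a [PedigreeEvidence-class].
#' @slot statistical a [ControlEvidence-class].
#' @slot geneFunctional a [GeneFunctionalEvidence-class].
#' @slot variantFunctional a [VariantFunctionalEvidence-class].
#' @export
setClass("EvidenceRecord", representation(
  combinationId = "character",
  articleId = "character",
  articleYear = "integer",
  curatorId = "character",
  pedigree = "PedigreeEvidence",
  statistical = "ControlEvidence",
  geneFunctional = "GeneFunctionalEvidence",
  variantFunctional = "VariantFunctionalEvidence"))

setValidity("EvidenceRecord", function(object) {
  msgs <- NULL
  for (s in c("combinationId", "articleId", "curatorId"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)) ||
        !nzchar(slot(object, s)))
      msgs <- c(msgs, sprintf("%s must be a non-empty string", s))
  if (length(msgs)) msgs else TRUE
})

#' Database-facing entry for one oligogenic variant combination
#'
#' Links the combination to its variants, derived gene set, disease and
#' source references. A combination is identified by its exact multiset of
#' variants; combinations sharing variants are distinct entities. The
#' canonical gene-combination key (case-normalized, lexicographically sorted
#' symbol tuple) drives corpus-level harmonization.
#'
#' @slot combinationId opaque combination accession.
#' @slot variants list of [Variant-class] objects covering at least two
#'   distinct gene symbols.
#' @slot diseaseName normalized disease name.
#' @slot diseaseId optional disease ontology identifier (`NA` if unknown).
#' @slot references data.frame with columns `articleId` (character, unique)
#'   and `year` (integer).
#' @export
setClass("CombinationEntry", representation(
  combinationId = "character",
  variants = "list",
  diseaseName = "character",
  diseaseId = "character",
  references = "data.frame"))

setValidity("CombinationEntry", function(object) {
  msgs <- NULL
  if (length(object@combinationId) != 1L || !nzchar(object@combinationId))
    msgs <- c(msgs, "combinationId must be a non-empty string")
  if (!all(vapply(object@variants, is, logical(1), "Variant")))
    msgs <- c(msgs, "variants must all be Variant objects")
  if (!all(c("articleId", "year") %in% names(object@references)))
    msgs <- c(msgs, "references needs columns articleId, year")
  else if (anyDuplicated(object@references$articleId))
    msgs <- c(msgs, "references: articleId must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Manual score vector for one combination
#'
#' Integer evidence levels judged solely from the source article(s):
#' familial (`fam`, 0-3), statistical (`stat`, 0-2; 2 is the ceiling for
#' this evidence class because the environmental background of cohort
#' controls cannot be controlled as in pedigrees), gene-level functional
#' (`gene`, 0-3) and variant-level functional (`var`, 0-3).
#'
#' @export
setClass("ManualScores", representation(
  fam = "integer", stat = "integer", gene = "integer", var = "integer"))

setValidity("ManualScores", function(object) {
  msgs <- NULL
  rng <- list(fam = 3L, stat = 2L, gene = 3L, var = 3L)
  for (s in names(rng)) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0L || v > rng[[s]])
      msgs <- c(msgs, sprintf("%s must be an integer in 0..%d", s, rng[[s]]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Knowledge score vector for one combination
#'
#' Scores computed from local annotation tables. `stat` (0-1) always carries
#' a reason code; `gene` (0-2) and `var` (0-1) are `NA` when *unassigned*,
#' i.e. when some unit of the combination has no entry in the relevant
#' tables. Unassigned is distinct from 0: metascores fall back to the manual
#' score when a knowledge score is unassigned, while a knowledge statistical
#' 0 with reason `"present_in_population_panel"` overrides the manual score.
#'
#' @slot stat integer 0 or 1.
#' @slot statReason one of `"assigned"`, `"present_in_population_panel"`,
#'   `"clinical_relevance_missing"`, `"insufficient_information"`.
#' @slot gene integer 0-2, or `NA` (unassigned).
#' @slot var integer 0-1, or `NA` (unassigned).
#' @export
setClass("KnowledgeScores", representation(
  stat = "integer", statReason = "character",
  gene = "integer", var = "integer"))

setValidity("KnowledgeScores", function(object) {
  msgs <- .checkEnum(object@statReason, "statReason", .STATK_REASONS)
  if (length(object@stat) != 1L || is.na(object@stat) ||
      object@stat < 0L || object@stat > 1L)
    msgs <- c(msgs, "stat must be 0 or 1")
  if (length(object@gene) != 1L ||
      (!is.na(object@gene) && (object@gene < 0L || object@gene > 2L)))
    msgs <- c(msgs, "gene must be NA (unassigned) or in 0..2")
  if (length(object@var) != 1L ||
      (!is.na(object@var) && (object@var < 0L || object@var > 1L)))
    msgs <- c(msgs, "var must be NA (unassigned) or in 0..1")
  if (length(msgs)) msgs else TRUE
})

#' Full score vector for one combination
#'
#' Holds the article-merged manual scores, the corpus-harmonized gene score,
#' the knowledge scores, and the derived tree aggregates and metascores.
#' Metascores are per-evidence maxima of manual and knowledge scores, with
#' one override: presence of the combination in the reference population
#' panel forces `statMeta` to 0 regardless of the manual score.
#'
#' @slot manual a [ManualScores-class] (cross-article maxima).
#' @slot knowledge a [KnowledgeScores-class].
#' @slot geneManualHarmonized max gene manual score over all articles
#'   mentioning this gene combination anywhere in the corpus.
#' @slot funManual,finalManual tree aggregates from manual components (with
#'   the harmonized gene score).
#' @slot statMeta,geneMeta,varMeta per-evidence metascores.
#' @slot funMeta,finalMeta tree aggregates from metascores.
#' @export
setClass("ScoreSet", representation(
  manual = "ManualScores",
  knowledge = "KnowledgeScores",
  geneManualHarmonized = "integer",
  funManual = "integer",
  finalManual = "integer",
  statMeta = "integer",
  geneMeta = "integer",
  varMeta = "integer",
  funMeta = "integer",
  finalMeta = "integer"))

setValidity("ScoreSet", function(object) {
  msgs <- NULL
  lims <- list(geneManualHarmonized = 3L, funManual = 3L, finalManual = 3L,
               statMeta = 2L, geneMeta = 3L, varMeta = 3L, funMeta = 3L,
               finalMeta = 3L)
  for (s in names(lims)) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0L || v > lims[[s]])
      msgs <- c(msgs, sprintf("%s must be an integer in 0..%d", s, lims[[s]]))
  }
  if (is.null(msgs)) {
    if (object@geneManualHarmonized < object@manual@gene)
      msgs <- c(msgs, "geneManualHarmonized must be >= manual gene score")
    if (object@geneMeta < object@geneManualHarmonized)
      msgs <- c(msgs, "geneMeta must be >= geneManualHarmonized")
    if (object@varMeta < object@manual@var)
      msgs <- c(msgs, "varMeta must be >= manual var score")
    override <- object@knowledge@statReason == "present_in_population_panel"
    if (override && object@statMeta != 0L)
      msgs <- c(msgs, "population-panel override requires statMeta = 0")
    if (!override && object@statMeta < object@manual@stat)
      msgs <- c(msgs, "statMeta must be >= manual stat score")
  }
  if (length(msgs)) msgs else TRUE
})

#' Local annotation store
#'
#' Lookup tables emulating the external resources consulted for knowledge
#' scores: reference population-panel membership per combination, clinical
#' relevance per variant, protein-protein interaction edges with confidence
#' in \[0, 1\], pathway memberships with a curated phenotype-relevance flag,
#' and per-variant pathogenicity predictor calls. Lookups are total: a key
#' missing from a table is an explicit "no entry" state, which propagates to
#' knowledge scores as unassigned/insufficient information.
#'
#' @slot populationPresence named logical vector, names = combination ids.
#' @slot clinicalRelevance named logical vector, names = variant keys.
#' @slot ppiEdges data.frame with columns `geneA`, `geneB`, `confidence`.
#' @slot pathways data.frame with columns `gene`, `pathwayId`,
#'   `phenotypeRelevant`.
#' @slot predictions data.frame with columns `variantKey`, `caddPhred`
#'   (numeric, `NA` = absent), `sift`, `mutationTaster`, `polyphen`
#'   (character calls, `"absent"` allowed).
#' @export
setClass("AnnotationStore", representation(
  populationPresence = "logical",
  clinicalRelevance = "logical",
  ppiEdges = "data.frame",
  pathways = "data.frame",
  predictions = "data.frame"))

setValidity("AnnotationStore", function(object) {
  msgs <- NULL
  if (length(object@populationPresence) &&
      is.null(names(object@populationPresence)))
    msgs <- c(msgs, "populationPresence must be named by combination id")
  if (length(object@clinicalRelevance) &&
      is.null(names(object@clinicalRelevance)))
    msgs <- c(msgs, "clinicalRelevance must be named by variant key")
  if (!all(c("geneA", "geneB", "confidence") %in% names(object@ppiEdges)))
    msgs <- c(msgs, "ppiEdges needs columns geneA, geneB, confidence")
  else if (nrow(object@ppiEdges) &&
           (any(object@ppiEdges$confidence < 0) ||
            any(object@ppiEdges$confidence > 1)))
    msgs <- c(msgs, "ppiEdges confidence must lie in [0, 1]")
  if (!all(c("gene", "pathwayId", "phenotypeRelevant") %in%
           names(object@pathways)))
    msgs <- c(msgs, "pathways needs columns gene, pathwayId, phenotypeRelevant")
  need <- c("variantKey", "caddPhred", "sift", "mutationTaster", "polyphen")
  if (!all(need %in% names(object@predictions)))
    msgs <- c(msgs, sprintf("predictions needs columns: %s",
                            paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Scoring configuration
#'
#' Thresholds for the knowledge scores and the two decision trees, stored as
#' flat lookup tables so they can be audited (see [writeTreeTables()]) or
#' replaced wholesale.
#'
#' @slot ppiThreshold interaction-confidence threshold; an edge qualifies
#'   when its confidence is *strictly greater* (default 0.8).
#' @slot caddThreshold CADD Phred threshold; a call is pathogenic when the
#'   value is greater *or equal* (default 15).
#' @slot polyphenAccept PolyPhen-2 categories accepted as deleterious
#'   (default `"probably_damaging"` and `"possibly_damaging"`).
#' @slot funTable 16-row lookup (gene 0-3 x var 0-3 -> fun).
#' @slot finalTable 16-row lookup (genetic 0-3 x fun 0-3 -> final), where
#'   genetic = max(familial, statistical).
#' @export
setClass("ScoringConfig", representation(
  ppiThreshold = "numeric",
  caddThreshold = "numeric",
  polyphenAccept = "character",
  funTable = "data.frame",
  finalTable = "data.frame"))

setValidity("ScoringConfig", function(object) {
  msgs <- NULL
  if (length(object@ppiThreshold) != 1L || object@ppiThreshold <= 0)
    msgs <- c(msgs, "ppiThreshold must be a single positive number")
  if (length(object@caddThreshold) != 1L || object@caddThreshold <= 0)
    msgs <- c(msgs, "caddThreshold must be a single positive number")
  if (!all(object@polyphenAccept %in% setdiff(.POLYPHEN_CALLS, "absent")))
    msgs <- c(msgs, "polyphenAccept must be PolyPhen-2 categories")
  if (!identical(dim(object@funTable), c(16L, 3L)) ||
      !all(c("gene", "var", "fun") %in% names(object@funTable)))
    msgs <- c(msgs, "funTable must be a 16-row (gene, var, fun) lookup")
  if (!identical(dim(object@finalTable), c(16L, 3L)) ||
      !all(c("genetic", "fun", "final") %in% names(object@finalTable)))
    msgs <- c(msgs, "finalTable must be a 16-row (genetic, fun, final) lookup")
  if (length(msgs)) msgs else TRUE
})
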