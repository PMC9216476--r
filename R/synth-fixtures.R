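#' @include aggregation.R
NULL

.checkDist <- function(p, what) {
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop(what, " probabilities must be non-negative and sum to 1")
  p
}

#' Configuration for the synthetic corpus generator
#'
#' The generator works backwards from target evidence levels to evidence
#' payloads (a constructive inverse of the scoring rules), so every rule
#' branch can be exercised and the intended scores are known exactly.
#' Defaults reflect a literature-curation corpus: mostly digenic
#' combinations with a tail up to five genes, a small fraction of CNV
#' carriers, most variants carrying at least one pathogenic predictor
#' call, and joint population-panel presence being rare.
#'
#' @param nCombinations number of combinations to generate.
#' @param genesPerCombination named probabilities over the number of genes
#'   (names = integers >= 2).
#' @param famLevels,statLevels,geneLevels,varLevels named probabilities
#'   over the target manual levels (names `"0"`.. max level of the
#'   evidence type).
#' @param kstatOutcomes named probabilities over the statistical knowledge
#'   outcome: `"assigned"` (absent from panel, all variants relevant),
#'   `"present_in_population_panel"`, `"clinical_relevance_missing"`,
#'   `"insufficient_information"` (a lookup without entry).
#' @param kgeneLevels named probabilities over `"0"`, `"1"`, `"2"`,
#'   `"unassigned"`.
#' @param kvarLevels named probabilities over `"0"`, `"1"`, `"unassigned"`.
#' @param cnvFraction probability that a combination carries one CNV.
#' @param multiArticleFraction probability that a combination is described
#'   by two articles (evidence split between them; the cross-article
#'   maxima realize the targets).
#' @param boundaryRate probability of emitting threshold-boundary
#'   annotation values (interaction confidence exactly 0.8 as a
#'   non-qualifying decoy edge, CADD Phred exactly 15 as a qualifying
#'   call).
#' @param seed integer seed; generation is reproducible given the config.
#' @return validated config list of class `"generatorConfig"`.
#' @export
generatorConfig <- function(
    nCombinations = 100L,
    genesPerCombination = c("2" = 0.79, "3" = 0.14, "4" = 0.05, "5" = 0.02),
    famLevels = c("0" = 0.45, "1" = 0.20, "2" = 0.20, "3" = 0.15),
    statLevels = c("0" = 0.50, "1" = 0.30, "2" = 0.20),
    geneLevels = c("0" = 0.35, "1" = 0.20, "2" = 0.30, "3" = 0.15),
    varLevels = c("0" = 0.30, "1" = 0.30, "2" = 0.25, "3" = 0.15),
    kstatOutcomes = c(assigned = 0.40, present_in_population_panel = 0.10,
                      clinical_relevance_missing = 0.30,
                      insufficient_information = 0.20),
    kgeneLevels = c("0" = 0.25, "1" = 0.30, "2" = 0.30,
                    unassigned = 0.15),
    kvarLevels = c("0" = 0.15, "1" = 0.65, unassigned = 0.20),
    cnvFraction = 0.068, multiArticleFraction = 0.15,
    boundaryRate = 0.10, seed = 1L) {
  stopifnot(nCombinations >= 1L, cnvFraction >= 0, cnvFraction <= 1,
            multiArticleFraction >= 0, multiArticleFraction <= 1,
            boundaryRate >= 0, boundaryRate <= 1)
  if (any(as.integer(names(genesPerCombination)) < 2L))
    stop("combinations need at least 2 genes")
  if (any(as.integer(names(statLevels)) > 2L))
    stop("unreachable target: statistical manual levels stop at 2")
  if (any(names(kgeneLevels) %in% as.character(3)))
    stop("unreachable target: gene knowledge levels stop at 2")
  cfg <- list(
    nCombinations = as.integer(nCombinations),
    genesPerCombination = .checkDist(genesPerCombination,
                                     "genesPerCombination"),
    famLevels = .checkDist(famLevels, "famLevels"),
    statLevels = .checkDist(statLevels, "statLevels"),
    geneLevels = .checkDist(geneLevels, "geneLevels"),
    varLevels = .checkDist(varLevels, "varLevels"),
    kstatOutcomes = .checkDist(kstatOutcomes, "kstatOutcomes"),
    kgeneLevels = .checkDist(kgeneLevels, "kgeneLevels"),
    kvarLevels = .checkDist(kvarLevels, "kvarLevels"),
    cnvFraction = cnvFraction,
    multiArticleFraction = multiArticleFraction,
    boundaryRate = boundaryRate, seed = as.integer(seed))
  class(cfg) <- c("generatorConfig", "list")
  cfg
}

.sampleLevel <- function(dist) sample(names(dist), 1L, prob = dist)

#' Evidence payloads realizing a target level
#'
#' Constructive inverses of the manual scoring rules: each returns an
#' evidence payload whose score is exactly `level`. Where several distinct
#' evidence configurations realize the same level, one is drawn at random
#' (so repeated generation covers all rule branches); pass `form` to force
#' a specific branch.
#'
#' @param level integer target level.
#' @param form optional integer branch selector.
#' @return the corresponding evidence object.
#' @name levelRealizers
NULL

#' @rdname levelRealizers
#' @export
pedigreeForLevel <- function(level, form = NULL) {
  pick <- function(n) if (is.null(form)) sample.int(n, 1L) else form
  switch(as.character(level),
    "0" = if (pick(2L) == 1L) PedigreeEvidence()
    else  # a single affected genotyped relative alone is not scoreable
      PedigreeEvidence("first", "affected", "full_carrier"),
    "1" = if (pick(2L) == 1L)  # one healthy informative first-degree
      PedigreeEvidence("first", "healthy", "non_carrier")
    else  # imperfect segregation, two first-degree relatives
      PedigreeEvidence(c("first", "first"), c("affected", "affected"),
                       c("full_carrier", "non_carrier")),
    "2" = if (pick(2L) == 1L)  # two first-degree, perfect, no healthy
      # second-degree relative (that would reach 3)
      PedigreeEvidence(c("first", "first", "first"),
                       c("affected", "healthy", "healthy"),
                       c("full_carrier", "non_carrier", "partial_carrier"))
    else  # both degrees informative but an affected partial carrier
      # breaks perfection
      PedigreeEvidence(c("first", "second", "second"),
                       c("healthy", "healthy", "affected"),
                       c("non_carrier", "non_carrier", "partial_carrier")),
    "3" = PedigreeEvidence(c("first", "first", "second"),
                           c("affected", "healthy", "healthy"),
                           c("full_carrier", "non_carrier", "non_carrier")),
    stop("unreachable familial target level: ", level))
}

#' @rdname levelRealizers
#' @export
controlForLevel <- function(level, form = NULL) {
  pick <- function(n) if (is.null(form)) sample.int(n, 1L) else form
  switch(as.character(level),
    "0" = if (pick(2L) == 1L) ControlEvidence()
    else  # control set exists but an essential quality flag fails
      ControlEvidence("cohort", combinationAbsent = TRUE,
                      sizeSufficient = TRUE, ethnicityMatched = FALSE,
                      phenotypesKnown = TRUE),
    "1" = ControlEvidence(if (pick(2L) == 1L) "cohort" else "public_db",
                          combinationAbsent = TRUE, sizeSufficient = TRUE,
                          ethnicityMatched = TRUE, phenotypesKnown = TRUE,
                          explicit = FALSE),
    "2" = ControlEvidence(if (pick(2L) == 1L) "cohort" else "public_db",
                          combinationAbsent = TRUE, sizeSufficient = TRUE,
                          ethnicityMatched = TRUE, phenotypesKnown = TRUE,
                          explicit = TRUE, sequencingSimilar = TRUE),
    stop("unreachable statistical target level: ", level))
}

#' @rdname levelRealizers
#' @export
geneEvidenceForLevel <- function(level, form = NULL) {
  pick <- function(n) if (is.null(form)) sample.int(n, 1L) else form
  switch(as.character(level),
    "0" = if (pick(2L) == 1L) GeneFunctionalEvidence()
    else GeneFunctionalEvidence(
      relationshipTypes = "monogenic_experiments_only",
      phenotypeRelevanceShown = FALSE),
    "1" = switch(pick(3L),
      GeneFunctionalEvidence(
        relationshipTypes = "relevant_pathways_for_phenotype",
        phenotypeRelevanceShown = TRUE),
      GeneFunctionalEvidence(relationshipTypes = "affecting_same_tissue",
                             phenotypeRelevanceShown = TRUE),
      # negative joint experiment caps a direct relationship at weak
      GeneFunctionalEvidence("joint_only", "negative",
                             relationshipTypes = "same_pathway",
                             phenotypeRelevanceShown = TRUE)),
    "2" = switch(pick(3L),
      GeneFunctionalEvidence("joint_only", "effect_shown"),
      GeneFunctionalEvidence("single_units_only", "effect_shown",
                             relationshipTypes = "similar_function"),
      GeneFunctionalEvidence(relationshipTypes = "directly_interacting",
                             phenotypeRelevanceShown = TRUE)),
    "3" = GeneFunctionalEvidence("single_and_joint",
                                 "synergistic_or_additive",
                                 relationshipTypes =
                                   if (pick(2L) == 1L) "same_pathway"
                                 else character(),
                                 phenotypeRelevanceShown = TRUE),
    stop("unreachable gene functional target level: ", level))
}

#' @rdname levelRealizers
#' @export
variantEvidenceForLevel <- function(level, form = NULL) {
  pick <- function(n) if (is.null(form)) sample.int(n, 1L) else form
  switch(as.character(level),
    "0" = VariantFunctionalEvidence(),
    "1" = switch(pick(4L),
      VariantFunctionalEvidence(allPredictedPathogenic = TRUE),
      VariantFunctionalEvidence(mixedExperimentAndPrediction = TRUE),
      VariantFunctionalEvidence("single_units_only",
                                "promising_inconclusive"),
      # negative result caps a clear in-silico joint effect at weak
      VariantFunctionalEvidence(insilicoJointEffectClear = TRUE,
                                negativeResultPresent = TRUE)),
    "2" = switch(pick(3L),
      VariantFunctionalEvidence("joint_only", "effect_shown"),
      VariantFunctionalEvidence("single_units_only", "effect_shown"),
      VariantFunctionalEvidence(insilicoJointEffectClear = TRUE)),
    "3" = VariantFunctionalEvidence("single_and_joint",
                                    "synergistic_or_additive"),
    stop("unreachable variant functional target level: ", level))
}

# The ScoreSet implied by planted levels, via the aggregation rules.
.impliedScores <- function(fam, stat, gene, var, kstatOutcome, kgene, kvar,
                           config) {
  knowledge <- KnowledgeScores(
    stat = if (kstatOutcome == "assigned") 1L else 0L,
    statReason = kstatOutcome,
    gene = if (kgene == "unassigned") NA_integer_ else as.integer(kgene),
    var = if (kvar == "unassigned") NA_integer_ else as.integer(kvar))
  computeMetascores(ManualScores(fam, stat, gene, var), gene, knowledge,
                    config)
}

#' Generate a synthetic curation corpus with planted scores
#'
#' Samples target evidence levels per combination and constructs evidence
#' records realizing exactly those levels (see [levelRealizers]). Each
#' combination receives a unique gene set so corpus-level harmonization
#' cannot mix planted gene scores across combinations. With probability
#' `multiArticleFraction` a combination is split over two articles, the
#' first carrying the pedigree and control evidence, the second the
#' functional evidence, so the cross-article maxima reproduce the targets.
#'
#' @param config a [generatorConfig()].
#' @param scoring a [ScoringConfig-class] used to derive the implied score
#'   sets.
#' @return list with `records`, `entries`, and `truth` — a data.frame of
#'   the planted levels and the implied full score vector per combination.
#' @seealso [generateStore()] for the matching annotation store.
#' @export
generateCorpus <- function(config = generatorConfig(),
                           scoring = scoringConfig()) {
  set.seed(config$seed)
  n <- config$nCombinations
  records <- list()
  entries <- vector("list", n)
  truthRows <- vector("list", n)
  for (i in seq_len(n)) {
    cid <- sprintf("CMB%05d", i)
    k <- as.integer(.sampleLevel(config$genesPerCombination))
    genes <- paste0("G", sprintf("%05d", i), LETTERS[seq_len(k)])
    hasCnv <- stats::runif(1) < config$cnvFraction
    variants <- lapply(seq_len(k), function(j) {
      vid <- sprintf("%s_v%d", cid, j)
      if (hasCnv && j == 1L)
        Variant(vid, genes[j], notation = "cnv", variantClass = "cnv",
                cnvDetail = list(start = 1000L * j, end = 1000L * j + 500L,
                                 change = sample(c("deletion",
                                                   "duplication"), 1L)),
                zygosity = "heterozygous")
      else
        Variant(vid, genes[j], notation = sprintf("c.%dA>G", 100L + j),
                zygosity = sample(c("heterozygous", "homozygous"), 1L,
                                  prob = c(0.9, 0.1)))
    })
    fam <- as.integer(.sampleLevel(config$famLevels))
    stat <- as.integer(.sampleLevel(config$statLevels))
    gene <- as.integer(.sampleLevel(config$geneLevels))
    var <- as.integer(.sampleLevel(config$varLevels))
    kstat <- .sampleLevel(config$kstatOutcomes)
    kgene <- .sampleLevel(config$kgeneLevels)
    kvar <- .sampleLevel(config$kvarLevels)
    multi <- stats::runif(1) < config$multiArticleFraction
    year <- sample(1995:2025, 1L)
    if (multi) {
      a1 <- paste0(cid, "_a1"); a2 <- paste0(cid, "_a2")
      records[[length(records) + 1L]] <- EvidenceRecord(
        cid, a1, year, pedigree = pedigreeForLevel(fam),
        statistical = controlForLevel(stat))
      records[[length(records) + 1L]] <- EvidenceRecord(
        cid, a2, year + 1L, geneFunctional = geneEvidenceForLevel(gene),
        variantFunctional = variantEvidenceForLevel(var))
      refs <- data.frame(articleId = c(a1, a2),
                         year = c(year, year + 1L))
    } else {
      a1 <- paste0(cid, "_a1")
      records[[length(records) + 1L]] <- EvidenceRecord(
        cid, a1, year, pedigree = pedigreeForLevel(fam),
        statistical = controlForLevel(stat),
        geneFunctional = geneEvidenceForLevel(gene),
        variantFunctional = variantEvidenceForLevel(var))
      refs <- data.frame(articleId = a1, year = year)
    }
    entries[[i]] <- CombinationEntry(
      cid, variants, diseaseName = sprintf("synthetic disease %03d",
                                           1L + (i - 1L) %% 40L),
      references = refs)
    implied <- .impliedScores(fam, stat, gene, var, kstat, kgene, kvar,
                              scoring)
    truthRows[[i]] <- cbind(
      data.frame(combination_id = cid, kstat_outcome = kstat,
                 kgene_level = kgene, kvar_level = kvar,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(scoreVector(implied))))
  }
  list(records = records, entries = entries,
       truth = do.call(rbind, truthRows))
}

# A random spanning tree over `genes`, as an edge data.frame.
.spanningEdges <- function(genes) {
  perm <- sample(genes)
  if (length(perm) < 2L)
    return(data.frame(geneA = character(), geneB = character()))
  data.frame(geneA = perm[-length(perm)], geneB = perm[-1],
             stringsAsFactors = FALSE)
}

#' Generate an annotation store realizing planted knowledge outcomes
#'
#' For each combination, emits population-presence, clinical-relevance,
#' interaction, pathway and predictor rows such that the knowledge scores
#' computed from the store equal the planted outcomes in `truth`.
#' Threshold boundary values (interaction confidence exactly 0.8, which
#' does not qualify; CADD Phred exactly 15, which does) are emitted at
#' rate `boundaryRate`.
#'
#' @param entries list of [CombinationEntry-class] objects.
#' @param truth the `truth` data.frame from [generateCorpus()] (columns
#'   `combination_id`, `kstat_outcome`, `kgene_level`, `kvar_level`).
#' @param seed integer seed.
#' @param boundaryRate probability of boundary values.
#' @param config a [ScoringConfig-class] supplying the thresholds.
#' @return an [AnnotationStore-class].
#' @export
generateStore <- function(entries, truth, seed = 1L, boundaryRate = 0.1,
                          config = scoringConfig()) {
  set.seed(seed)
  presence <- logical(); relevance <- logical()
  ppi <- list(); pathways <- list(); predictions <- list()
  thr <- config@ppiThreshold
  caddThr <- config@caddThreshold
  benignRow <- function(key) data.frame(
    variantKey = key, caddPhred = stats::runif(1, 0, caddThr - 1),
    sift = "tolerated", mutationTaster = "polymorphism",
    polyphen = "benign", stringsAsFactors = FALSE)
  pathogenicRow <- function(key) {
    tool <- sample(.PREDICTOR_TOOLS, 1L)
    data.frame(
      variantKey = key,
      caddPhred = if (tool == "cadd") {
        if (stats::runif(1) < boundaryRate) caddThr
        else stats::runif(1, caddThr, 45)
      } else NA_real_,
      sift = if (tool == "sift") "deleterious" else "absent",
      mutationTaster = if (tool == "mutation_taster") "disease_causing"
      else "absent",
      polyphen = if (tool == "polyphen") sample(config@polyphenAccept, 1L)
      else "absent", stringsAsFactors = FALSE)
  }
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    cid <- combinationId(e)
    row <- truth[truth$combination_id == cid, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("no planted truth for combination ", cid)
    keys <- variantKeys(e)
    genes <- geneSymbols(e)

    # statistical outcome
    switch(row$kstat_outcome,
      present_in_population_panel = {
        presence[cid] <- TRUE
      },
      assigned = {
        presence[cid] <- FALSE
        relevance[keys] <- TRUE
      },
      clinical_relevance_missing = {
        presence[cid] <- FALSE
        rel <- rep(TRUE, length(keys))
        rel[sample.int(length(keys), 1L)] <- FALSE
        relevance[keys] <- rel
      },
      insufficient_information = {
        # either the panel lookup or one relevance lookup has no entry
        if (stats::runif(1) < 0.5) {
          presence[cid] <- FALSE
          relevance[keys[-sample.int(length(keys), 1L)]] <- TRUE
        }
      },
      stop("unknown statistical knowledge outcome: ", row$kstat_outcome))

    # gene-level outcome
    addPathway <- function(gene, id, relevant)
      pathways[[length(pathways) + 1L]] <<- data.frame(
        gene = gene, pathwayId = id, phenotypeRelevant = relevant,
        stringsAsFactors = FALSE)
    addDecoyEdge <- function() {
      if (length(genes) >= 2L && stats::runif(1) < boundaryRate) {
        pair <- sample(genes, 2L)
        ppi[[length(ppi) + 1L]] <<- data.frame(
          geneA = pair[1], geneB = pair[2], confidence = thr,
          stringsAsFactors = FALSE)  # exactly at threshold: non-qualifying
      }
    }
    switch(row$kgene_level,
      "2" = {
        if (stats::runif(1) < 0.5) {
          edges <- .spanningEdges(genes)
          edges$confidence <- stats::runif(nrow(edges), thr + 1e-6, 1)
          ppi[[length(ppi) + 1L]] <- edges
        } else {
          for (g in genes) addPathway(g, sprintf("PW_shared_%04d", i), TRUE)
        }
      },
      "1" = {
        for (j in seq_along(genes))
          addPathway(genes[j], sprintf("PW_%04d_%d", i, j), TRUE)
        addDecoyEdge()
      },
      "0" = {
        for (j in seq_along(genes))
          addPathway(genes[j], sprintf("PW_%04d_%d", i, j), FALSE)
        addDecoyEdge()
      },
      unassigned = {
        # one gene absent from every table
        for (g in genes[-sample.int(length(genes), 1L)])
          addPathway(g, sprintf("PW_%04d_x", i), FALSE)
      },
      stop("unknown gene knowledge level: ", row$kgene_level))

    # variant-level outcome
    switch(row$kvar_level,
      "1" = for (key in keys)
        predictions[[length(predictions) + 1L]] <- pathogenicRow(key),
      "0" = {
        failing <- sample.int(length(keys), 1L)
        for (j in seq_along(keys))
          predictions[[length(predictions) + 1L]] <-
            if (j == failing) benignRow(keys[j]) else pathogenicRow(keys[j])
      },
      unassigned = {
        # one variant with no prediction from any tool
        for (key in keys[-sample.int(length(keys), 1L)])
          predictions[[length(predictions) + 1L]] <- pathogenicRow(key)
      },
      stop("unknown variant knowledge level: ", row$kvar_level))
  }
  AnnotationStore(
    populationPresence = presence, clinicalRelevance = relevance,
    ppiEdges = if (length(ppi)) do.call(rbind, ppi)
    else data.frame(geneA = character(), geneB = character(),
                    confidence = numeric()),
    pathways = if (length(pathways)) do.call(rbind, pathways)
    else data.frame(gene = character(), pathwayId = character(),
                    phenotypeRelevant = logical()),
    predictions = if (length(predictions)) do.call(rbind, predictions)
    else data.frame(variantKey = character(), caddPhred = numeric(),
                    sift = character(), mutationTaster = character(),
                    polyphen = character()))
}
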