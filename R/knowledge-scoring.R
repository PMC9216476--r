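#' @include annotation-store.R scoring-config.R
NULL

#' Statistical knowledge score
#'
#' Computed from the reference population panel and per-variant clinical
#' relevance: 0 with reason `"present_in_population_panel"` when the joint
#' combination is found in the panel (this reason later overrides the
#' manual score in the metascore); 1 with reason `"assigned"` when the
#' combination is absent and every involved variant has disease-relevant
#' clinical citations; 0 with reason `"clinical_relevance_missing"` when
#' absent but some variant lacks relevance; 0 with reason
#' `"insufficient_information"` when any required lookup has no entry.
#'
#' @param combinationId combination accession (population-panel membership
#'   is keyed by the joint combination, not individual variants).
#' @param variantKeys character vector of the combination's variant keys.
#' @param store an [AnnotationStore-class].
#' @return list with integer `value` (0-1) and character `reason`.
#' @export
scoreStatKnowledge <- function(combinationId, variantKeys, store) {
  pres <- store@populationPresence
  if (!(combinationId %in% names(pres)))
    return(list(value = 0L, reason = "insufficient_information"))
  if (isTRUE(pres[[combinationId]]))
    return(list(value = 0L, reason = "present_in_population_panel"))
  rel <- store@clinicalRelevance
  if (!all(variantKeys %in% names(rel)))
    return(list(value = 0L, reason = "insufficient_information"))
  if (all(rel[variantKeys]))
    list(value = 1L, reason = "assigned")
  else
    list(value = 0L, reason = "clinical_relevance_missing")
}

# Edges among `genes` whose confidence strictly exceeds the threshold.
.qualifyingEdges <- function(genes, store, config) {
  e <- store@ppiEdges
  keep <- e$geneA %in% genes & e$geneB %in% genes &
    e$confidence > config@ppiThreshold
  e[keep, , drop = FALSE]
}

#' Gene-combination knowledge score
#'
#' Computed from interaction and pathway tables; assigned only when every
#' gene of the combination has an entry in at least one table, otherwise
#' `NA` (unassigned). Value 2 when the genes form a connected interaction
#' network using only edges with confidence strictly above the threshold,
#' or when all genes share a common phenotype-relevant pathway; 1 when
#' every gene has at least one phenotype-relevant pathway; 0 otherwise.
#'
#' @param genes character vector of two or more gene symbols.
#' @param store an [AnnotationStore-class].
#' @param config a [ScoringConfig-class].
#' @return integer 0-2, or `NA` when unassigned.
#' @export
scoreGeneKnowledge <- function(genes, store, config = scoringConfig()) {
  genes <- unique(genes)
  if (length(genes) < 2L)
    stop("scoreGeneKnowledge requires at least 2 genes")
  known <- genes %in% c(store@ppiEdges$geneA, store@ppiEdges$geneB,
                        store@pathways$gene)
  if (!all(known))
    return(NA_integer_)
  edges <- .qualifyingEdges(genes, store, config)
  connected <- if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("geneA", "geneB")],
                                       directed = FALSE,
                                       vertices = data.frame(name = genes))
    igraph::is_connected(g)
  } else FALSE
  pw <- store@pathways
  relevant <- pw[pw$gene %in% genes & pw$phenotypeRelevant, , drop = FALSE]
  commonRelevant <- length(genes) > 0L &&
    any(vapply(unique(relevant$pathwayId), function(id)
      all(genes %in% relevant$gene[relevant$pathwayId == id]), logical(1)))
  if (connected || commonRelevant)
    return(2L)
  if (all(genes %in% relevant$gene))
    return(1L)
  0L
}

#' Is a single predictor call pathogenic?
#'
#' Per-tool rules: CADD Phred greater or equal to the configured threshold
#' (15 by default, the threshold value itself passes); SIFT
#' `"deleterious"`; MutationTaster2 `"disease_causing"`; PolyPhen-2 in the
#' accepted damaging categories. Absent values are never pathogenic.
#'
#' @param tool one of `"cadd"`, `"sift"`, `"mutation_taster"`,
#'   `"polyphen"`.
#' @param value the call: numeric for CADD, category string otherwise.
#' @param config a [ScoringConfig-class].
#' @return logical.
#' @export
isPathogenicCall <- function(tool, value, config = scoringConfig()) {
  switch(tool,
    cadd = !is.na(value) && is.numeric(value) &&
      value >= config@caddThreshold,
    sift = identical(value, "deleterious"),
    mutation_taster = identical(value, "disease_causing"),
    polyphen = !is.na(value) && value %in% config@polyphenAccept,
    stop("unknown predictor tool: ", tool))
}

.hasAnyPrediction <- function(row) {
  !is.na(row$caddPhred) || row$sift != "absent" ||
    row$mutationTaster != "absent" || row$polyphen != "absent"
}

.hasPathogenicCall <- function(row, config) {
  isPathogenicCall("cadd", row$caddPhred, config) ||
    isPathogenicCall("sift", row$sift, config) ||
    isPathogenicCall("mutation_taster", row$mutationTaster, config) ||
    isPathogenicCall("polyphen", row$polyphen, config)
}

#' Variant-combination knowledge score
#'
#' Computed from per-variant pathogenicity predictor calls; assigned only
#' when every variant has at least one prediction from any tool, otherwise
#' `NA` (unassigned). Value 1 when every variant has at least one
#' pathogenic call; 0 when all variants are predicted but some variant has
#' no pathogenic call.
#'
#' @param variantKeys character vector of two or more variant keys.
#' @param store an [AnnotationStore-class].
#' @param config a [ScoringConfig-class].
#' @return integer 0-1, or `NA` when unassigned.
#' @export
scoreVariantKnowledge <- function(variantKeys, store,
                                  config = scoringConfig()) {
  pred <- store@predictions
  perVariant <- vapply(variantKeys, function(k) {
    rows <- pred[pred$variantKey == k, , drop = FALSE]
    if (nrow(rows) == 0L)
      return(NA)
    predicted <- any(vapply(seq_len(nrow(rows)), function(i)
      .hasAnyPrediction(rows[i, ]), logical(1)))
    if (!predicted)
      return(NA)
    any(vapply(seq_len(nrow(rows)), function(i)
      .hasPathogenicCall(rows[i, ], config), logical(1)))
  }, logical(1))
  if (anyNA(perVariant))
    return(NA_integer_)
  if (all(perVariant)) 1L else 0L
}

#' Knowledge score vector for one combination
#'
#' Convenience wrapper applying the three knowledge scorers to an entry.
#'
#' @param entry a [CombinationEntry-class].
#' @param store an [AnnotationStore-class].
#' @param config a [ScoringConfig-class].
#' @return a [KnowledgeScores-class].
#' @export
scoreKnowledge <- function(entry, store, config = scoringConfig()) {
  statK <- scoreStatKnowledge(combinationId(entry), variantKeys(entry), store)
  KnowledgeScores(
    stat = statK$value, statReason = statK$reason,
    gene = scoreGeneKnowledge(geneSymbols(entry), store, config),
    var = scoreVariantKnowledge(variantKeys(entry), store, config))
}
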