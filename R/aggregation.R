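#' @include manual-scoring.R knowledge-scoring.R
NULL

#' Cross-article merge of manual scores
#'
#' For a combination described in multiple articles, each evidence type
#' receives the highest manual score found among the articles (different
#' papers may prove different aspects of oligogenicity); the tree
#' aggregates are recomputed downstream from the merged values. The
#' operation is the component-wise maximum, hence idempotent, commutative
#' and associative.
#'
#' @param records non-empty list of [EvidenceRecord-class] objects for one
#'   combination.
#' @return a [ManualScores-class] of component-wise maxima.
#' @export
mergeCrossArticle <- function(records) {
  if (length(records) == 0L)
    stop("mergeCrossArticle requires at least one record")
  ids <- unique(vapply(records, combinationId, character(1)))
  if (length(ids) != 1L)
    stop("records span multiple combinations: ", paste(ids, collapse = ", "))
  scored <- lapply(records, scoreManual)
  ManualScores(
    fam = max(vapply(scored, function(s) s@fam, integer(1))),
    stat = max(vapply(scored, function(s) s@stat, integer(1))),
    gene = max(vapply(scored, function(s) s@gene, integer(1))),
    var = max(vapply(scored, function(s) s@var, integer(1))))
}

#' Corpus-wide harmonization of gene-level manual scores
#'
#' Corrects literature bias: each canonical gene combination receives the
#' maximum gene-level manual score observed for it in any article of the
#' corpus, and every combination sharing that gene set inherits this
#' value. Gene keys are order-independent (case-normalized, sorted).
#'
#' @param records list of [EvidenceRecord-class] objects (the whole
#'   corpus).
#' @param entries list of [CombinationEntry-class] objects supplying the
#'   combination -> gene-set mapping.
#' @return named integer vector, gene-combination key -> harmonized score.
#' @export
harmonizeGeneScores <- function(records, entries) {
  entryKeys <- stats::setNames(
    vapply(entries, geneCombinationId, character(1)),
    vapply(entries, combinationId, character(1)))
  out <- integer()
  for (r in records) {
    key <- entryKeys[[combinationId(r)]]
    if (is.null(key))
      stop("record for unknown combination: ", combinationId(r))
    g <- scoreGeneManual(r@geneFunctional)
    out[[key]] <- max(g, if (key %in% names(out)) out[[key]] else 0L)
  }
  out
}

#' Combine manual and knowledge scores into metascores
#'
#' Per-evidence metascores are the maxima of the corresponding manual and
#' knowledge scores (the gene metascore uses the corpus-harmonized gene
#' score); an unassigned knowledge score falls back to the manual value.
#' One exception: when the statistical knowledge score is 0 because the
#' combination is present in the reference population panel, the
#' statistical metascore is forced to 0 regardless of the manual score.
#' The functional and final trees are then re-applied to the metascores
#' (the familial score has no knowledge counterpart and enters the final
#' tree unchanged); the manual-only aggregates use the harmonized gene
#' score with the un-augmented manual components.
#'
#' @param manual a [ManualScores-class] (cross-article merged).
#' @param harmonized integer 0-3, the corpus-harmonized gene manual score
#'   (at least `manual` gene score).
#' @param knowledge a [KnowledgeScores-class].
#' @param config a [ScoringConfig-class].
#' @return a [ScoreSet-class].
#' @export
computeMetascores <- function(manual, harmonized, knowledge,
                              config = scoringConfig()) {
  harmonized <- .checkLevel(harmonized, "harmonized", 3L)
  funManual <- funTree(harmonized, manual@var, config)
  finalManual <- finalTree(manual@fam, manual@stat, funManual, config)
  statMeta <- if (knowledge@statReason == "present_in_population_panel") 0L
  else max(manual@stat,
           if (knowledge@statReason == "assigned") knowledge@stat else 0L)
  geneMeta <- max(harmonized,
                  if (is.na(knowledge@gene)) 0L else knowledge@gene)
  varMeta <- max(manual@var, if (is.na(knowledge@var)) 0L else knowledge@var)
  funMeta <- funTree(geneMeta, varMeta, config)
  finalMeta <- finalTree(manual@fam, statMeta, funMeta, config)
  new("ScoreSet", manual = manual, knowledge = knowledge,
      geneManualHarmonized = harmonized, funManual = funManual,
      finalManual = finalManual, statMeta = statMeta, geneMeta = geneMeta,
      varMeta = varMeta, funMeta = funMeta, finalMeta = finalMeta)
}

#' Score a whole curation corpus
#'
#' Runs the full deterministic pipeline: per-record manual scoring,
#' cross-article merge per combination, corpus-wide gene harmonization,
#' knowledge scoring against the annotation store, and metascore
#' computation.
#'
#' @param records list of [EvidenceRecord-class] objects.
#' @param entries list of [CombinationEntry-class] objects; every record's
#'   combination must have an entry, and entries must pass
#'   [validateEntry()].
#' @param store an [AnnotationStore-class].
#' @param config a [ScoringConfig-class].
#' @return named list of [ScoreSet-class], one per combination entry.
#' @seealso [scoresTable()] to flatten the result.
#' @export
scorePipeline <- function(records, entries, store = AnnotationStore(),
                          config = scoringConfig()) {
  for (e in entries) {
    issues <- validateEntry(e)
    if (length(issues))
      stop("invalid entry ", combinationId(e), ": ",
           paste(issues, collapse = "; "))
  }
  entryIds <- vapply(entries, combinationId, character(1))
  if (anyDuplicated(entryIds))
    stop("duplicated combination ids among entries")
  recIds <- vapply(records, combinationId, character(1))
  if (!all(recIds %in% entryIds))
    stop("records without a matching entry: ",
         paste(unique(setdiff(recIds, entryIds)), collapse = ", "))
  harmonized <- harmonizeGeneScores(records, entries)
  out <- vector("list", length(entries))
  names(out) <- entryIds
  for (i in seq_along(entries)) {
    entry <- entries[[i]]
    cid <- entryIds[i]
    recs <- records[recIds == cid]
    manual <- if (length(recs)) mergeCrossArticle(recs) else ManualScores()
    key <- geneCombinationId(entry)
    harm <- max(manual@gene,
                if (key %in% names(harmonized)) harmonized[[key]] else 0L)
    knowledge <- scoreKnowledge(entry, store, config)
    out[[cid]] <- computeMetascores(manual, harm, knowledge, config)
  }
  out
}

#' Flatten score sets into a data frame
#'
#' @param scoresets named list of [ScoreSet-class], as returned by
#'   [scorePipeline()].
#' @return data.frame with one row per combination (`combination_id` plus
#'   the components of [scoreVector()] and the statistical knowledge
#'   reason code).
#' @export
scoresTable <- function(scoresets) {
  rows <- lapply(names(scoresets), function(cid) {
    s <- scoresets[[cid]]
    v <- as.list(scoreVector(s))
    cbind(data.frame(combination_id = cid, stringsAsFactors = FALSE),
          as.data.frame(v),
          data.frame(kstat_reason = s@knowledge@statReason,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
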