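#' @include aggregation.R
NULL

.OVERLAP_CATEGORIES <- c("FAM", "STAT", "FUN", "FAM+STAT", "FAM+FUN",
                         "STAT+FUN", "FAM+STAT+FUN", "none")

#' Corpus-level summary report
#'
#' Computes the corpus-wide reporting structures: the distribution of final
#' scores (manual and meta variants), the overlap of the three main
#' evidence classes (familial = merged manual familial score >= 1,
#' statistical = statistical metascore >= 1, functional = functional
#' metascore >= 1: the seven non-empty subsets plus the none category), a
#' 4x4 genetic-by-functional heatmap where the genetic axis is
#' `max(fam, stat)` (one matrix from manual scores, one from metascores),
#' a histogram of gene-relationship types over combinations, and overall
#' corpus counts.
#'
#' @param scoresets named list of [ScoreSet-class] from [scorePipeline()];
#'   every entry must be scored.
#' @param entries list of [CombinationEntry-class] objects.
#' @param records optional list of [EvidenceRecord-class] objects, used
#'   only for the relationship-type histogram (zero-filled when omitted).
#' @return list of class `"corpusSummary"` with elements
#'   `finalScoreDistribution` (2x4 matrix, rows manual/meta),
#'   `evidenceOverlap` (named counts over the 8 categories),
#'   `geneticFunctionalHeatmap` (list of two 4x4 matrices, `manual` and
#'   `meta`), `relationshipHistogram`, and `corpusCounts`.
#' @export
summarizeCorpus <- function(scoresets, entries, records = NULL) {
  ids <- vapply(entries, combinationId, character(1))
  if (!all(ids %in% names(scoresets)))
    stop("unscored entries: ",
         paste(setdiff(ids, names(scoresets)), collapse = ", "))
  sets <- scoresets[ids]
  n <- length(sets)
  lev <- function(slotName) vapply(sets, slot, integer(1), slotName)
  manualFinal <- lev("finalManual")
  metaFinal <- lev("finalMeta")
  dist <- rbind(
    manual = tabulate(manualFinal + 1L, nbins = 4L),
    meta = tabulate(metaFinal + 1L, nbins = 4L))
  colnames(dist) <- as.character(0:3)

  fam <- vapply(sets, function(s) s@manual@fam, integer(1))
  statMeta <- lev("statMeta")
  funMeta <- lev("funMeta")
  cat3 <- function(f, s, u) {
    present <- c(FAM = f >= 1L, STAT = s >= 1L, FUN = u >= 1L)
    if (!any(present)) "none"
    else paste(names(present)[present], collapse = "+")
  }
  overlap <- stats::setNames(integer(length(.OVERLAP_CATEGORIES)),
                             .OVERLAP_CATEGORIES)
  if (n) {
    got <- table(mapply(cat3, fam, statMeta, funMeta))
    overlap[names(got)] <- as.integer(got)
  }

  heat <- function(genetic, fun) {
    m <- matrix(0L, 4, 4, dimnames = list(genetic = 0:3, fun = 0:3))
    for (i in seq_len(n))
      m[genetic[i] + 1L, fun[i] + 1L] <- m[genetic[i] + 1L, fun[i] + 1L] + 1L
    m
  }
  statManual <- vapply(sets, function(s) s@manual@stat, integer(1))
  funManual <- lev("funManual")
  heatmaps <- list(
    manual = heat(pmax(fam, statManual), funManual),
    meta = heat(pmax(fam, statMeta), funMeta))

  relHist <- stats::setNames(integer(length(.RELATIONSHIP_TYPES)),
                             .RELATIONSHIP_TYPES)
  if (!is.null(records)) {
    byComb <- split(records, vapply(records, combinationId, character(1)))
    for (recs in byComb) {
      types <- unique(unlist(lapply(recs, function(r)
        r@geneFunctional@relationshipTypes)))
      relHist[types] <- relHist[types] + 1L
    }
  }

  nGenesPer <- vapply(entries, function(e)
    length(unique(toupper(geneSymbols(e)))), integer(1))
  hasCnv <- vapply(entries, function(e)
    any(vapply(e@variants, function(v) v@variantClass == "cnv",
               logical(1))), logical(1))
  counts <- c(
    combinations = n,
    distinct_variants = length(unique(unlist(lapply(entries, variantKeys)))),
    distinct_genes = length(unique(toupper(unlist(lapply(entries,
                                                         geneSymbols))))),
    diseases = length(unique(vapply(entries, function(e) e@diseaseName,
                                    character(1)))),
    combinations_gt2_genes = sum(nGenesPer > 2L),
    combinations_with_cnv = sum(hasCnv))

  out <- list(finalScoreDistribution = dist, evidenceOverlap = overlap,
              geneticFunctionalHeatmap = heatmaps,
              relationshipHistogram = relHist, corpusCounts = counts)
  class(out) <- c("corpusSummary", "list")
  out
}

#' @export
print.corpusSummary <- function(x, ...) {
  cat("Corpus summary:", x$corpusCounts[["combinations"]],
      "combinations\n\nFinal score distribution (columns = level):\n")
  print(x$finalScoreDistribution)
  cat("\nEvidence overlap (FAM manual / STAT meta / FUN meta >= 1):\n")
  print(x$evidenceOverlap)
  cat("\nGenetic x functional heatmap (meta):\n")
  print(x$geneticFunctionalHeatmap$meta)
  cat("\nCorpus counts:\n")
  print(x$corpusCounts)
  invisible(x)
}
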