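#' @include constructors.R
NULL

#' Validate a combination entry
#'
#' Checks the structural invariants of an entry: at least two distinct gene
#' symbols among its variants, per-variant CNV/coordinate consistency, and
#' non-duplicated references. Issues are returned (not thrown) so a corpus
#' can be screened in bulk; an entry with an empty issue list is safe for
#' every scoring operation.
#'
#' @param entry a [CombinationEntry-class].
#' @return character vector of issues, each naming the field and the
#'   violated rule; empty when the entry is well-formed.
#' @examples
#' e <- digenicEntry("OLI1", c("GJB2", "GJB6"))
#' validateEntry(e)  # character(0)
#' @export
validateEntry <- function(entry) {
  issues <- character()
  if (!is(entry, "CombinationEntry"))
    return("entry: not a CombinationEntry")
  if (length(entry@variants) < 2L)
    issues <- c(issues, "variants: fewer than 2 variants")
  syms <- tryCatch(geneSymbols(entry), error = function(e) character())
  if (length(unique(toupper(syms))) < 2L)
    issues <- c(issues, "genes: fewer than 2 distinct genes")
  for (v in entry@variants) {
    msg <- validObject(v, test = TRUE)
    if (is.character(msg))
      issues <- c(issues,
                  sprintf("variant %s: %s", v@localId,
                          paste(msg, collapse = "; ")))
  }
  msg <- validObject(entry, test = TRUE)
  if (is.character(msg))
    issues <- c(issues, paste0("entry: ", msg))
  issues
}

#' Normalize gene symbols and disease names
#'
#' Replaces curated ("raw") gene symbols and disease names by their
#' standardized forms from user-supplied maps, mirroring nomenclature
#' harmonization against reference naming authorities. Unmapped inputs pass
#' through unchanged and are flagged in the attached normalization report.
#' The operation is deterministic and idempotent.
#'
#' @param entry a [CombinationEntry-class].
#' @param geneMap named character vector, raw symbol -> normalized symbol.
#' @param diseaseMap data.frame with columns `raw`, `name` and optionally
#'   `id`, mapping raw disease names to standardized names/identifiers.
#' @return the normalized [CombinationEntry-class], with attribute
#'   `"normalizationReport"`: a data.frame of (`kind`, `raw`, `mapped`)
#'   rows, `mapped = NA` for inputs absent from the maps.
#' @examples
#' e <- digenicEntry("OLI606", c("MKL2", "MYH7"))
#' e2 <- normalizeSymbols(e, geneMap = c(MKL2 = "MRTFB"))
#' geneSymbols(e2)  # "MRTFB" "MYH7"
#' @export
normalizeSymbols <- function(entry, geneMap = character(),
                             diseaseMap = data.frame(raw = character(),
                                                     name = character())) {
  report <- data.frame(kind = character(), raw = character(),
                       mapped = character(), stringsAsFactors = FALSE)
  variants <- lapply(entry@variants, function(v) {
    raw <- v@geneSymbol
    if (raw %in% names(geneMap)) {
      v@geneSymbol <- unname(geneMap[[raw]])
      if (v@rawSymbol == raw || !nzchar(v@rawSymbol)) v@rawSymbol <- raw
      report <<- rbind(report, data.frame(kind = "gene", raw = raw,
                                          mapped = v@geneSymbol))
    } else {
      report <<- rbind(report, data.frame(kind = "gene", raw = raw,
                                          mapped = NA_character_))
    }
    v
  })
  entry@variants <- variants
  rawDisease <- entry@diseaseName
  hit <- match(rawDisease, diseaseMap$raw)
  if (!is.na(hit)) {
    entry@diseaseName <- diseaseMap$name[hit]
    if ("id" %in% names(diseaseMap))
      entry@diseaseId <- as.character(diseaseMap$id[hit])
    report <- rbind(report, data.frame(kind = "disease", raw = rawDisease,
                                       mapped = entry@diseaseName))
  } else if (nzchar(rawDisease)) {
    report <- rbind(report, data.frame(kind = "disease", raw = rawDisease,
                                       mapped = NA_character_))
  }
  attr(entry, "normalizationReport") <- report
  entry
}

#' Set the coordinate flag of a variant
#'
#' Variants whose genomic coordinates could be resolved are flagged
#' `"mapped"`, those without coordinates `"unmapped"`. A curator override to
#' `"manual_review"` is preserved.
#'
#' @param variant a [Variant-class].
#' @return the variant with `coordinateFlag` updated.
#' @export
flagCoordinates <- function(variant) {
  if (variant@coordinateFlag == "manual_review")
    return(variant)
  variant@coordinateFlag <-
    if (length(variant@coordinates)) "mapped" else "unmapped"
  variant
}

.payloadDiff <- function(a, b, prefix) {
  slots <- slotNames(class(a))
  out <- character()
  for (s in slots) {
    va <- slot(a, s)
    vb <- slot(b, s)
    eq <- if (is.data.frame(va)) {
      isTRUE(all.equal(va, vb, check.attributes = FALSE)) &&
        nrow(va) == nrow(vb)
    } else identical(va, vb)
    if (!eq) out <- c(out, paste0(prefix, ".", s))
  }
  out
}

#' Reconcile two independent curations
#'
#' Compares the evidence payloads of two records for the same
#' (combination, article) pair, field by field. Identical payloads yield a
#' consensus (the first record); any difference is reported for curator
#' discussion — no automatic resolution is attempted, since score conflicts
#' are settled by consensus between curators, not by rule.
#'
#' @param a,b [EvidenceRecord-class] objects for the same combination and
#'   article (curators may differ).
#' @return a list with `consensus` (the record, or `NULL` on conflict) and
#'   `conflicts` (character vector of differing field paths, e.g.
#'   `"pedigree.relatives"`). Conflict detection is symmetric in `a`, `b`.
#' @export
reconcileCurations <- function(a, b) {
  if (!identical(a@combinationId, b@combinationId) ||
      !identical(a@articleId, b@articleId))
    stop("non-comparable records: combinationId/articleId differ")
  conflicts <- c(
    .payloadDiff(a@pedigree, b@pedigree, "pedigree"),
    .payloadDiff(a@statistical, b@statistical, "statistical"),
    .payloadDiff(a@geneFunctional, b@geneFunctional, "geneFunctional"),
    .payloadDiff(a@variantFunctional, b@variantFunctional,
                 "variantFunctional"))
  list(consensus = if (length(conflicts)) NULL else a, conflicts = conflicts)
}
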