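#' @include AllClasses.R
NULL

#' Accessors for curation objects
#'
#' `combinationId()` returns the combination accession; `geneSymbols()` the
#' distinct normalized gene symbols of an entry; `geneCombinationId()` the
#' canonical gene-combination key (upper-cased, lexicographically sorted
#' symbols joined with `","`), which is order-independent and drives
#' corpus-level harmonization; `variantKeys()` the variants' local
#' identifiers used to join annotation tables.
#'
#' @param x a [CombinationEntry-class] or [EvidenceRecord-class].
#' @return character vector (length 1 for the id accessors).
#' @examples
#' entry <- digenicEntry("OLI1", c("TGB", "TGA"), disease = "demo disease")
#' geneCombinationId(entry)  # "TGA,TGB"
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("combinationId", function(x) standardGeneric("combinationId"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("geneCombinationId",
           function(x) standardGeneric("geneCombinationId"))

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname accessors
#' @export
setMethod("combinationId", "CombinationEntry", function(x) x@combinationId)

#' @rdname accessors
#' @export
setMethod("combinationId", "EvidenceRecord", function(x) x@combinationId)

#' @rdname accessors
#' @export
setMethod("geneSymbols", "CombinationEntry", function(x) {
  unique(vapply(x@variants, function(v) v@geneSymbol, character(1)))
})

#' Canonical gene-combination key from raw symbols
#'
#' Case-normalizes (upper case), deduplicates and sorts gene symbols, then
#' joins them with `","`. Used as the harmonization key for gene-level
#' scores.
#'
#' @param symbols character vector of gene symbols.
#' @return single character key.
#' @export
canonicalGeneKey <- function(symbols) {
  paste(sort(unique(toupper(symbols))), collapse = ",")
}

#' @rdname accessors
#' @export
setMethod("geneCombinationId", "CombinationEntry", function(x) {
  canonicalGeneKey(geneSymbols(x))
})

#' @rdname accessors
#' @export
setMethod("variantKeys", "CombinationEntry", function(x) {
  vapply(x@variants, function(v) v@localId, character(1))
})

#' Extract score components from a ScoreSet
#'
#' `scoreVector()` flattens a [ScoreSet-class] into a named integer vector
#' with components `fam`, `stat`, `gene`, `var` (manual, cross-article
#' maxima), `gene_harmonized`, `fun_manual`, `final_manual`, `kstat`,
#' `kgene`, `kvar` (knowledge; `NA` = unassigned), `stat_meta`, `gene_meta`,
#' `var_meta`, `fun_meta`, `final_meta`.
#'
#' @param x a [ScoreSet-class].
#' @return named integer vector.
#' @export
setGeneric("scoreVector", function(x) standardGeneric("scoreVector"))

#' @rdname scoreVector
#' @export
setMethod("scoreVector", "ScoreSet", function(x) {
  c(fam = x@manual@fam, stat = x@manual@stat, gene = x@manual@gene,
    var = x@manual@var, gene_harmonized = x@geneManualHarmonized,
    fun_manual = x@funManual, final_manual = x@finalManual,
    kstat = x@knowledge@stat, kgene = x@knowledge@gene,
    kvar = x@knowledge@var, stat_meta = x@statMeta, gene_meta = x@geneMeta,
    var_meta = x@varMeta, fun_meta = x@funMeta, final_meta = x@finalMeta)
})

#' Supported controlled vocabularies
#'
#' `relationshipTypes()` returns the ten recognised gene-relationship
#' categories plus the `"monogenic_experiments_only"` marker.
#'
#' @return character vector.
#' @export
relationshipTypes <- function() .RELATIONSHIP_TYPES
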