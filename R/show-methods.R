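#' @include AllClasses.R AllGenerics.R
NULL

.levelWord <- function(x) {
  if (is.na(x)) return("unassigned")
  c("Absent", "Weak", "Moderate", "Strong")[x + 1L]
}

setMethod("show", "Variant", function(object) {
  cat(sprintf("Variant %s | %s (%s) %s [%s, %s, %s]\n", object@localId,
              object@geneSymbol, object@rawSymbol, object@notation,
              object@variantClass, object@zygosity, object@coordinateFlag))
})

setMethod("show", "EvidenceRecord", function(object) {
  cat(sprintf("EvidenceRecord %s | article %s | curator %s\n",
              object@combinationId, object@articleId, object@curatorId))
  cat(sprintf("  relatives: %d | statistical source: %s\n",
              nrow(object@pedigree@relatives), object@statistical@source))
  cat(sprintf("  gene functional: %s/%s | variant functional: %s/%s\n",
              object@geneFunctional@experimentDesign,
              object@geneFunctional@experimentOutcome,
              object@variantFunctional@experimentDesign,
              object@variantFunctional@experimentOutcome))
})

setMethod("show", "CombinationEntry", function(object) {
  cat(sprintf("CombinationEntry %s | %d variants in %s | %s\n",
              object@combinationId, length(object@variants),
              geneCombinationId(object), object@diseaseName))
})

setMethod("show", "ManualScores", function(object) {
  cat(sprintf("ManualScores: FAM %d | STAT %d | GENE %d | VAR %d\n",
              object@fam, object@stat, object@gene, object@var))
})

setMethod("show", "KnowledgeScores", function(object) {
  cat(sprintf("KnowledgeScores: STAT %d (%s) | GENE %s | VAR %s\n",
              object@stat, object@statReason,
              .levelWord(object@gene), .levelWord(object@var)))
})

setMethod("show", "ScoreSet", function(object) {
  v <- scoreVector(object)
  cat("ScoreSet\n")
  cat(sprintf("  manual: FAM %d STAT %d GENE %d (harmonized %d) VAR %d",
              v[["fam"]], v[["stat"]], v[["gene"]],
              v[["gene_harmonized"]], v[["var"]]),
      sprintf("-> FUN %d FINAL %d\n", v[["fun_manual"]],
              v[["final_manual"]]))
  cat(sprintf("  knowledge: STAT %d (%s) GENE %s VAR %s\n",
              v[["kstat"]], object@knowledge@statReason,
              .levelWord(object@knowledge@gene),
              .levelWord(object@knowledge@var)))
  cat(sprintf("  meta: STAT %d GENE %d VAR %d -> FUN %d FINAL %d (%s)\n",
              v[["stat_meta"]], v[["gene_meta"]], v[["var_meta"]],
              v[["fun_meta"]], v[["final_meta"]],
              .levelWord(v[["final_meta"]])))
})

setMethod("show", "AnnotationStore", function(object) {
  cat(sprintf(paste0("AnnotationStore: %d panel entries | %d relevance",
                     " entries | %d PPI edges | %d pathway rows | %d",
                     " prediction rows\n"),
              length(object@populationPresence),
              length(object@clinicalRelevance), nrow(object@ppiEdges),
              nrow(object@pathways), nrow(object@predictions)))
})

setMethod("show", "ScoringConfig", function(object) {
  cat(sprintf(paste0("ScoringConfig: PPI confidence > %g | CADD Phred >=",
                     " %g | PolyPhen-2 accepts: %s\n"),
              object@ppiThreshold, object@caddThreshold,
              paste(object@polyphenAccept, collapse = ", ")))
})
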