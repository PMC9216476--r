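#' @include constructors.R
NULL

.STORE_FILES <- c(populationPresence = "population_presence.tsv",
                  clinicalRelevance = "clinical_relevance.tsv",
                  ppiEdges = "ppi_edges.tsv",
                  pathways = "pathways.tsv",
                  predictions = "predictions.tsv")

#' Read / write an annotation store as TSV tables
#'
#' The store is a directory of five tab-separated tables:
#' `population_presence.tsv` (`combination_id`, `present`),
#' `clinical_relevance.tsv` (`variant_key`, `relevant`),
#' `ppi_edges.tsv` (`gene_a`, `gene_b`, `confidence`),
#' `pathways.tsv` (`gene`, `pathway_id`, `phenotype_relevant`) and
#' `predictions.tsv` (`variant_key`, `cadd_phred`, `sift`,
#' `mutation_taster`, `polyphen`). Missing predictor values are written as
#' empty fields / `"absent"`. A key absent from a table is an explicit
#' "no entry" state for the knowledge scores.
#'
#' @param dir directory containing (or to receive) the five tables.
#' @return `readAnnotationStore` returns an [AnnotationStore-class];
#'   `writeAnnotationStore` invisibly returns the file paths.
#' @export
readAnnotationStore <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path))
      stop("missing annotation table: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  pp <- rd(.STORE_FILES[["populationPresence"]])
  cr <- rd(.STORE_FILES[["clinicalRelevance"]])
  ppi <- rd(.STORE_FILES[["ppiEdges"]])
  pw <- rd(.STORE_FILES[["pathways"]])
  pred <- rd(.STORE_FILES[["predictions"]])
  AnnotationStore(
    populationPresence = stats::setNames(as.logical(pp$present),
                                         pp$combination_id),
    clinicalRelevance = stats::setNames(as.logical(cr$relevant),
                                        cr$variant_key),
    ppiEdges = data.frame(geneA = ppi$gene_a, geneB = ppi$gene_b,
                          confidence = as.numeric(ppi$confidence),
                          stringsAsFactors = FALSE),
    pathways = data.frame(gene = pw$gene, pathwayId = pw$pathway_id,
                          phenotypeRelevant = as.logical(pw$phenotype_relevant),
                          stringsAsFactors = FALSE),
    predictions = data.frame(
      variantKey = pred$variant_key,
      caddPhred = suppressWarnings(as.numeric(pred$cadd_phred)),
      sift = ifelse(nzchar(pred$sift), pred$sift, "absent"),
      mutationTaster = ifelse(nzchar(pred$mutation_taster),
                              pred$mutation_taster, "absent"),
      polyphen = ifelse(nzchar(pred$polyphen), pred$polyphen, "absent"),
      stringsAsFactors = FALSE))
}

#' @rdname readAnnotationStore
#' @param store an [AnnotationStore-class].
#' @export
writeAnnotationStore <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    path <- file.path(dir, f)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    path
  }
  paths <- c(
    wt(data.frame(combination_id = names(store@populationPresence),
                  present = store@populationPresence),
       .STORE_FILES[["populationPresence"]]),
    wt(data.frame(variant_key = names(store@clinicalRelevance),
                  relevant = store@clinicalRelevance),
       .STORE_FILES[["clinicalRelevance"]]),
    wt(data.frame(gene_a = store@ppiEdges$geneA,
                  gene_b = store@ppiEdges$geneB,
                  confidence = store@ppiEdges$confidence),
       .STORE_FILES[["ppiEdges"]]),
    wt(data.frame(gene = store@pathways$gene,
                  pathway_id = store@pathways$pathwayId,
                  phenotype_relevant = store@pathways$phenotypeRelevant),
       .STORE_FILES[["pathways"]]),
    wt(data.frame(variant_key = store@predictions$variantKey,
                  cadd_phred = store@predictions$caddPhred,
                  sift = store@predictions$sift,
                  mutation_taster = store@predictions$mutationTaster,
                  polyphen = store@predictions$polyphen),
       .STORE_FILES[["predictions"]]))
  invisible(paths)
}
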