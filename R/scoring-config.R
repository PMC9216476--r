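#' @include AllClasses.R
NULL

# Closed-form rules from which the audit lookup tables are materialized.
# fun: 0 when either side is absent; 3 only when BOTH gene and variant
# functional evidence are strong; 2 when either reaches moderate; else 1.
.funRule <- function(gene, var) {
  if (min(gene, var) == 0L) 0L
  else if (gene == 3L && var == 3L) 3L
  else if (max(gene, var) >= 2L) 2L
  else 1L
}

# final: both a genetic leg (max of familial and statistical) and a
# functional leg are required; strong needs strong functional evidence with
# at least moderate genetic evidence.
.finalRule <- function(genetic, fun) {
  if (genetic == 0L || fun == 0L) 0L
  else if (fun == 3L && genetic >= 2L) 3L
  else if ((fun >= 2L && genetic >= 2L) || (fun == 3L && genetic == 1L)) 2L
  else 1L
}

#' Build a scoring configuration
#'
#' Assembles the thresholds used by the knowledge scores and the two
#' decision trees as flat lookup tables. The interaction-confidence bound is
#' strict (an edge with confidence exactly at the threshold does not
#' qualify); the CADD Phred bound is inclusive (a value exactly at the
#' threshold is a pathogenic call). Tree tables may be supplied to replace
#' the built-in trees wholesale, e.g. after an audit.
#'
#' @param ppiThreshold interaction-confidence threshold (default 0.8,
#'   strictly greater-than).
#' @param caddThreshold CADD Phred threshold (default 15, greater-or-equal).
#' @param polyphenAccept PolyPhen-2 categories counted as deleterious.
#' @param funTable,finalTable optional replacement lookup tables with the
#'   shapes documented in [ScoringConfig-class].
#' @return a [ScoringConfig-class].
#' @examples
#' cfg <- scoringConfig()
#' funTree(3, 3, cfg)   # 3
#' finalTree(2, 0, 3, cfg)  # 3
#' @export
scoringConfig <- function(ppiThreshold = 0.8, caddThreshold = 15,
                          polyphenAccept = c("probably_damaging",
                                             "possibly_damaging"),
                          funTable = NULL, finalTable = NULL) {
  if (is.null(funTable)) {
    funTable <- expand.grid(gene = 0:3, var = 0:3, KEEP.OUT.ATTRS = FALSE)
    funTable$fun <- mapply(.funRule, funTable$gene, funTable$var)
  }
  if (is.null(finalTable)) {
    finalTable <- expand.grid(genetic = 0:3, fun = 0:3,
                              KEEP.OUT.ATTRS = FALSE)
    finalTable$final <- mapply(.finalRule, finalTable$genetic, finalTable$fun)
  }
  new("ScoringConfig", ppiThreshold = ppiThreshold,
      caddThreshold = caddThreshold, polyphenAccept = polyphenAccept,
      funTable = as.data.frame(funTable), finalTable = as.data.frame(finalTable))
}

.checkLevel <- function(x, what, max) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < 0L || x > max)
    stop(sprintf("%s must be an integer in 0..%d", what, max))
  as.integer(x)
}

#' Functional decision tree
#'
#' Aggregates the gene-combination and variant-combination functional
#' levels into one functional score, via the lookup table in `config`.
#' With the default table: 0 when either input is 0; 3 only when both are
#' 3; 2 when either input reaches 2; 1 otherwise.
#'
#' @param gene,var integer levels 0-3.
#' @param config a [ScoringConfig-class].
#' @return integer level 0-3.
#' @export
funTree <- function(gene, var, config = scoringConfig()) {
  gene <- .checkLevel(gene, "gene", 3L)
  var <- .checkLevel(var, "var", 3L)
  tab <- config@funTable
  as.integer(tab$fun[tab$gene == gene & tab$var == var])
}

#' Final decision tree
#'
#' Combines the familial, statistical and functional levels into the
#' overall confidence score. The genetic leg is `max(fam, stat)`; with the
#' default table both legs must be non-zero for any score, strong requires
#' strong functional evidence with at least moderate genetic evidence, and
#' moderate is reached with both legs moderate or strong functional
#' evidence on a weak genetic leg.
#'
#' @param fam integer familial level 0-3.
#' @param stat integer statistical level 0-2.
#' @param fun integer functional level 0-3.
#' @param config a [ScoringConfig-class].
#' @return integer level 0-3.
#' @export
finalTree <- function(fam, stat, fun, config = scoringConfig()) {
  fam <- .checkLevel(fam, "fam", 3L)
  stat <- .checkLevel(stat, "stat", 2L)
  fun <- .checkLevel(fun, "fun", 3L)
  genetic <- max(fam, stat)
  tab <- config@finalTable
  as.integer(tab$final[tab$genetic == genetic & tab$fun == fun])
}

#' Dump the decision trees as audit TSV tables
#'
#' Writes `fun_tree.tsv` (gene, var -> fun) and `final_tree.tsv`
#' (genetic, fun -> final) so the exact trees in force can be inspected,
#' diffed, or replaced via [scoringConfig()].
#'
#' @param config a [ScoringConfig-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
writeTreeTables <- function(config = scoringConfig(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "fun_tree.tsv"), file.path(dir, "final_tree.tsv"))
  utils::write.table(config@funTable, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(config@finalTable, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
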