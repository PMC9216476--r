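#' @include constructors.R
NULL

.ENTITY_NAMES <- c("combinations", "variants", "genes", "gene_combinations",
                   "diseases", "references")

# Column inventory and numeric columns per entity table; column order is
# fixed so serialization is bit-stable.
.ENTITY_SCHEMA <- list(
  combinations = list(
    cols = c("combination_id", "gene_combination_id", "disease_name",
             "n_variants"),
    num = "n_variants", key = "combination_id"),
  variants = list(
    cols = c("variant_id", "combination_id", "gene_symbol", "notation",
             "variant_class", "zygosity", "coordinate_flag", "genome_build",
             "chromosome", "start", "ref", "alt", "cnv_start", "cnv_end",
             "cnv_change"),
    num = c("start", "cnv_start", "cnv_end"),
    key = c("variant_id", "combination_id")),
  genes = list(cols = c("gene_symbol", "raw_symbol"), num = character(),
               key = c("gene_symbol", "raw_symbol")),
  gene_combinations = list(
    cols = c("gene_combination_id", "gene_symbols", "n_genes"),
    num = "n_genes", key = "gene_combination_id"),
  diseases = list(cols = c("disease_name", "ontology_id"), num = character(),
                  key = "disease_name"),
  references = list(cols = c("article_id", "year", "combination_id"),
                    num = "year", key = c("article_id", "combination_id")))

.chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Build the six entity tables from combination entries
#'
#' Flattens a corpus into the six cross-referenced tabular sections
#' (combinations, variants, genes, gene combinations, diseases,
#' references) with stable column order and primary-key row sort, ready
#' for [writeTables()].
#'
#' @param entries list of [CombinationEntry-class] objects.
#' @return named list of six data.frames (class `"entityTables"`).
#' @export
entityTables <- function(entries) {
  comb <- list(); vars <- list(); refs <- list()
  genes <- list(); gcomb <- list(); dis <- list()
  for (e in entries) {
    cid <- combinationId(e)
    gkey <- geneCombinationId(e)
    comb[[cid]] <- data.frame(
      combination_id = cid, gene_combination_id = gkey,
      disease_name = .chr(e@diseaseName),
      n_variants = length(e@variants), stringsAsFactors = FALSE)
    gcomb[[gkey]] <- data.frame(
      gene_combination_id = gkey,
      gene_symbols = paste(sort(unique(toupper(geneSymbols(e)))),
                           collapse = ","),
      n_genes = length(unique(toupper(geneSymbols(e)))),
      stringsAsFactors = FALSE)
    dn <- .chr(e@diseaseName)
    dis[[dn]] <- data.frame(disease_name = dn,
                            ontology_id = .chr(e@diseaseId),
                            stringsAsFactors = FALSE)
    if (nrow(e@references))
      refs[[cid]] <- data.frame(article_id = .chr(e@references$articleId),
                                year = e@references$year,
                                combination_id = cid,
                                stringsAsFactors = FALSE)
    for (v in e@variants) {
      co <- v@coordinates
      cd <- v@cnvDetail
      vars[[paste(cid, v@localId)]] <- data.frame(
        variant_id = v@localId, combination_id = cid,
        gene_symbol = v@geneSymbol, notation = .chr(v@notation),
        variant_class = v@variantClass, zygosity = v@zygosity,
        coordinate_flag = v@coordinateFlag,
        genome_build = if (length(co)) .chr(co$genomeBuild) else "",
        chromosome = if (length(co)) .chr(co$chromosome) else "",
        start = if (length(co)) as.numeric(co$start) else NA_real_,
        ref = if (length(co)) .chr(co$ref) else "",
        alt = if (length(co)) .chr(co$alt) else "",
        cnv_start = if (length(cd)) as.numeric(cd$start) else NA_real_,
        cnv_end = if (length(cd)) as.numeric(cd$end) else NA_real_,
        cnv_change = if (length(cd)) cd$change else "",
        stringsAsFactors = FALSE)
      genes[[paste(v@geneSymbol, v@rawSymbol)]] <- data.frame(
        gene_symbol = v@geneSymbol, raw_symbol = v@rawSymbol,
        stringsAsFactors = FALSE)
    }
  }
  bindRows <- function(lst, schema) {
    df <- if (length(lst)) do.call(rbind, unname(lst))
    else as.data.frame(stats::setNames(
      lapply(schema$cols, function(cc)
        if (cc %in% schema$num) numeric() else character()), schema$cols))
    df <- df[, schema$cols, drop = FALSE]
    ord <- do.call(order, unname(df[, schema$key, drop = FALSE]))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  out <- lapply(stats::setNames(nm = .ENTITY_NAMES), function(nm)
    bindRows(get(c(combinations = "comb", variants = "vars",
                   genes = "genes", gene_combinations = "gcomb",
                   diseases = "dis", references = "refs")[[nm]]),
             .ENTITY_SCHEMA[[nm]]))
  class(out) <- c("entityTables", "list")
  out
}

#' Check referential integrity of entity tables
#'
#' @param tables named list of the six entity tables.
#' @return character vector describing dangling keys; empty when the table
#'   set is internally consistent.
#' @export
checkIntegrity <- function(tables) {
  missing <- setdiff(.ENTITY_NAMES, names(tables))
  if (length(missing))
    return(paste("missing tables:", paste(missing, collapse = ", ")))
  issues <- character()
  fk <- function(child, col, parent, pcol) {
    dangling <- setdiff(tables[[child]][[col]], tables[[parent]][[pcol]])
    if (length(dangling))
      issues <<- c(issues, sprintf("%s.%s -> %s.%s dangling: %s", child, col,
                                   parent, pcol,
                                   paste(dangling, collapse = ", ")))
  }
  fk("variants", "combination_id", "combinations", "combination_id")
  fk("variants", "gene_symbol", "genes", "gene_symbol")
  fk("references", "combination_id", "combinations", "combination_id")
  fk("combinations", "gene_combination_id", "gene_combinations",
     "gene_combination_id")
  fk("combinations", "disease_name", "diseases", "disease_name")
  issues
}

.escapeField <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.unescapeField <- function(x) {
  # token-wise so that escaped backslashes do not re-trigger
  vapply(x, function(s) {
    parts <- strsplit(s, "\\\\", fixed = TRUE)[[1]]
    if (length(parts) == 0L) parts <- ""
    parts <- gsub("\\t", "\t", parts, fixed = TRUE)
    parts <- gsub("\\n", "\n", parts, fixed = TRUE)
    paste(parts, collapse = "\\")
  }, character(1), USE.NAMES = FALSE)
}

.formatCol <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v)
      if (is.na(v)) ""
      else format(v, scientific = FALSE, trim = TRUE, digits = 15),
      character(1))
    out
  } else .escapeField(.chr(x))
}

#' Write / read the entity tables
#'
#' `writeTables()` serializes the six tables with a canonical layout:
#' fixed column order, rows sorted by primary key, UTF-8, header row, tab
#' separation with tabs/newlines/backslashes escaped inside fields (TSV
#' format), or a single JSON object of six row arrays (JSON format).
#' Output is bit-stable given identical input. `readTables()` is the
#' inverse on its image; both refuse table sets with dangling keys.
#'
#' @param tables list of six entity tables, as from [entityTables()].
#' @param destination directory (TSV: six files `<table>.tsv`) or file
#'   path (JSON).
#' @param format `"tsv"` or `"json"`.
#' @return `writeTables` invisibly returns the paths written;
#'   `readTables` returns the table list.
#' @export
writeTables <- function(tables, destination, format = c("tsv", "json")) {
  format <- match.arg(format)
  issues <- checkIntegrity(tables)
  if (length(issues))
    stop("referential integrity violated: ", paste(issues, collapse = "; "))
  if (format == "json") {
    payload <- lapply(stats::setNames(nm = .ENTITY_NAMES),
                      function(nm) tables[[nm]])
    jsonlite::write_json(payload, destination, dataframe = "rows",
                         na = "null", digits = NA, pretty = TRUE)
    return(invisible(destination))
  }
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(.ENTITY_NAMES, function(nm) {
    df <- tables[[nm]]
    schema <- .ENTITY_SCHEMA[[nm]]
    cells <- lapply(schema$cols, function(cc) .formatCol(df[[cc]]))
    lines <- c(paste(schema$cols, collapse = "\t"),
               if (nrow(df)) do.call(paste, c(cells, sep = "\t")))
    path <- file.path(destination, paste0(nm, ".tsv"))
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname writeTables
#' @param source directory (TSV) or file (JSON) produced by
#'   [writeTables()].
#' @export
readTables <- function(source, format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- if (format == "json") {
    payload <- jsonlite::read_json(source, simplifyVector = TRUE)
    lapply(stats::setNames(nm = .ENTITY_NAMES), function(nm) {
      schema <- .ENTITY_SCHEMA[[nm]]
      df <- payload[[nm]]
      if (is.null(df) || length(df) == 0L || nrow(as.data.frame(df)) == 0L)
        return(entityTables(list())[[nm]])
      df <- as.data.frame(df, stringsAsFactors = FALSE)
      for (cc in schema$cols) {
        if (!cc %in% names(df))
          df[[cc]] <- if (cc %in% schema$num) NA_real_ else ""
        df[[cc]] <- if (cc %in% schema$num) as.numeric(df[[cc]])
        else .chr(df[[cc]])
      }
      df[, schema$cols, drop = FALSE]
    })
  } else {
    lapply(stats::setNames(nm = .ENTITY_NAMES), function(nm) {
      path <- file.path(source, paste0(nm, ".tsv"))
      if (!file.exists(path))
        stop("missing entity table file: ", path)
      lines <- readLines(path, encoding = "UTF-8")
      header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
      schema <- .ENTITY_SCHEMA[[nm]]
      body <- lines[-1]
      cells <- lapply(seq_along(body), function(i) {
        f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
        # trailing empty fields are dropped by strsplit; pad them back
        length(f) <- length(header)
        f[is.na(f)] <- ""
        if (length(f) != length(header))
          stop(sprintf("%s line %d: expected %d fields", path, i + 1L,
                       length(header)))
        f
      })
      df <- as.data.frame(
        stats::setNames(lapply(seq_along(header), function(j)
          vapply(cells, `[[`, character(1), j)), header),
        stringsAsFactors = FALSE)
      if (nrow(df) == 0L)
        df <- as.data.frame(stats::setNames(
          lapply(header, function(cc) character()), header))
      for (cc in names(df)) {
        df[[cc]] <- if (cc %in% schema$num)
          suppressWarnings(as.numeric(df[[cc]]))
        else .unescapeField(df[[cc]])
      }
      # unknown columns are preserved as opaque annotations, after the
      # canonical ones
      known <- intersect(schema$cols, names(df))
      extra <- setdiff(names(df), schema$cols)
      for (cc in setdiff(schema$cols, names(df)))
        df[[cc]] <- if (cc %in% schema$num) NA_real_ else ""
      df[, c(schema$cols, extra), drop = FALSE]
    })
  }
  class(out) <- c("entityTables", "list")
  issues <- checkIntegrity(out)
  if (length(issues))
    stop("referential integrity violated: ", paste(issues, collapse = "; "))
  out
}

#' Serialize a curation corpus (records and entries) as JSON
#'
#' Evidence records carry nested payloads (pedigrees, experiment
#' descriptors) that do not fit the flat entity tables, so a corpus is
#' exchanged as one JSON document with `records` and `entries` arrays.
#' `readCorpus()` is the inverse of `writeCorpus()`.
#'
#' @param records list of [EvidenceRecord-class] objects.
#' @param entries list of [CombinationEntry-class] objects.
#' @param path output / input file path.
#' @return `writeCorpus` invisibly returns `path`; `readCorpus` returns
#'   `list(records = , entries = )`.
#' @export
writeCorpus <- function(records, entries, path) {
  recList <- lapply(records, function(r) list(
    combination_id = r@combinationId, article_id = r@articleId,
    article_year = r@articleYear, curator_id = r@curatorId,
    pedigree = r@pedigree@relatives,
    statistical = list(
      source = r@statistical@source, explicit = r@statistical@explicit,
      size_sufficient = r@statistical@sizeSufficient,
      ethnicity_matched = r@statistical@ethnicityMatched,
      phenotypes_known = r@statistical@phenotypesKnown,
      sequencing_similar = r@statistical@sequencingSimilar,
      combination_absent = r@statistical@combinationAbsent,
      shared_variant_support = I(r@statistical@sharedVariantSupport)),
    gene_functional = list(
      experiment_design = r@geneFunctional@experimentDesign,
      experiment_outcome = r@geneFunctional@experimentOutcome,
      relationship_types = I(r@geneFunctional@relationshipTypes),
      phenotype_relevance_shown = r@geneFunctional@phenotypeRelevanceShown),
    variant_functional = list(
      experiment_design = r@variantFunctional@experimentDesign,
      experiment_outcome = r@variantFunctional@experimentOutcome,
      all_predicted_pathogenic = r@variantFunctional@allPredictedPathogenic,
      mixed_experiment_and_prediction =
        r@variantFunctional@mixedExperimentAndPrediction,
      insilico_joint_effect_clear =
        r@variantFunctional@insilicoJointEffectClear,
      negative_result_present = r@variantFunctional@negativeResultPresent)))
  entList <- lapply(entries, function(e) list(
    combination_id = e@combinationId, disease_name = e@diseaseName,
    disease_id = e@diseaseId, references = e@references,
    variants = lapply(e@variants, function(v) list(
      local_id = v@localId, gene_symbol = v@geneSymbol,
      raw_symbol = v@rawSymbol, notation = v@notation,
      coordinates = v@coordinates, variant_class = v@variantClass,
      cnv_detail = v@cnvDetail, zygosity = v@zygosity,
      coordinate_flag = v@coordinateFlag))))
  jsonlite::write_json(list(records = recList, entries = entList), path,
                       auto_unbox = TRUE, na = "null", digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  asChr <- function(x) vapply(x, as.character, character(1))
  records <- lapply(doc$records, function(r) {
    ped <- r$pedigree
    EvidenceRecord(
      r$combination_id, r$article_id,
      articleYear = if (is.null(r$article_year)) NA_integer_
      else as.integer(r$article_year),
      curatorId = r$curator_id,
      pedigree = PedigreeEvidence(
        degree = asChr(lapply(ped, `[[`, "degree")),
        phenotype = asChr(lapply(ped, `[[`, "phenotype")),
        genotype = asChr(lapply(ped, `[[`, "genotype"))),
      statistical = ControlEvidence(
        source = r$statistical$source,
        explicit = r$statistical$explicit,
        sizeSufficient = r$statistical$size_sufficient,
        ethnicityMatched = r$statistical$ethnicity_matched,
        phenotypesKnown = r$statistical$phenotypes_known,
        sequencingSimilar = r$statistical$sequencing_similar,
        combinationAbsent = r$statistical$combination_absent,
        sharedVariantSupport =
          asChr(r$statistical$shared_variant_support)),
      geneFunctional = GeneFunctionalEvidence(
        experimentDesign = r$gene_functional$experiment_design,
        experimentOutcome = r$gene_functional$experiment_outcome,
        relationshipTypes = asChr(r$gene_functional$relationship_types),
        phenotypeRelevanceShown =
          r$gene_functional$phenotype_relevance_shown),
      variantFunctional = VariantFunctionalEvidence(
        experimentDesign = r$variant_functional$experiment_design,
        experimentOutcome = r$variant_functional$experiment_outcome,
        allPredictedPathogenic =
          r$variant_functional$all_predicted_pathogenic,
        mixedExperimentAndPrediction =
          r$variant_functional$mixed_experiment_and_prediction,
        insilicoJointEffectClear =
          r$variant_functional$insilico_joint_effect_clear,
        negativeResultPresent =
          r$variant_functional$negative_result_present))
  })
  entries <- lapply(doc$entries, function(e) {
    variants <- lapply(e$variants, function(v)
      Variant(v$local_id, v$gene_symbol, notation = v$notation,
              rawSymbol = v$raw_symbol,
              coordinates = if (length(v$coordinates)) v$coordinates,
              variantClass = v$variant_class,
              cnvDetail = if (length(v$cnv_detail)) v$cnv_detail,
              zygosity = v$zygosity, coordinateFlag = v$coordinate_flag))
    refs <- if (length(e$references))
      data.frame(articleId = asChr(lapply(e$references, `[[`, "articleId")),
                 year = vapply(e$references, function(x)
                   as.integer(x$year), integer(1)),
                 stringsAsFactors = FALSE)
    else data.frame(articleId = character(), year = integer())
    CombinationEntry(e$combination_id, variants,
                     diseaseName = e$disease_name,
                     diseaseId = if (is.null(e$disease_id)) NA_character_
                     else e$disease_id,
                     references = refs)
  })
  list(records = records, entries = entries)
}
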