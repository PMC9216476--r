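# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as direct transcriptions of the scoring rule tables,
# separate from the package's implementation paths.

# Hand-transcribed functional tree: rows = gene level 0..3, cols = var 0..3.
FUN_TABLE_ORACLE <- matrix(
  c(0, 0, 0, 0,
    0, 1, 2, 2,
    0, 2, 2, 2,
    0, 2, 2, 3),
  nrow = 4, byrow = TRUE, dimnames = list(gene = 0:3, var = 0:3))

# Hand-transcribed final tree: rows = genetic level max(fam, stat) 0..3,
# cols = fun 0..3.
FINAL_TABLE_ORACLE <- matrix(
  c(0, 0, 0, 0,
    0, 1, 1, 2,
    0, 1, 2, 3,
    0, 1, 2, 3),
  nrow = 4, byrow = TRUE, dimnames = list(genetic = 0:3, fun = 0:3))

# Statistical manual rule, transcribed independently: weak needs implicit
# absence with a quality-checked control set; explicit checking upgrades to
# moderate; nothing reaches strong.
oracleStatistical <- function(source, explicit, sizeSufficient,
                              ethnicityMatched, phenotypesKnown,
                              combinationAbsent) {
  ok <- source != "none" && combinationAbsent && sizeSufficient &&
    ethnicityMatched && phenotypesKnown
  if (!ok) 0L else if (explicit) 2L else 1L
}

# Every ControlEvidence state over source x the five gating/explicit flags.
enumerateControlStates <- function() {
  grid <- expand.grid(
    source = c("none", "public_db", "cohort"),
    explicit = c(FALSE, TRUE), sizeSufficient = c(FALSE, TRUE),
    ethnicityMatched = c(FALSE, TRUE), phenotypesKnown = c(FALSE, TRUE),
    sequencingSimilar = c(FALSE, TRUE), combinationAbsent = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  # the type invariant pins all flags FALSE when there is no control set
  keep <- grid$source != "none" |
    (!grid$explicit & !grid$sizeSufficient & !grid$ethnicityMatched &
       !grid$phenotypesKnown & !grid$sequencingSimilar &
       !grid$combinationAbsent)
  grid[keep, , drop = FALSE]
}

controlFromState <- function(st) {
  ControlEvidence(source = st$source, explicit = st$explicit,
                  sizeSufficient = st$sizeSufficient,
                  ethnicityMatched = st$ethnicityMatched,
                  phenotypesKnown = st$phenotypesKnown,
                  sequencingSimilar = st$sequencingSimilar,
                  combinationAbsent = st$combinationAbsent)
}

# Gene functional manual rule, transcribed independently from the rule table.
oracleGeneManual <- function(design, outcome, rels, relevance) {
  strong <- design == "single_and_joint" &&
    outcome == "synergistic_or_additive"
  jointEffect <- design != "none" &&
    outcome %in% c("synergistic_or_additive", "effect_shown")
  direct <- relevance && length(intersect(
    rels, c("same_pathway", "directly_interacting",
            "same_protein_complex"))) > 0
  weak <- relevance && length(intersect(
    rels, c("relevant_pathways_for_phenotype",
            "affecting_same_tissue"))) > 0
  score <- if (strong) 3L else if (jointEffect || direct) 2L
  else if (weak) 1L else 0L
  if (outcome == "negative") score <- min(score, 1L)
  score
}

# Variant functional manual rule, transcribed independently.
oracleVariantManual <- function(design, outcome, allPred, mixed, insilico,
                                negative) {
  strong <- design == "single_and_joint" &&
    outcome == "synergistic_or_additive"
  moderate <- (design != "none" &&
                 outcome %in% c("synergistic_or_additive",
                                "effect_shown")) || insilico
  weak <- allPred || mixed ||
    (design == "single_units_only" && outcome == "promising_inconclusive")
  score <- if (strong) 3L else if (moderate) 2L else if (weak) 1L else 0L
  if (negative) score <- min(score, 1L)
  score
}

# Brute-force reachability: is the undirected graph over `genes` connected
# when restricted to the given edges?
oracleConnected <- function(genes, edgeA, edgeB) {
  if (length(genes) == 0L) return(FALSE)
  reached <- genes[1]
  repeat {
    hit <- (edgeA %in% reached & !(edgeB %in% reached)) |
      (edgeB %in% reached & !(edgeA %in% reached))
    if (!any(hit)) break
    reached <- union(reached, c(edgeA[hit], edgeB[hit]))
  }
  length(setdiff(genes, reached)) == 0L
}

# Store in which every gene is known via an irrelevant pathway row, so the
# gene knowledge score is 2 iff the qualifying edges connect the genes, and
# 0 otherwise.
connectivityStore <- function(genes, edges) {
  AnnotationStore(
    ppiEdges = edges,
    pathways = data.frame(gene = genes,
                          pathwayId = paste0("PW_", seq_along(genes)),
                          phenotypeRelevant = FALSE))
}

# A small scored record built from target levels via the level realizers.
recordFromLevels <- function(cid, article, fam = 0L, stat = 0L, gene = 0L,
                             var = 0L) {
  EvidenceRecord(cid, article,
                 pedigree = pedigreeForLevel(fam),
                 statistical = controlForLevel(stat),
                 geneFunctional = geneEvidenceForLevel(gene),
                 variantFunctional = variantEvidenceForLevel(var))
}
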