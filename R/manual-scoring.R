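#' @include constructors.R
NULL

# Informative relatives and segregation status for a pedigree.
.pedigreeFacts <- function(p) {
  rel <- p@relatives
  inf <- rel[rel$phenotype != "unknown" & rel$genotype != "unknown", ,
             drop = FALSE]
  violation <-
    (inf$genotype == "full_carrier" & inf$phenotype == "healthy") |
    (inf$genotype %in% c("non_carrier", "partial_carrier") &
       inf$phenotype == "affected")
  list(
    informative = inf,
    perfect = nrow(inf) > 0L && !any(violation),
    nFirst = sum(inf$degree == "first"),
    nSecond = sum(inf$degree == "second"),
    healthyFirst = sum(inf$degree == "first" & inf$phenotype == "healthy"),
    healthySecond = sum(inf$degree == "second" & inf$phenotype == "healthy"))
}

#' Familial evidence score
#'
#' Grades pedigree segregation evidence on the 0-3 scale. A relative is
#' informative iff both phenotype and genotype are known; segregation is
#' perfect iff every informative full carrier is affected and every
#' informative non- or partial carrier is healthy (a healthy partial
#' carrier — a relative carrying only part of the combination — is
#' consistent with the oligogenic model).
#'
#' Levels: 3 when informative *healthy* relatives exist at both first and
#' second degree and segregation is perfect; 2 when two or more informative
#' first-degree relatives segregate perfectly, or segregation is imperfect
#' but informative relatives span both degrees; 1 when exactly one
#' informative healthy first-degree relative is described, or segregation
#' is imperfect with two or more informative first-degree relatives; 0
#' otherwise (in particular, a single affected genotyped relative alone
#' scores 0).
#'
#' @param p a [PedigreeEvidence-class].
#' @return integer level 0-3.
#' @export
scoreFamilial <- function(p) {
  f <- .pedigreeFacts(p)
  if (nrow(f$informative) == 0L)
    return(0L)
  if (f$healthyFirst >= 1L && f$healthySecond >= 1L && f$perfect)
    return(3L)
  if ((f$nFirst >= 2L && f$perfect) ||
      (!f$perfect && f$nFirst >= 1L && f$nSecond >= 1L))
    return(2L)
  if (f$healthyFirst == 1L || (!f$perfect && f$nFirst >= 2L))
    return(1L)
  0L
}

#' Statistical evidence score
#'
#' Grades article-level statistical evidence on the 0-2 scale; 2 is the
#' ceiling for this class of evidence. Any score requires absence of the
#' combination from a control set with known phenotypes, sufficient size
#' and matched ethnicity; explicit absence checking raises weak (implicit)
#' to moderate. Similar sequencing technology is recorded but does not gate
#' the score, and shared-variant context flags never raise it.
#'
#' @param c a [ControlEvidence-class].
#' @return integer level 0-2.
#' @export
scoreStatistical <- function(c) {
  if (c@source == "none" || !c@combinationAbsent || !c@sizeSufficient ||
      !c@ethnicityMatched || !c@phenotypesKnown)
    return(0L)
  if (c@explicit) 2L else 1L
}

.DIRECT_RELATIONSHIPS <- c("same_pathway", "directly_interacting",
                           "same_protein_complex")
.WEAK_RELATIONSHIPS <- c("relevant_pathways_for_phenotype",
                         "affecting_same_tissue")

#' Gene-combination functional evidence score
#'
#' Grades article-level functional evidence for the gene combination:
#' 3 for a synergistic or additive effect shown with both single and joint
#' gene knockouts; 2 for an effect of the combination shown experimentally
#' short of demonstrated synergy (e.g. only a joint knockout, or only
#' single knockouts), or a direct gene relationship (same pathway, direct
#' interaction, same protein complex) relevant to the phenotype; 1 for
#' phenotype-relevant pathway or tissue-expression links only; 0 otherwise.
#' A negative experimental outcome caps the score at 1 (relevance may
#' remain; synergy is contradicted).
#'
#' @param g a [GeneFunctionalEvidence-class].
#' @return integer level 0-3.
#' @export
scoreGeneManual <- function(g) {
  base <- if (g@experimentDesign == "single_and_joint" &&
              g@experimentOutcome == "synergistic_or_additive") 3L
  else if ((g@experimentDesign != "none" &&
            g@experimentOutcome %in% c("effect_shown",
                                       "synergistic_or_additive")) ||
           (any(g@relationshipTypes %in% .DIRECT_RELATIONSHIPS) &&
            g@phenotypeRelevanceShown)) 2L
  else if (any(g@relationshipTypes %in% .WEAK_RELATIONSHIPS) &&
           g@phenotypeRelevanceShown) 1L
  else 0L
  if (g@experimentOutcome == "negative") min(base, 1L) else base
}

#' Variant-combination functional evidence score
#'
#' Grades article-level functional evidence for the variant combination:
#' 3 for a synergistic or additive effect with single and multiple variant
#' mutants; 2 for an experimentally shown effect short of demonstrated
#' synergy, or a clear in silico joint effect; 1 when all variants are
#' predicted pathogenic, experiments and predictions are mixed, or single
#' mutants gave promising but inconclusive results; 0 otherwise. A reported
#' negative result caps the score at 1.
#'
#' @param v a [VariantFunctionalEvidence-class].
#' @return integer level 0-3.
#' @export
scoreVariantManual <- function(v) {
  base <- if (v@experimentDesign == "single_and_joint" &&
              v@experimentOutcome == "synergistic_or_additive") 3L
  else if ((v@experimentDesign != "none" &&
            v@experimentOutcome %in% c("effect_shown",
                                       "synergistic_or_additive")) ||
           v@insilicoJointEffectClear) 2L
  else if (v@allPredictedPathogenic || v@mixedExperimentAndPrediction ||
           (v@experimentDesign == "single_units_only" &&
            v@experimentOutcome == "promising_inconclusive")) 1L
  else 0L
  if (v@negativeResultPresent) min(base, 1L) else base
}

#' Manual score vector for one evidence record
#'
#' Applies the four component scorers to one curator record.
#'
#' @param r an [EvidenceRecord-class].
#' @return a [ManualScores-class].
#' @seealso [scoreFamilial()], [scoreStatistical()], [scoreGeneManual()],
#'   [scoreVariantManual()].
#' @export
scoreManual <- function(r) {
  ManualScores(fam = scoreFamilial(r@pedigree),
               stat = scoreStatistical(r@statistical),
               gene = scoreGeneManual(r@geneFunctional),
               var = scoreVariantManual(r@variantFunctional))
}
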