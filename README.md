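# oligoscore

Confidence scoring for oligogenic variant combinations.

Monogenic variant interpretation has mature, rule-based curation frameworks;
combinations of variants in two or more genes that jointly cause or modulate
a disease do not. `oligoscore` implements a transparent curation engine for
such combinations, aimed at biocurators and statistical geneticists who need
reproducible, auditable confidence levels rather than ad hoc judgement:
structured evidence in, integer evidence scores and decision-tree aggregates
out, with corpus-level harmonization, reporting, and a synthetic fixture
generator for testing.

## The scoring model

Every score is an integer level: **0 Absent, 1 Weak, 2 Moderate, 3 Strong**.

**Manual scores** grade the evidence found in a combination's source
article(s):

* `FAMmanual` (0–3) — pedigree segregation. A relative is *informative* when
  both phenotype and genotype are known; segregation is *perfect* when every
  informative full carrier of the combination is affected and every
  informative non-carrier or partial carrier is healthy (a healthy partial
  carrier is consistent with the oligogenic model). Strong requires perfect
  segregation with informative healthy relatives at both first and second
  degree.
* `STATmanual` (0–2) — absence of the combination from a quality-checked
  control set (known phenotypes, sufficient size, matched ethnicity);
  explicit absence checking gives 2, implicit gives 1. Two is the ceiling:
  cohort controls cannot match a pedigree's environmental control.
* `GENEmanual` / `VARmanual` (0–3) — functional evidence for the gene
  combination and the variant combination; 3 requires synergistic or
  additive effects shown with both single and joint knockouts/mutants, and a
  negative experimental result caps the score at 1.

**Knowledge scores** recompute what local annotation tables support:
`STATknowledge` (0–1) from reference population-panel presence plus
per-variant clinical relevance; `GENEknowledge` (0–2) from protein–protein
interaction edges (confidence strictly > 0.8) and phenotype-relevant pathway
sharing; `VARknowledge` (0–1) from pathogenicity predictor calls (CADD Phred
≥ 15, SIFT deleterious, MutationTaster2 disease-causing, PolyPhen-2
possibly/probably damaging). A knowledge score is *unassigned* — distinct
from 0 — when any unit of the combination has no table entry.

**Aggregation.** Per combination, manual scores are merged across articles
by component-wise maximum and each gene combination receives the highest
gene score seen for it anywhere in the corpus (`GENEmanual_harmonized`).
Metascores take the per-evidence maximum of manual and knowledge scores,
with one override: a combination present in the population panel has
`STATmeta = 0` regardless of its manual score. Two decision trees — shipped
as flat, auditable lookup tables — derive the functional aggregate
`FUN = tree(GENE, VAR)` and the overall confidence
`FINAL = tree(genetic, FUN)` with `genetic = max(FAM, STAT)`; both a genetic
and a functional leg are required for any final score.

## Worked example

```r
library(oligoscore)
wx <- workedExamples()          # three packaged fixtures + annotation TSVs
scores <- scorePipeline(wx$records, wx$entries, wx$store)
scoresTable(scores)
```

```
  combination_id fam stat gene var gene_harmonized fun_manual final_manual
1         OLI606   2    0    3   3               3          3            3
2         OLI474   0    1    2   1               2          2            1
3         OLI302   1    0    3   3               3          3            2
  kstat kgene kvar stat_meta gene_meta var_meta fun_meta final_meta
1     0     1    1         0         3        3        3          3
2     1     2    1         1         2        1        2          1
3     1     2    1         1         3        3        3          2
                kstat_reason
1 clinical_relevance_missing
2                   assigned
3                   assigned
```

`OLI606` is a trigenic left-ventricular-noncompaction combination: moderate
familial evidence (segregation spans both degrees but is not shown complete)
plus strong gene- and variant-level synergy from a triple-mutant mouse model
yield `final_meta = 3`. `OLI474` (congenital hypothyroidism) has no familial
evidence, weak statistics (implicit matched-cohort absence, confirmed by
panel absence and clinical relevance), moderate functional evidence (shared
thyroid-hormone-synthesis process, no synergy experiments), hence
`final_meta = 1`. `OLI302` shows the knowledge route supplying the
statistical leg (`stat_meta = 1` from panel absence plus relevance) under
strong functional synergy (`fun_meta = 3`).

A thin command-line wrapper is installed at
`system.file("scripts", "oligoscore", package = "oligoscore")` with
subcommands `validate`, `score`, `report`, `fixtures`, `trees` and
`examples`.

## Package layout

* `R/` — S4 evidence model, manual/knowledge scorers, decision trees,
  aggregation pipeline, entity-table I/O, reporting, synthetic generator.
* `inst/extdata/worked_examples/` — annotation tables of the packaged
  fixtures (plain TSV).
* `vignettes/oligogenic-confidence-scoring.Rmd` — the methods vignette:
  model assumptions, thresholds, numerical choices, generator design and
  limitations.
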