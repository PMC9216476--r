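---
title: "Scoring the evidence behind oligogenic variant combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the evidence behind oligogenic variant combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscore)
```

## The problem

A growing share of genetic disease is attributed to *oligogenic* variant
combinations: variants in two or more genes whose joint presence causes or
modulates a phenotype. The digenic special case ranges from "true digenic"
(both variants required for any symptoms) to "monogenic plus modifier"
(one driver gene, one severity/onset modifier). Evidence for such claims is
heterogeneous — pedigrees, control cohorts, knockout experiments, predictor
output — and papers differ wildly in which parts they prove. `oligoscore`
turns that heterogeneity into a small set of integer confidence levels with
explicit, auditable rules, so that combinations curated from different
articles become comparable.

All scores share one scale: 0 = Absent, 1 = Weak, 2 = Moderate, 3 = Strong.
Evidence below the weakest rule threshold scores 0; there are no fractional
levels, because the inputs are categorical curator judgements, not
measurements.

## The evidence model

A *combination entry* links a combination accession to its variants
(SNV/indel/CNV, each with a gene symbol, free-text notation and optional
genomic coordinates), its disease, and its source references; its derived
canonical gene key (upper-cased, sorted symbols) identifies the gene
combination. A combination is identified by its exact multiset of variants:
two combinations sharing a variant remain distinct entities, each requiring
its own evidence. An *evidence record* holds one curator's structured
reading of one article: pedigree observations, control-cohort descriptors,
and gene- and variant-level experiment descriptors. Two independent records
for the same (combination, article) pair are compared field-wise by
`reconcileCurations()`; conflicts are reported for discussion, never
auto-resolved, since no defensible automatic tie-break exists for
subjective curation differences.

CNVs are represented as explicit (start, end, deletion/duplication) blocks
with 1-based inclusive coordinates — literature notation for CNVs in
oligogenic reports follows no usable standard, so the package defines its
own minimal one. Variants with resolvable genomic coordinates are flagged
`mapped`, the rest `unmapped`, with `manual_review` reserved as a curator
override; no liftover or HGVS validation is attempted (out of scope; use
dedicated tooling upstream).

## Manual scores and their edge cases

**Familial (0–3).** Only relatives with known phenotype *and* genotype are
informative. Perfection of segregation is consistency: informative full
carriers must be affected; informative non-carriers must be healthy. A
*healthy partial carrier* (carrying part of the combination) supports the
oligogenic model rather than contradicting it, so it does not break
perfection; an *affected* partial carrier does. One consequence deserves
note: a pedigree whose only informative relative is a single affected full
carrier is perfectly consistent yet scores 0 — one affected relative alone
demonstrates nothing about joint necessity, and the weak level explicitly
requires either a healthy genotyped first-degree relative or an imperfect
pedigree with at least two informative first-degree relatives.

**Statistical (0–2).** Any non-zero score requires absence of the
combination from a control set whose phenotypes are known, whose size the
curator judged sufficient, and whose ethnicity matched the patients. These
are curator-supplied booleans, not computed thresholds — no defensible
numeric cutoff exists across study designs. Similar sequencing technology
is recorded for reporting but does not gate the moderate level
("preferably" similar, not "necessarily"). Flags describing variants shared
with other combinations (modifier role, dominant role, severity modifier)
are admissible context only next to a real absence result and never raise
the score by themselves.

**Gene / variant functional (0–3).** The strong level is deliberately
narrow: synergy or additivity demonstrated with *both* single-unit and
joint experiments. An effect shown with any experimental design short of
that is moderate, as is a phenotype-relevant direct gene relationship (same
pathway, direct interaction, same protein complex) or a clear in silico
joint effect. Pathway/tissue relevance alone, all-variants-predicted-
pathogenic, mixed experiment-plus-prediction, or promising-but-inconclusive
single-unit results are weak. A negative experimental result caps the score
at 1 rather than zeroing it: relevance may survive a failed synergy
experiment, but synergy itself is contradicted. The cap value is a design
choice; the rule set only fixes that negatives must "negatively impact"
the level.

One rule interaction was resolved during design: the moderate branch
accepts any non-`none` experimental design with an effect shown, including
single-and-joint designs whose outcome fell short of synergy. Restricting
it to joint-only/single-only designs would make the score drop when a
curator upgrades the recorded design with the same outcome, violating the
monotonicity property the scorers are tested against.

## Knowledge scores

Knowledge scores recompute evidence from local annotation tables —
population-panel membership per combination (the joint genotype, not the
individual variants), clinical relevance per variant, interaction edges
with confidences, pathway memberships with a curated phenotype-relevance
boolean, and per-variant predictor calls. The tables emulate the public
resources a production deployment would consult; the package never queries
anything remote, which keeps scoring deterministic and testable.

Two thresholds matter, with deliberate boundary semantics:

* interaction confidence: an edge qualifies when confidence is **strictly
  greater than** 0.8 — an edge at exactly 0.8 does not count;
* CADD Phred: a call is pathogenic when the value is **at least** 15 — the
  threshold value itself passes.

`GENEknowledge = 2` requires the qualifying edges to connect *all* genes of
the combination (one connected component), or all genes to share one
phenotype-relevant pathway; for combinations of more than two genes the
common-pathway reading is all-genes-common, not pairwise. Both defaults
live in `scoringConfig()` and are printed by `writeTreeTables()` alongside
the decision trees.

A knowledge score is **unassigned** when any unit of the combination lacks
a table entry. Unassigned is not 0: the metascore falls back to the manual
score. The only knowledge 0 that overrides a manual score is statistical 0
with reason `present_in_population_panel` — observing the joint genotype in
a healthy reference individual actively contradicts the article's
statistical claim, so `STATmeta` is forced to 0.

## Decision trees

The functional tree and the final tree are stored as flat lookup tables
(16 rows each) inside the configuration, so they can be dumped, diffed and
replaced wholesale; `funTree()` and `finalTree()` only consult the table.
The defaults encode:

```{r trees}
cfg <- scoringConfig()
xtabs(fun ~ gene + var, cfg@funTable)
xtabs(final ~ genetic + fun, cfg@finalTable)
```

Functional strength demands strength on *both* the gene and the variant
side; either side absent zeroes the aggregate. The final tree's genetic leg
is `max(FAM, STAT)`; both legs must be non-zero for any final score, strong
requires strong functional evidence with at least moderate genetic
evidence, and the (genetic = 1, functional = 3) cell — pinned by no worked
example — was set to 2: strong functional synergy with only weak genetic
support warrants moderate, not strong, overall confidence. Both trees are
monotone non-decreasing in each argument, verified exhaustively.

Whether the manual-only final aggregate should use the corpus-harmonized
gene score or the raw per-article one is genuinely ambiguous; the package
uses the harmonized score for both the manual and the meta aggregate, since
harmonization is described as triggering recalculation of all affected
aggregates.

## The synthetic generator

`generateCorpus()` works *backwards* from sampled target levels to evidence
payloads — a constructive inverse of each scoring rule — rather than
sampling raw evidence and hoping every branch is hit. Each level with
multiple realizing branches picks one at random, so repeated generation
covers the whole rule table; `generateStore()` likewise plants knowledge
outcomes, including threshold-boundary values (confidence exactly 0.8,
CADD exactly 15) at a configurable rate. The planted truth table is the
exact expected output of the pipeline, and the core generator test asserts
zero mismatches.

Default conditions model a literature-curation corpus: 79% digenic
combinations with a tail to five genes, 6.8% of combinations carrying a
CNV, most variants carrying at least one pathogenic predictor call
(`kvar = 1` at 65%), joint population-panel presence rare (10%), and 15% of
combinations split over two articles. Manual-level distributions
(e.g. familial 45/20/20/15% over levels 0–3) were chosen once to exercise
all levels with a realistic skew toward absent/weak evidence. Each
synthetic combination receives a unique gene set, so corpus-level gene
harmonization cannot mix planted scores between combinations — real
corpora do share gene pairs, and that path is tested separately with
hand-built fixtures.

What the generator does *not* emulate: real sequences, allele frequencies
or genome coordinates (placeholders only), curator disagreement, free-text
evidence, or correlated evidence types (a real pedigree paper is likelier
to also report functional work). Passing the planted-recovery test
therefore shows the engine inverts its own rules faithfully — it says
nothing about how well the rules capture any particular article.

## Numerical and testing choices

All scores are integers; there is no floating-point tolerance anywhere in
the scoring path. Serialization is canonical (fixed column order, primary-
key row sort, escaped TSV, UTF-8) so that write–read–write is byte-stable
and diffs are meaningful. The test suite enumerates the statistical
evidence space exhaustively (129 valid states), checks both trees against
independently hand-transcribed tables on every input tuple, verifies graph
connectivity against a brute-force reachability oracle on random graphs of
up to six genes, and runs planted-score recovery on corpora of 200 and
1000 combinations plus a 5000-combination frequency check of the level
distributions — sizes chosen to keep the whole suite under a minute while
making every branch's failure visible.

## Limitations

* The rule tables grade evidence *presence and design*, not effect sizes;
  a well-powered cohort and a marginal one both satisfy "sufficient size"
  if the curator says so.
* Knowledge scores are only as good as the local annotation tables;
  `oligoscore` deliberately has no live-database path.
* Dual-curator reconciliation stops at a field diff; consensus is a human
  step.
* The decision trees are reconstructions constrained by the documented
  worked examples and level semantics; the table-driven design exists
  precisely so a richer tree can replace them without code changes.
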