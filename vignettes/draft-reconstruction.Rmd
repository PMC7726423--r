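---
title: "Homology-based draft reconstruction of genome-scale metabolic models"
author: "gemdraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based draft reconstruction of genome-scale metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemdraft)
```

## The problem

A genome-scale metabolic model (GEM) assembles an organism's metabolic
reactions, their stoichiometry and compartmentalization, and
gene-protein-reaction (GPR) Boolean rules linking reactions to the genes
whose products catalyze them.  For well-studied species a draft GEM can be
generated from organism-specific biochemical databases.  For a non-model
species with a young or fragmented genome annotation, no such databases
exist; the practicable route is *homology transfer*: pick a curated
template GEM from a related (or functionally analogous) organism, map the
target species' proteins onto the template's genes by reciprocal protein
search, and carry over every reaction for which orthologous enzymes exist.
The motivating use case is a liver model of a non-model teleost fish
drafted from a curated human hepatocyte GEM; the mechanics are generic.

This vignette describes the model of each pipeline stage, the parameters
that matter, the numerical conventions, and what the synthetic fixtures do
and do not establish.

## Ortholog mapping

The input is the standard 12-column tabular output of a protein search run
in both directions (target proteome against template proteome and back).
Three alignment-quality thresholds gate every decision:

| parameter | meaning                        | unit      | default |
|-----------|--------------------------------|-----------|---------|
| `maxE`    | maximum acceptable E-value     | —         | 1e-30   |
| `minLen`  | minimum alignment length       | residues  | 200     |
| `minIde`  | minimum percent identity       | %         | 40      |

All three boundaries are **inclusive**: the stated maximum E-value is
itself acceptable, as are alignments of exactly 200 residues or exactly
40% identity.  "Maximum acceptable" naturally includes the named value;
inclusive boundaries also make the predicate monotone in each threshold,
which the property tests rely on.

A search may emit several high-scoring pairs (HSPs) for one query/subject
combination; they are first collapsed to the single representative with the
lowest E-value (ties: higher bit score).  Mapping then proceeds under one
of three strictness regimes:

* **strictness 1** — a pair (target gene *t*, template gene *g*) is
  accepted when a threshold-passing hit exists in *both* directions.  One
  template gene may acquire several target orthologs (one-to-many), which
  is biologically expected for lineages with an extra whole-genome
  duplication, but also inflates counts through splice variants and
  assembly artifacts.
* **strictness 2** — a passing hit in *at least one* direction suffices.
  The loosest regime.  The phrase "in one direction" is read permissively
  ("at least one"), which makes the regimes nest; this reading is stated
  prominently here because tools differ on it.
* **strictness 3** — classic best reciprocal hits: each direction is first
  reduced to the best (lowest-E-value) hit per query; a pair is accepted
  when the two best hits point at each other *and both pass the
  thresholds*.  The result is an injective partial matching in both
  directions (one-to-one).

Two deliberate decisions at strictness 3: thresholds are applied *after*
best-hit selection, so a best hit that fails them kills the pair rather
than promoting the runner-up (promotion would accept evidence the search
itself ranked second); and E-value ties break by higher bit score, then
lexicographically smaller subject id, making the mapping deterministic.
An E-value printed as `0.0` (underflow) ranks as the strongest possible
evidence.

For fixed inputs the accepted pair sets nest: strictness 3 ⊆ 1 ⊆ 2.
Relaxing any threshold can only grow the strictness-1/2 maps.  Both
properties are enforced by tests against a brute-force oracle that
evaluates the three predicates literally over every gene pair.

## Draft extraction and GPR rewriting

A template reaction enters the draft when **at least one gene of its
original GPR is mapped**.  The inclusion test deliberately uses the
original template rule: an enzyme complex with only some subunits mapped is
still carried over, because absence of the other subunits from a draft
annotation is weak evidence of true absence.  GPR-less reactions
(spontaneous, transport, exchange) are excluded by default — homology
offers no evidence for them — and re-enter through gap curation, or
wholesale via `includeNonGeneReactions = TRUE`.

Kept reactions get their rule rewritten onto target genes under one of two
policies:

* `or_of_orthologs` (default) — the rewritten rule is a flat OR over all
  target orthologs of any gene in the rule.  This matches the inclusion
  rule's semantics (any mapped enzyme suffices) and avoids asserting
  complex stoichiometry that homology cannot confirm.
* `preserve_logic` — each leaf becomes an OR of its orthologs; a leaf with
  no ortholog is deleted; an AND node that loses any child becomes empty
  (strict complex semantics).  Provided for users who prefer conservative
  complexes; both policies include exactly the same reactions.

Stoichiometry, bounds, compartments and subsystem labels are copied
verbatim, so a draft is always a substructure of its template.  The
extractor also returns a mapped-gene report (template gene → orthologs →
reactions carried), which is the right currency for comparing drafts built
from different genome annotations: reaction counts hide one-to-many
inflation, mapped template genes do not.  `genePartition()` turns several
reports into exact Venn region sizes, and `mergeDrafts()` combines a
baseline draft (typically from the most complete annotation) with
complementary ones.  Merging is id-based, baseline-priority and
order-dependent on the complement list; shared reactions union their GPRs,
and conflicting stoichiometry for a shared id is an error because
template-derived drafts cannot honestly disagree.

## GPR rules: grammar and canonical form

Rules use case-insensitive `and`/`or` with parentheses; gene ids are
maximal runs of non-whitespace, non-parenthesis characters; there is no
NOT (absent from GEM practice).  Parsed trees are normalized: nested
same-operator nodes are flattened, duplicate children dropped, single-child
nodes collapsed, and children ordered lexicographically by their serialized
text.  Canonical ordering makes serialized models diffable and tests
deterministic; normalization is semantics-preserving (verified by
truth-table tests) and `parse(serialize(e))` is the identity on normal
forms.

## Model I/O

Models read and write as SBML Level 3 Version 1 with the
flux-balance-constraints (fbc) package for gene products and flux bounds,
and as COBRA-style JSON (entities keyed by id, stoichiometry as
metabolite→coefficient maps) for hand-written fixtures.  Older
HMR-lineage SBML files predate uniform fbc usage and store rules in notes
(`GENE_ASSOCIATION: ...`); the reader falls back to parsing those, and
carries subsystem labels through `SUBSYSTEM:` notes either way.  Entity
ids are written with the conventional `R_`/`M_`/`G_`/`C_` prefixes
(non-SId characters escaped as `__<code>__`); a prefix is stripped on
reading only when every id of that class carries it, so foreign ids that
genuinely start with such a prefix are not mangled silently.  A reversible
flag maps to bounds (−1000, 1000) versus (0, 1000), the standard GEM
convention.  Referential integrity is enforced on every read and
construction — a dangling metabolite, compartment or gene reference raises
an error listing the offenders, never a silent repair.

## Gap analysis and curation

`subsystemDiff()` classifies every template reaction of one subsystem as
`auto` (in the draft) or `missing`.  Curation is driven by declarative
rules rather than ad hoc edits, for reproducibility: a `spontaneous` rule
includes a reaction that proceeds without enzymatic catalysis (empty GPR);
a `family` rule includes a reaction whose chemistry clearly implicates an
enzyme family — e.g. a cytochrome P450 monooxygenation — under a
family-level placeholder gene.  Placeholders carry a `putative` flag so
downstream users can always separate them from homology-derived genes.
The four statuses (`auto`, `filled_spontaneous`, `filled_family`,
`missing`) partition the subsystem before and after curation; curation
never removes or modifies `auto` reactions and is idempotent.
`exportReactionStates()` writes the partition as CSV and as an
Escher-loadable reaction-data JSON (auto = 1, spontaneous = 2, family = 3,
missing = 0) for coloring a pathway map.

## Expression overlay

Gene-level differential-expression calls (id, log2 fold change,
significance flag) project onto reactions through the GPRs: a reaction is
`up` when all significant genes in its rule move up, `down` when all move
down, `mixed` otherwise, `none` when no significant measured gene appears
(GPR-less reactions are always `none`).  The default score aggregation
`max_abs` keeps the signed value of the largest-magnitude responder —
branch-level reasoning in toxicology typically follows the strongest
responder (e.g. an induced activation enzyme versus repressed conjugation
enzymes); `mean` is available.  Mixed states are reported, not resolved;
the intended resolution level is the route: `routeSummary()` tallies
states over named reaction sets so an activation branch can be contrasted
with a clearance branch.  Significance is taken from the caller:
differential-expression testing is upstream of this tool.

## The fixture generator

`fixtureSpec()`/`makeTemplate()`/`makeHomology()`/`makeExpression()`
generate the full input chain deterministically from a seed.  The template
is a connected linear pathway (an extracellular substrate chased through a
cytosolic metabolite chain) over two compartments, split into named
subsystems with a controlled mixture of single-gene, isoenzyme (OR),
complex (AND) and gene-less reactions.  Homology tables plant a known set
of ortholog pairs as strong reciprocal hits (E ≤ 1e-40, identity ≥ 60%,
length ≥ 250 — comfortably inside the default thresholds) and add decoys
of two kinds: hits failing at least one default threshold, and hits that
pass but exist in one direction only.  Every decoy is strictly weaker
(higher E-value) than any planted hit sharing its query, so strictness-3
recovery of the planted truth is exact *by construction* — that is the
point: the fixtures test the mapping semantics, not alignment biology.

Accordingly, passing fixture tests shows that the strictness predicates,
the inclusion rule, the rewriting policies and the bookkeeping are
implemented exactly; it does **not** show that real draft models are
biologically complete.  Real proteomes bring paralog families with
near-tied E-values, splice-variant redundancy, fragmented peptides below
`minLen`, and template/annotation id drift — phenomena the generator
deliberately omits (it emulates their decision-relevant effects, controlled
E-value/identity/length patterns, not their sequence-level causes).

Default generator conditions: 30 template genes, 40 target genes, 60% of
template genes with a planted ortholog, 40 reactions in 4 subsystems, 10%
gene-less reactions, 30% complexes.  The test suite runs the
strictness-oracle comparison on 200 random table pairs (up to 10×10 genes,
40 hits each) and the round-trip properties on 100 random rules; the
acceptance script uses a 50-reaction, 40×55-gene instance with 30 decoys.
These sizes exercise every code path with comfortable margins while
keeping the whole suite fast enough to run habitually.

## Known limitations

* One template organism at a time; multi-template reconciliation is out of
  scope.
* No flux balance analysis, mass/charge balancing or biomass objective —
  drafting ends where constraint-based analysis begins.
* No automated (optimization-based) gap filling; curation is declarative
  and user-supplied.
* Orthology is sequence-similarity-based only; no synteny or tree-aware
  methods.
* SBML support targets the fbc and notes dialects described above, not
  every historical SBML level/version combination.
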