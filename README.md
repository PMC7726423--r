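# gemdraft

Template-based draft reconstruction of genome-scale metabolic models
(GEMs) in R.

## The problem

For a non-model species with a sparse genome annotation, a metabolic
reconstruction cannot be bootstrapped from organism-specific biochemical
databases.  The practicable alternative is homology transfer: take a
curated template GEM from a well-studied organism (for example, a human
hepatocyte model when the goal is a fish liver model), map the target
species' proteins onto the template's genes by reciprocal protein search
(BLASTp), and carry over every template reaction supported by an
orthologous enzyme.  `gemdraft` implements that workflow for
bioinformaticians building first drafts for less-annotated organisms:

* **Ortholog mapping** from 12-column tabular search output under three
  strictness regimes, with thresholds *maxE* (maximum E-value, default
  10⁻³⁰), *minLen* (minimum alignment length, default 200 residues) and
  *minIde* (minimum identity, default 40%), all boundaries inclusive:
  * *s1* — a passing hit in both directions (one-to-many allowed),
  * *s2* — a passing hit in at least one direction,
  * *s3* — best reciprocal hits: per query keep only the lowest-E-value
    hit; accept (t, g) iff t's best hit is g, g's best hit is t, and both
    pass the thresholds (one-to-one).

  For fixed inputs, pairs(s3) ⊆ pairs(s1) ⊆ pairs(s2).
* **Draft extraction**: a template reaction is kept iff ≥ 1 gene of its
  original GPR (gene–protein–reaction Boolean rule, `and` = complex
  subunits, `or` = isoenzymes) is mapped; rules are rewritten onto target
  genes (`or_of_orthologs` or strict `preserve_logic`); a mapped-gene
  report supports Venn comparison (`genePartition()`) and baseline-priority
  merging (`mergeDrafts()`) of drafts from different genome annotations.
* **Gap analysis and curation**: per-subsystem `auto`/`missing`
  classification against the template, declarative curation rules
  (spontaneous reactions; enzyme-family placeholder assignments), and an
  Escher-compatible reaction-state export for pathway-map coloring.
* **Expression overlay**: project differential-expression calls through
  GPRs to classify reactions as up/down/mixed and contrast pathway
  branches (`routeSummary()`).
* **Model I/O** in SBML Level 3 (+ fbc, with a notes-field fallback for
  HMR-lineage files) and COBRA-style JSON; proteome FASTA and BLAST
  tabular I/O; a deterministic fixture generator with planted ground
  truth.

## Worked example

```r
library(gemdraft)

spec <- fixtureSpec(seed = 42, nTemplateGenes = 30, nTargetGenes = 40,
                    plantedFraction = 0.6, decoyHits = 10, nReactions = 40)
template <- makeTemplate(spec)
template
#> GEModel 'toy_template_seed42': 40 reactions, 41 metabolites, 30 genes, 2 compartments, 4 subsystems

hom <- makeHomology(spec)   # reciprocal tables + planted ground truth
map <- mapOrthologs(hom$fwd, hom$rev, mappingParams(strictness = 3))
map
#> OrthologMap: 18 pairs (18 target genes, 18 template genes), strictness=3
```

18 of the 30 template genes (the planted 60%) get a best-reciprocal
ortholog; the 10 decoy hits are all rejected.  Extract the draft:

```r
draft <- extractDraft(template, map)
draft$model
#> GEModel 'toy_template_seed42_draft': 26 reactions, 36 metabolites, 18 genes, 1 compartments, 4 subsystems
head(draft$report, 3)
#>   template_gene orthologs n_orthologs n_reactions
#> 1          h001      t007           1           2
#> 2          h002      t025           1           2
#> 3          h004      t014           1           2
```

26 of 40 template reactions carry at least one mapped enzyme.  Gap-analyze
the cytochrome P450 xenobiotics subsystem and fill one gap as a
spontaneous reaction:

```r
gr <- subsystemDiff(template, draft$model,
                    "Metabolism of xenobiotics by cytochrome P450")
gr
#> GapReport for subsystem 'Metabolism of xenobiotics by cytochrome P450': 10 reactions (auto=6, filled_spontaneous=0, filled_family=0, missing=4)

rules <- curationRules(
  spontaneous = gapStates(gr)$reaction_id[gapStates(gr)$status == "missing"][1])
cur <- applyCuration(gr, rules, template, draft$model)
gapSummary(cur$report)
#>               auto filled_spontaneous      filled_family            missing
#>                  6                  1                  0                  3
```

Overlay a differential-expression experiment (one induced gene, two
repressed) on the draft:

```r
expr <- makeExpression(spec, draft$model,
                       upGenes = modelGenes(draft$model)$id[1],
                       downGenes = modelGenes(draft$model)$id[2:3])
reg <- overlayExpression(draft$model, expr)
table(reg$state)
#> down none   up
#>    4   20    2
```

Two reactions are catalyzed (solely or redundantly) by the induced gene
and classify as `up`; four follow the repressed genes `down`; the rest
have no significant gene in their rule.

A thin command-line front end over the same functions is installed at
`system.file("cli/gemdraft.R", package = "gemdraft")` with subcommands
`stats`, `lengths`, `map`, `build`, `compare`, `merge`, `gaps`, `overlay`
and `fixtures`.

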