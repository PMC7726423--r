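Package: gemdraft
Title: Template-Based Draft Genome-Scale Metabolic Reconstruction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building draft genome-scale metabolic models (GEMs)
    of less-annotated species by protein homology against a curated template
    model: reciprocal-BLAST ortholog mapping under three strictness regimes,
    template-reaction extraction with gene-protein-reaction (GPR) Boolean
    rule rewriting, draft statistics and multi-annotation comparison,
    per-subsystem gap analysis driven by declarative curation rules, and
    overlay of differential gene expression onto the reconstructed network.
    Includes SBML (Level 3 with flux-balance-constraints gene associations)
    and COBRA-style JSON model input/output, BLAST tabular homology parsing,
    and a deterministic synthetic-fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Metabolomics, SystemsBiology, NetworkInference
RoxygenNote: 7.3.3
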