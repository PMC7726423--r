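## Shared in-code fixtures for the test suite.

hitRow <- function(q, s, e = 1e-50, ide = 80, len = 250L, bit = 500) {
  len <- as.integer(len)
  data.frame(query_id = q, subject_id = s, percent_identity = ide,
             alignment_length = len, mismatches = 0L, gap_opens = 0L,
             q_start = 1L, q_end = len, s_start = 1L, s_end = len,
             e_value = e, bit_score = bit, stringsAsFactors = FALSE)
}

homTable <- function(..., direction = "target_to_template") {
  rows <- list(...)
  hits <- if (length(rows)) do.call(rbind, rows) else
    gemdraft:::emptyHits()
  HomologyTable(hits, direction = direction)
}

## Minimal hand-built model: 3 reactions, 4 metabolites, 2 genes, 1
## compartment, 2 subsystems.
toyModel <- function() {
  GEModel("toy",
    compartments = data.frame(id = "c", name = "cytosol"),
    genes = data.frame(id = c("g1", "g2")),
    metabolites = data.frame(id = c("A", "B", "C", "D"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2", "R3"),
                           subsystem = c("S1", "S1", "S2"),
                           gpr = c("g1", "g1 and g2", "")),
    stoichiometry = list(R1 = c(A = -1, B = 1),
                         R2 = c(B = -1, C = 1),
                         R3 = c(C = -1, D = 1)))
}

## Random GPR expression tree over a gene pool; may return NULL (empty).
randomGpr <- function(genes, depth = 3L, pEmpty = 0) {
  if (stats::runif(1) < pEmpty) return(NULL)
  build <- function(d) {
    if (d == 0L || stats::runif(1) < 0.4) return(sample(genes, 1L))
    op <- sample(c("and", "or"), 1L)
    n <- sample(2:3, 1L)
    args <- lapply(seq_len(n), function(i) build(d - 1L))
    structure(list(op = op, args = args), class = "gpr_node")
  }
  build(depth)
}

## Random reciprocal homology table pair over small gene universes, with
## duplicate HSPs and occasional E-value ties to exercise tie-breaking.
randomHomologyPair <- function(nTarget = 8L, nTemplate = 8L, nHits = 30L) {
  tgt <- sprintf("t%02d", seq_len(nTarget))
  tpl <- sprintf("h%02d", seq_len(nTemplate))
  randTable <- function(qs, ss, direction) {
    rows <- lapply(seq_len(nHits), function(i) {
      e <- 10^-sample(0:60, 1L)   # integer exponents create ties
      hitRow(sample(qs, 1L), sample(ss, 1L), e = e,
             ide = stats::runif(1, 20, 100),
             len = sample(50:500, 1L),
             bit = sample(seq(50, 800, by = 10), 1L))
    })
    HomologyTable(do.call(rbind, rows), direction = direction)
  }
  list(fwd = randTable(tgt, tpl, "target_to_template"),
       rev = randTable(tpl, tgt, "template_to_target"))
}

pairKey <- function(df) paste(df$target, df$template, sep = "\r")

expectSamePairs <- function(got, want) {
  expect_setequal(pairKey(got), pairKey(want))
}
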