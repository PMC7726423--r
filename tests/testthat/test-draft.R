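mapOf <- function(...) {
  pairs <- do.call(rbind, lapply(list(...), function(p)
    data.frame(target = p[1], template = p[2], stringsAsFactors = FALSE)))
  if (is.null(pairs)) pairs <- data.frame(target = character(0),
                                          template = character(0))
  pairs
}

test_that("rewriteGpr maps leaves onto orthologs", {
  map <- mapOf(c("c1", "h1"), c("c3", "h3"))
  e <- parseGpr("h1 or h3")
  expect_identical(serializeGpr(rewriteGpr(e, map, "or_of_orthologs")),
                   "c1 or c3")
  expect_identical(serializeGpr(rewriteGpr(e, map, "preserve_logic")),
                   "c1 or c3")
  expect_null(rewriteGpr(e, mapOf()))
  expect_null(rewriteGpr(parseGpr(""), map))
})

test_that("an unmapped AND subunit empties the rule under preserve_logic only", {
  map <- mapOf(c("c1", "h1"))
  e <- parseGpr("h1 and h2")
  expect_identical(serializeGpr(rewriteGpr(e, map, "or_of_orthologs")), "c1")
  expect_null(rewriteGpr(e, map, "preserve_logic"))
  ## emptiness is dropped from OR but propagates through AND
  e2 <- parseGpr("(h1 and h2) or h1")
  expect_identical(serializeGpr(rewriteGpr(e2, map, "preserve_logic")), "c1")
})

test_that("preserve_logic agrees with a truth-table oracle", {
  set.seed(51)
  templates <- sprintf("h%d", 1:5)
  targets <- sprintf("c%d", 1:7)
  for (i in 1:30) {
    n <- sample(0:6, 1L)
    map <- unique(data.frame(target = sample(targets, n, replace = TRUE),
                             template = sample(templates, n, replace = TRUE),
                             stringsAsFactors = FALSE))
    e <- gemdraft:::normalizeGpr(randomGpr(templates, depth = 2L))
    r <- rewriteGpr(e, map, "preserve_logic")
    ## oracle: under every target-gene presence assignment, the rewritten
    ## rule must equal the original evaluated with each template gene
    ## considered present iff one of its orthologs is present AND it has
    ## orthologs at all
    for (j in 1:10) {
      present <- sample(targets, sample(0:7, 1L))
      tplPresent <- templates[vapply(templates, function(h) {
        orth <- map$target[map$template == h]
        length(orth) > 0 && any(orth %in% present)
      }, logical(1L))]
      want <- gemdraft:::evalGpr(e, tplPresent)
      got <- gemdraft:::evalGpr(r, present)
      if (is.na(want) || is.na(got)) {
        ## empty rules: both sides must be empty together only when the
        ## original was empty; a rewritten-away rule means "cannot be
        ## satisfied", so the original must evaluate FALSE
        if (is.na(got) && !is.na(want)) expect_false(want)
      } else {
        expect_identical(got, want)
      }
    }
  }
})

test_that("extractDraft keeps reactions with at least one mapped enzyme", {
  tpl <- GEModel("tpl",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = c("h1", "h2")),
    metabolites = data.frame(id = c("A", "B", "C", "D"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2", "R3"),
                           gpr = c("h1", "h2", "")),
    stoichiometry = list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1),
                         R3 = c(C = -1, D = 1)))
  d <- extractDraft(tpl, mapOf(c("c1", "h1")))
  expect_identical(modelReactions(d$model)$id, "R1")
  expect_identical(modelGenes(d$model)$id, "c1")
  expect_identical(d$report$template_gene, "h1")
  expect_identical(d$report$orthologs, "c1")
  expect_identical(d$report$n_reactions, 1L)

  d2 <- extractDraft(tpl, mapOf(c("c1", "h1")),
                     includeNonGeneReactions = TRUE)
  expect_setequal(modelReactions(d2$model)$id, c("R1", "R3"))

  ## inclusion tests the ORIGINAL rule: a partially mapped complex is kept
  tpl2 <- GEModel("tpl2",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = c("h1", "h2")),
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = "R1", gpr = "h1 and h2"),
    stoichiometry = list(R1 = c(A = -1, B = 1)))
  for (mode in c("or_of_orthologs", "preserve_logic")) {
    d3 <- extractDraft(tpl2, mapOf(c("c1", "h1")), gprMode = mode)
    expect_identical(modelReactions(d3$model)$id, "R1")
    expect_identical(modelReactions(d3$model)$gpr,
                     if (mode == "or_of_orthologs") "c1" else "")
  }
})

test_that("extractDraft warns on unknown template ids and errors on GPR-less templates", {
  tpl <- toyModel()
  expect_warning(
    d <- extractDraft(tpl, mapOf(c("c1", "g1"), c("cX", "ghost"))),
    "absent from the template")
  expect_setequal(modelReactions(d$model)$id, c("R1", "R2"))

  bare <- GEModel("bare",
    compartments = data.frame(id = "c"),
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = "R1", gpr = ""),
    stoichiometry = list(R1 = c(A = -1, B = 1)))
  expect_error(suppressWarnings(extractDraft(bare, mapOf(c("c1", "h1")))),
               "includeNonGeneReactions")
})

test_that("drafts are substructures of their template", {
  spec <- fixtureSpec(seed = 61, nReactions = 30L, decoyHits = 8L)
  tpl <- makeTemplate(spec)
  hom <- makeHomology(spec)
  for (s in 1:3) {
    map <- mapOrthologs(hom$fwd, hom$rev, mappingParams(strictness = s))
    d <- extractDraft(tpl, map)$model
    expect_true(all(modelReactions(d)$id %in% modelReactions(tpl)$id))
    expect_true(all(modelMetabolites(d)$id %in% modelMetabolites(tpl)$id))
    expect_true(all(modelCompartments(d)$id %in% modelCompartments(tpl)$id))
    expect_true(all(modelReactions(d)$subsystem %in%
                      modelReactions(tpl)$subsystem))
    for (rid in modelReactions(d)$id)
      expect_identical(modelStoichiometry(d)[[rid]],
                       modelStoichiometry(tpl)[[rid]])
    ## every draft gene occurs in a GPR; every metabolite in a reaction
    gprGeneSet <- unique(unlist(lapply(modelReactions(d)$gpr,
                                       function(g) gprGenes(parseGpr(g)))))
    expect_setequal(modelGenes(d)$id, gprGeneSet)
    usedMets <- unique(unlist(lapply(modelStoichiometry(d), names)))
    expect_setequal(modelMetabolites(d)$id, usedMets)
  }
})

test_that("a larger ortholog map never yields fewer draft reactions", {
  spec <- fixtureSpec(seed = 62, nReactions = 30L)
  tpl <- makeTemplate(spec)
  hom <- makeHomology(spec)
  map2 <- mapOrthologs(hom$fwd, hom$rev, mappingParams(strictness = 2))
  map3 <- mapOrthologs(hom$fwd, hom$rev, mappingParams(strictness = 3))
  d2 <- extractDraft(tpl, map2)$model
  d3 <- extractDraft(tpl, map3)$model
  expect_true(all(modelReactions(d3)$id %in% modelReactions(d2)$id))
})

test_that("both gpr modes include exactly the same reactions", {
  spec <- fixtureSpec(seed = 63, nReactions = 30L, fractionComplex = 0.5)
  tpl <- makeTemplate(spec)
  hom <- makeHomology(spec)
  map <- mapOrthologs(hom$fwd, hom$rev, mappingParams(strictness = 3))
  dOr <- extractDraft(tpl, map, gprMode = "or_of_orthologs")$model
  dPl <- extractDraft(tpl, map, gprMode = "preserve_logic")$model
  expect_identical(modelReactions(dOr)$id, modelReactions(dPl)$id)
})

test_that("genePartition computes exact Venn regions", {
  p <- genePartition(list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2"))
  expect_identical(p[["A"]], 1L)
  expect_identical(p[["B"]], 1L)
  expect_identical(p[["C"]], 0L)
  expect_identical(p[["A&B&C"]], 1L)
  expect_identical(p[["A&B"]], 0L)
  expect_identical(p[["A&C"]], 0L)
  expect_identical(p[["B&C"]], 0L)
  expect_identical(sum(p), 3L)   # regions sum to |union|

  same <- genePartition(list(X = c("a", "b"), Y = c("a", "b")))
  expect_identical(same[["X&Y"]], 2L)
  expect_identical(same[["X"]] + same[["Y"]], 0L)

  expect_error(genePartition(list(A = "g1")), "at least two")

  set.seed(64)
  for (i in 1:10) {
    sets <- list(A = sample(sprintf("g%02d", 1:40), 30L),
                 B = sample(sprintf("g%02d", 1:40), 30L),
                 C = sample(sprintf("g%02d", 1:40), 30L))
    got <- genePartition(sets)
    want <- oracleVenn(sets)
    for (nm in names(want)) expect_identical(got[[nm]], want[[nm]])
    expect_identical(sum(got), length(unique(unlist(sets))))
  }
})

test_that("mergeDrafts keeps the baseline and adds complements in order", {
  base <- GEModel("base",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = "c1"),
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = "R1", gpr = "c1"),
    stoichiometry = list(R1 = c(A = -1, B = 1)))
  comp <- GEModel("comp",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = "c2"),
    metabolites = data.frame(id = c("A", "B", "C"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2"), gpr = c("c2", "c2")),
    stoichiometry = list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)))

  m <- mergeDrafts(base, list(gadMor1 = comp))
  expect_setequal(modelReactions(m$model)$id, c("R1", "R2"))
  expect_identical(
    m$sources$source[m$sources$entity == "reaction" & m$sources$id == "R2"],
    "gadMor1")
  ## shared reaction: GPR union
  expect_identical(
    modelReactions(m$model)$gpr[modelReactions(m$model)$id == "R1"],
    "c1 or c2")

  ## disjoint drafts: union, stats additive
  baseStats <- modelStats(base)
  compOnly <- GEModel("other",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = "c9"),
    metabolites = data.frame(id = c("X", "Y"), compartment = "c"),
    reactions = data.frame(id = "R9", gpr = "c9"),
    stoichiometry = list(R9 = c(X = -1, Y = 1)))
  mm <- mergeDrafts(base, list(x = compOnly))$model
  expect_identical(modelStats(mm)$n_reactions,
                   baseStats$n_reactions + 1L)
  expect_identical(modelStats(mm)$n_metabolites,
                   baseStats$n_metabolites + 2L)

  ## conflicting stoichiometry is an error
  bad <- GEModel("bad",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = "c2"),
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = "R1", gpr = "c2"),
    stoichiometry = list(R1 = c(A = -2, B = 1)))
  expect_error(mergeDrafts(base, list(y = bad)), "conflicting stoichiometry")
})
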