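test_that("modelStats counts entity sets and distinct subsystems", {
  empty <- GEModel("empty")
  expect_identical(unclass(modelStats(empty)),
                   list(n_genes = 0L, n_reactions = 0L, n_metabolites = 0L,
                        n_compartments = 0L, n_subsystems = 0L))
  st <- modelStats(toyModel())
  expect_identical(st$n_genes, 2L)
  expect_identical(st$n_reactions, 3L)
  expect_identical(st$n_metabolites, 4L)
  expect_identical(st$n_compartments, 1L)
  expect_identical(st$n_subsystems, 2L)
})

test_that("modelStats is invariant under entity reordering", {
  m <- toyModel()
  perm <- GEModel(modelId(m),
                  compartments = modelCompartments(m),
                  genes = modelGenes(m)[2:1, ],
                  metabolites = modelMetabolites(m)[c(3, 1, 4, 2), ],
                  reactions = modelReactions(m)[c(2, 3, 1), ],
                  stoichiometry = modelStoichiometry(m)[c("R2", "R3", "R1")])
  expect_identical(modelStats(perm), modelStats(m))
})

test_that("referential integrity is rejected, not repaired", {
  expect_error(GEModel("bad",
    compartments = data.frame(id = "c"),
    metabolites = data.frame(id = "A", compartment = "c"),
    reactions = data.frame(id = "R1"),
    stoichiometry = list(R1 = c(A = -1, ghost = 1))),
    "unknown metabolite")
  expect_error(GEModel("bad",
    compartments = data.frame(id = "c"),
    metabolites = data.frame(id = "A", compartment = "nowhere"),
    reactions = data.frame(id = "R1"),
    stoichiometry = list(R1 = c(A = -1))),
    "compartment")
  expect_error(GEModel("bad",
    compartments = data.frame(id = "c"),
    metabolites = data.frame(id = "A", compartment = "c"),
    reactions = data.frame(id = "R1", gpr = "gX"),
    stoichiometry = list(R1 = c(A = -1))),
    "unknown gene")
  expect_error(GEModel("bad",
    compartments = data.frame(id = "c"),
    metabolites = data.frame(id = c("A", "A"), compartment = "c")),
    "duplicate metabolite")
})

sbmlRoundTrip <- function(m) {
  f <- tempfile(fileext = ".xml")
  on.exit(unlink(f))
  writeGEM(m, f)
  readGEM(f)
}

jsonRoundTrip <- function(m) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeGEM(m, f)
  readGEM(f)
}

expectStructurallyEqual <- function(got, want) {
  expect_identical(modelStats(got), modelStats(want))
  expect_setequal(modelReactions(got)$id, modelReactions(want)$id)
  gi <- match(modelReactions(want)$id, modelReactions(got)$id)
  expect_identical(modelReactions(got)$gpr[gi], modelReactions(want)$gpr)
  expect_identical(modelReactions(got)$subsystem[gi],
                   modelReactions(want)$subsystem)
  expect_equal(modelReactions(got)$lower[gi], modelReactions(want)$lower)
  expect_equal(modelReactions(got)$upper[gi], modelReactions(want)$upper)
  for (rid in modelReactions(want)$id) {
    sw <- modelStoichiometry(want)[[rid]]
    sg <- modelStoichiometry(got)[[rid]]
    expect_equal(sg[sort(names(sg))], sw[sort(names(sw))])
  }
}

test_that("SBML and JSON round trips preserve model structure", {
  for (seed in c(11, 12, 13)) {
    m <- makeTemplate(fixtureSpec(seed = seed, nReactions = 15L,
                                  nTemplateGenes = 12L))
    expectStructurallyEqual(sbmlRoundTrip(m), m)
    expectStructurallyEqual(jsonRoundTrip(m), m)
  }
  expectStructurallyEqual(sbmlRoundTrip(toyModel()), toyModel())
  expectStructurallyEqual(jsonRoundTrip(toyModel()), toyModel())
})

test_that("an empty model writes to a valid file with zero reactions", {
  m <- GEModel("void")
  expect_identical(modelStats(sbmlRoundTrip(m)), modelStats(m))
  expect_identical(modelStats(jsonRoundTrip(m)), modelStats(m))
})

test_that("GPR rules survive the round trip canonically", {
  m <- GEModel("gprs",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = c("a", "b", "c", "d")),
    metabolites = data.frame(id = c("X", "Y"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2"),
                           gpr = c("(a and b) or c", "d")),
    stoichiometry = list(R1 = c(X = -1, Y = 1), R2 = c(Y = -1, X = 1)))
  expect_identical(modelReactions(sbmlRoundTrip(m))$gpr,
                   c("(a and b) or c", "d"))
  expect_identical(modelReactions(jsonRoundTrip(m))$gpr,
                   c("(a and b) or c", "d"))
})

test_that("a putative gene flag survives both formats", {
  m <- GEModel("putative",
    compartments = data.frame(id = "c"),
    genes = data.frame(id = c("g1", "CYP_family"),
                       putative = c(FALSE, TRUE)),
    metabolites = data.frame(id = c("X", "Y"), compartment = "c"),
    reactions = data.frame(id = c("R1", "R2"), gpr = c("g1", "CYP_family")),
    stoichiometry = list(R1 = c(X = -1, Y = 1), R2 = c(Y = -1, X = 1)))
  for (rt in list(sbmlRoundTrip, jsonRoundTrip)) {
    g <- modelGenes(rt(m))
    expect_identical(g$putative[match(c("g1", "CYP_family"), g$id)],
                     c(FALSE, TRUE))
  }
})

test_that("a hand-written minimal SBML fixture parses", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="mini" fbc:strict="false">
  <listOfCompartments><compartment id="C_c" name="cytosol" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="M_a" compartment="C_c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
   <species id="M_b" compartment="C_c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="R_r1" reversible="true" fast="false">
    <listOfReactants><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="M_b" stoichiometry="2" constant="true"/></listOfProducts>
    <fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="G_g1"/></fbc:geneProductAssociation>
   </reaction>
   <reaction id="R_r2" reversible="false" fast="false">
    <listOfReactants><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="R_r3" reversible="false" fast="false">
    <listOfReactants><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- readGEM(f)
  expect_identical(modelStats(m)$n_reactions, 3L)
  expect_identical(modelReactions(m)$gpr, c("g1", "", ""))
  expect_equal(modelStoichiometry(m)$r1, c(a = -1, b = 2))
  expect_true(modelReactions(m)$lower[1] < 0)   # reversible flag honored
  expect_identical(modelReactions(m)$lower[2], 0)
})

test_that("gene associations stored in notes fields are understood", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="noted">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="a" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
   <species id="b" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="false" fast="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: hA or (hB and hC)</p>
      <p>SUBSYSTEM: Glycolysis</p>
    </body></notes>
    <listOfReactants><speciesReference species="a" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="b" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- readGEM(f)
  expect_identical(modelReactions(m)$gpr, "hA or (hB and hC)")
  expect_identical(modelReactions(m)$subsystem, "Glycolysis")
  expect_setequal(modelGenes(m)$id, c("hA", "hB", "hC"))
})

test_that("invalid files raise clear errors", {
  f <- tempfile(fileext = ".xml")
  writeLines("<this is not xml", f)
  expect_error(readGEM(f), "invalid SBML")
  fj <- tempfile(fileext = ".json")
  writeLines("{nope", fj)
  expect_error(readGEM(fj), "invalid JSON")
  expect_error(readGEM(tempfile(fileext = ".xml")), "no such file")
  expect_error(readGEM("model.txt"), "cannot infer")
})
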