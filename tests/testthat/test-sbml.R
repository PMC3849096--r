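test_that("SBML write/read round-trips toy models field by field", {
  for (name in c("TOY1", "TOY1-dup", "TOY1-H")) {
    m <- make_toy_model(name)
    tf <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, tf)
    m2 <- read_sbml(tf)
    expect_model_equal(m, m2)
    # write(read(write(m))) is stable too
    tf2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m2, tf2)
    expect_model_equal(m2, read_sbml(tf2))
  }
})

test_that("bounds, GPRs and metadata survive SBML", {
  m <- metabolic_model("meta",
    list(metabolite("A_e", compartment = "e"),
         metabolite("A_c", formula = "C6H12O6", charge = -2L),
         metabolite("B_c")),
    list(reaction("EX_A", c(A_e = -1), -100, 100),
         reaction("T_A", c(A_e = -1, A_c = 1), gpr = "(tA and tB) or tC"),
         reaction("CONV", c(A_c = -1, B_c = 1)),          # no GPR
         reaction("biomass_rxn", c(B_c = -1))),
    objective_id = "biomass_rxn")
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, tf)
  m2 <- read_sbml(tf)
  expect_equal(m2$reactions$EX_A$lower_bound, -100)
  expect_equal(m2$reactions$EX_A$upper_bound, 100)
  expect_identical(gpr_to_string(m2$reactions$T_A$gpr), "(tA and tB) or tC")
  expect_null(m2$reactions$CONV$gpr)
  expect_identical(m2$metabolites$A_c$formula, "C6H12O6")
  expect_identical(m2$metabolites$A_c$charge, -2L)
  expect_identical(m2$objective_id, "biomass_rxn")
  # GPR omitted from the file for the unassociated reaction only
  txt <- readLines(tf)
  expect_length(grep("geneProductAssociation", txt), 2)  # open+close for T_A
})

test_that("SBML reader rejects malformed input with informative errors", {
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml level='3'><model><unclosed>", tf)
  expect_error(read_sbml(tf))   # xml2 names the parse failure
  expect_error(read_sbml(file.path(tempdir(), "nope-missing.xml")), "not found")

  # inverted bounds must be rejected at validation
  m <- make_toy_model("TOY1")
  write_sbml(m, tf)
  txt <- readLines(tf)
  txt <- sub('id="cs_bnd_1" value="-4"', 'id="cs_bnd_1" value="200"', txt)
  writeLines(txt, tf)
  expect_error(read_sbml(tf), "lower_bound > upper_bound")

  # duplicate reaction ids
  write_sbml(m, tf)
  txt <- readLines(tf)
  i <- grep('<reaction id="RESP"', txt)
  j <- grep("</reaction>", txt); j <- min(j[j > i])
  writeLines(append(txt, txt[i:j], after = j), tf)
  expect_error(read_sbml(tf), "duplicate reaction ids")
})

test_that("an fbc-less model falls back to the unique biomass-named reaction", {
  m <- metabolic_model("fb",
    list(metabolite("A_c")),
    list(reaction("R_up", c(A_c = 1), 0, 10),
         reaction("Biomass_core", c(A_c = -1))),
    objective_id = "Biomass_core")
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, tf)
  txt <- readLines(tf)
  txt <- txt[!grepl("fbc:listOfObjectives|fbc:objective|fbc:fluxObjective|listOfFluxObjectives", txt)]
  writeLines(txt, tf)
  expect_identical(read_sbml(tf)$objective_id, "Biomass_core")
})

test_that("COBRA-style Level 2 SBML is readable", {
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    ' <model id="l2toy">',
    '  <listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>',
    '  <listOfSpecies>',
    '   <species id="A_e" compartment="e"/>',
    '   <species id="A_c" compartment="c"/>',
    '   <species id="A_b" compartment="e" boundaryCondition="true"/>',
    '  </listOfSpecies>',
    '  <listOfReactions>',
    '   <reaction id="EX_A" reversible="true">',
    '    <listOfReactants><speciesReference species="A_e"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="A_b"/></listOfProducts>',
    '    <kineticLaw><listOfParameters>',
    '     <parameter id="LOWER_BOUND" value="-4"/><parameter id="UPPER_BOUND" value="100"/>',
    '    </listOfParameters></kineticLaw>',
    '   </reaction>',
    '   <reaction id="T_A" reversible="false">',
    '    <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: gA and gB</p></body></notes>',
    '    <listOfReactants><speciesReference species="A_e"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="A_c"/></listOfProducts>',
    '   </reaction>',
    '   <reaction id="Biomass" reversible="false">',
    '    <listOfReactants><speciesReference species="A_c"/></listOfReactants>',
    '    <kineticLaw><listOfParameters>',
    '     <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '    </listOfParameters></kineticLaw>',
    '   </reaction>',
    '  </listOfReactions>',
    ' </model>',
    '</sbml>'), tf)
  m <- read_sbml(tf)
  expect_identical(m$objective_id, "Biomass")
  expect_equal(m$reactions$EX_A$lower_bound, -4)
  expect_false("A_b" %in% names(m$metabolites))   # boundary species dropped
  expect_equal(sum(build_stoich_matrix(m)[, "EX_A"] != 0), 1)
  expect_identical(gpr_to_string(m$reactions$T_A$gpr), "gA and gB")
  expect_equal(solve_fba(m)$objective_value, 4)
})
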