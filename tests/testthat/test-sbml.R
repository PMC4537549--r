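round_trip <- function(net) {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  write_sbml(net, path)
  read_sbml(path)
}

test_that("toy networks round-trip losslessly through SBML", {
  for (net in list(make_birth_death(10, 1), make_linear_chain(4, 2, 1))) {
    back <- round_trip(net)
    expect_identical(stoichiometry_matrix(net), stoichiometry_matrix(back))
    expect_equal(net$params[sort(names(net$params))],
                 back$params[sort(names(back$params))])
    expect_equal(net$species$initial_concentration,
                 back$species$initial_concentration)
    expect_equal(vapply(back$reactions, function(r) r$law$form, ""),
                 vapply(net$reactions, function(r) r$law$form, ""))
    # dynamics preserved
    tr1 <- simulate_network(net, t_end = 3)
    tr2 <- simulate_network(back, t_end = 3)
    expect_equal(tr1$conc, tr2$conc, tolerance = 1e-9)
  }
})

test_that("random network round trip preserves the registry to full precision", {
  net <- make_random_network(5, 8, 0.5, seed = 1)
  back <- round_trip(net)
  expect_identical(sort(names(net$params)), sort(names(back$params)))
  expect_identical(unname(net$params[sort(names(net$params))]),
                   unname(back$params[sort(names(net$params))]))
})

test_that("write_sbml summarizes the document and validates structure", {
  bd <- make_birth_death()
  path <- tempfile(fileext = ".xml")
  info <- write_sbml(bd, path)
  expect_equal(info$n_compartments, 1)
  expect_equal(info$n_species, 1)
  expect_equal(info$n_reactions, 2)
  expect_equal(info$level, 3)
  expect_length(info$unsupported, 0)
  doc <- xml2::read_xml(path) # well-formed XML
  expect_equal(xml2::xml_name(doc), "sbml")
})

test_that("minimal foreign SBML files load with law recognition", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mini">',
    '<listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="cell" initialConcentration="2"/>',
    '<species id="B" compartment="cell" initialConcentration="0"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="conv" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>k</ci><ci>A</ci></apply></math>',
    '<listOfParameters><parameter id="k" value="0.5"/></listOfParameters>',
    '</kineticLaw></reaction></listOfReactions>',
    '</model></sbml>'), path)
  net <- read_sbml(path)
  expect_equal(nrow(net$species), 2)
  expect_length(net$reactions, 1)
  expect_equal(net$reactions[["conv"]]$law$form, "MASS_ACTION")
  expect_equal(unname(net$params["conv.k"]), 0.5)
  # Level 2 'size' attribute and implicit stoichiometry of 1
  expect_identical(unname(stoichiometry_matrix(net)),
                   matrix(c(-1L, 1L), 2))
})

test_that("unrecognized kinetic math falls back to an opaque law", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="odd">',
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c" initialConcentration="1"/></listOfSpecies>',
    '<listOfReactions><reaction id="r" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><divide/><apply><times/><ci>v</ci><ci>A</ci><ci>A</ci></apply>',
    '<apply><plus/><ci>K</ci><apply><times/><ci>A</ci><ci>A</ci></apply></apply>',
    '</apply></math>',
    '<listOfLocalParameters><localParameter id="v" value="3"/>',
    '<localParameter id="K" value="4"/></listOfLocalParameters>',
    '</kineticLaw></reaction></listOfReactions>',
    '</model></sbml>'), path)
  net <- read_sbml(path)
  r <- net$reactions[["r"]]
  expect_equal(r$law$form, "OPAQUE")
  # Hill-type flux v*A^2/(K + A^2) evaluates through the opaque path
  expect_equal(reaction_flux(r, c(A = 2), net$params), 3 * 4 / (4 + 4),
               tolerance = 1e-12)
  # and the rhs machinery can differentiate it symbolically
  ops <- lna_operators(net, c(A = 2))
  expect_equal(unname(ops$A[1, 1]), -(2 * 3 * 2 * 4 / (4 + 4)^2),
               tolerance = 1e-10)
})

test_that("the assembled sphingolipid model survives an SBML round trip", {
  net <- build_homeostasis_model()
  back <- round_trip(net)
  expect_equal(glance(back), glance(net))
  expect_identical(stoichiometry_matrix(back), stoichiometry_matrix(net))
  expect_equal(back$params[names(net$params)], net$params)
  # kinetic-law forms (incl. inhibited MM) are recognized on re-import
  forms <- table(vapply(back$reactions, function(r) r$law$form, ""))
  expect_equal(unname(forms[["MASS_ACTION"]]), 29)
  expect_equal(unname(forms[["MICHAELIS_MENTEN"]]) +
                 unname(forms[["MM_INHIBITED"]]), 40)
})

test_that("parse failures carry informative errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines("this is not xml <", bad)
  expect_error(read_sbml(bad), "not parseable")
  notsbml <- tempfile(fileext = ".xml")
  writeLines("<foo><bar/></foo>", notsbml)
  expect_error(read_sbml(notsbml), "sbml|model")
})
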