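# Model serialization: the TSV reaction-table dialect and SBML.

model_equal <- function(a, b) {
  expect_setequal(names(a$reactions), names(b$reactions))
  for (id in names(a$reactions)) {
    expect_stoich_equal(a$reactions[[id]], b$reactions[[id]])
    expect_equal(a$reactions[[id]]$lb, b$reactions[[id]]$lb)
    expect_equal(a$reactions[[id]]$ub, b$reactions[[id]]$ub)
  }
  expect_setequal(a$species$id, b$species$id)
  expect_equal(a$biomass_id, b$biomass_id)
  expect_equal(a$gam, b$gam)
  expect_setequal(a$oxidation_ids, b$oxidation_ids)
}

test_that("a toy model round-trips through the TSV dialect", {
  m <- make_toy_autotroph(0.1, 0.05, include_oxidation_module = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table_model(m, path)
  m2 <- read_table_model(path, species_path = sub("\\.tsv$", "_species.tsv", path))
  model_equal(m, m2)
  expect_equal(sort(m2$species$molar_mass), sort(m$species$molar_mass))
})

test_that("reversible arrows in the table yield reversible bounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tequation",
               "R1\t\ta_c <=> b_c",
               "R2\t\tb_c -> c_c"), path)
  m <- read_table_model(path)
  expect_equal(m$reactions$R1$lb, -1000)
  expect_equal(m$reactions$R2$lb, 0)
})

test_that("random generated models round-trip through the TSV dialect", {
  for (seed in 1:20) {
    m <- make_random_model(n_species = sample(4:10, 1), n_reactions = sample(3:9, 1),
                           seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_table_model(m, path)
    m2 <- read_table_model(path, species_path = sub("\\.tsv$", "_species.tsv", path))
    model_equal(m, m2)
  }
})

test_that("a toy model round-trips through SBML with identical coefficients", {
  m <- make_toy_autotroph(0.12, 0.08, include_oxidation_module = TRUE,
                          include_futile_loop = TRUE)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  model_equal(m, m2)
  expect_equal(sort(m2$species$molar_mass), sort(m$species$molar_mass))
  expect_setequal(m2$exchange_ids, m$exchange_ids)
})

test_that("an empty model file reads as a model with zero reactions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tname\tequation\tlb\tub\tsubsystem\tgenes", path)
  m <- read_table_model(path)
  expect_length(m$reactions, 0)

  m0 <- metabolic_model(list(), biomass_id = NULL)
  xml <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m0, xml)
  expect_length(read_sbml(xml)$reactions, 0)
})

test_that("SBML without bounds falls back to reversibility defaults with a warning", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="legacy">',
    '    <listOfSpecies>',
    '      <species id="a_c" compartment="c"/>',
    '      <species id="b_c" compartment="c"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="R1" reversible="true">',
    '        <listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="b_c" stoichiometry="2"/></listOfProducts>',
    '      </reaction>',
    '      <reaction id="R2" reversible="false">',
    '        <listOfReactants><speciesReference species="b_c"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="a_c"/></listOfProducts>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  expect_warning(m <- read_sbml(path), "defaults")
  expect_equal(c(m$reactions$R1$lb, m$reactions$R1$ub), c(-1000, 1000))
  expect_equal(c(m$reactions$R2$lb, m$reactions$R2$ub), c(0, 1000))
  expect_equal(unname(m$reactions$R1$stoich["b_c"]), 2)
})

test_that("kinetic-law bound parameters in legacy SBML are honoured", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version1" level="2" version="1">',
    '  <model id="legacy">',
    '    <listOfSpecies><species id="a_c" compartment="c"/></listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="EX_a" reversible="true">',
    '        <listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '        <kineticLaw>',
    '          <listOfParameters>',
    '            <parameter id="LOWER_BOUND" value="-5"/>',
    '            <parameter id="UPPER_BOUND" value="7"/>',
    '          </listOfParameters>',
    '        </kineticLaw>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  m <- read_sbml(path)
  expect_equal(c(m$reactions$EX_a$lb, m$reactions$EX_a$ub), c(-5, 7))
})
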