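# SBML subset reader/writer and the base set.

fixture_file <- function(model) {
  f <- tempfile(fileext = ".xml")
  write_sbml(model, f)
  f
}

test_that("fixture models load with the expected content", {
  m <- load_sbml(fixture_file(example_model("decay")))
  expect_identical(nrow(m$species), 1L)
  expect_identical(nrow(m$quantities), 1L)
  expect_length(m$reactions, 1L)
  expect_identical(m$reactions[[1]]$id, "deg")
})

test_that("round trips reproduce every fixture model field-wise", {
  for (kind in c("decay", "conversion", "oscillator", "growth")) {
    m <- example_model(kind)
    m2 <- load_sbml(fixture_file(m))
    expect_true(mutantgraph:::models_equal(m, m2), info = kind)
    # kinetic-law math survives as an equal canonical string
    for (i in seq_along(m$reactions))
      expect_identical(format_expr(m2$reactions[[i]]$law),
                       format_expr(m$reactions[[i]]$law))
    # a written file re-loads without errors under the strict loader
    expect_no_error(load_sbml(fixture_file(m2)))
  }
})

test_that("level 2 input and initialConcentration conversion are accepted", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="conc">
    <listOfCompartments><compartment id="c" size="2"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" initialConcentration="3"/>
      <species id="Bnd" compartment="c" initialAmount="1" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfParameters><parameter id="k" value="1.5"/></listOfParameters>
    <listOfReactions>
      <reaction id="r1">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k</ci><ci>A</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(l2, f)
  m <- load_sbml(f)
  expect_equal(m$species$initial_amount[m$species$id == "A"], 6) # 3 * size 2
  bs <- base_set(m)
  expect_false("Bnd" %in% names(bs$values)) # boundary species excluded
  expect_setequal(names(bs$values), c("k", "A", "c"))
})

test_that("unsupported constructs fail loudly, never silently", {
  tpl <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="m">
    <listOfCompartments><compartment id="c" size="1"/></listOfCompartments>
    %s
  </model>
</sbml>'
  cases <- list(
    events = "<listOfEvents><event id='e'/></listOfEvents>",
    `algebraic rules` = "<listOfRules><algebraicRule><math xmlns='http://www.w3.org/1998/Math/MathML'><cn>1</cn></math></algebraicRule></listOfRules>",
    `function definitions` = "<listOfFunctionDefinitions><functionDefinition id='f'/></listOfFunctionDefinitions>")
  for (feature in names(cases)) {
    f <- tempfile(fileext = ".xml")
    writeLines(sprintf(tpl, cases[[feature]]), f)
    err <- tryCatch(load_sbml(f), mg_unsupported_feature = function(c) c)
    expect_s3_class(err, "mg_unsupported_feature")
    expect_identical(err$feature, feature)
  }
})

test_that("a kinetic law referencing an undeclared id names the culprit", {
  m <- example_model("decay")
  m$reactions[[1]]$law <- parse_expr("kX*A")
  err <- tryCatch(validate_sbml_model(m), mg_sbml_parse_error = function(c) c)
  expect_s3_class(err, "mg_sbml_parse_error")
  expect_match(conditionMessage(err), "kX")
})

test_that("base_set covers exactly the three assignable categories", {
  bs <- base_set(example_model("decay"))
  expect_equal(bs$values[["A"]], 1)
  expect_equal(bs$values[["k"]], 1)
  expect_equal(bs$values[["cell"]], 1)
  expect_identical(bs$category[["A"]], "SPECIES_INITIAL")
  expect_identical(bs$category[["k"]], "GLOBAL_QUANTITY")
  expect_identical(bs$category[["cell"]], "COMPARTMENT_SIZE")
  expect_identical(sort(names(bs$values)), sort(names(bs$category)))
  # no reaction ids
  expect_false("deg" %in% names(bs$values))

  noq <- example_model("decay")
  noq$quantities <- noq$quantities[0, , drop = FALSE]
  noq$reactions[[1]]$law <- parse_expr("A") # drop the k reference
  expect_setequal(names(base_set(noq)$values), c("A", "cell"))
})

test_that("apply_values changes values only, and rejects unknown keys", {
  m <- example_model("decay")
  m2 <- apply_values(m, c(k = 0))
  expect_equal(m2$quantities$value, 0)
  expect_equal(m2$species$initial_amount, m$species$initial_amount)
  expect_length(m2$reactions, length(m$reactions))
  expect_identical(format_expr(m2$reactions[[1]]$law),
                   format_expr(m$reactions[[1]]$law))

  expect_true(mutantgraph:::models_equal(apply_values(m, list()), m))
  expect_error(apply_values(m, c(nope = 1)), class = "mg_unknown_key")

  g <- example_model("growth") # mdt: 80 -> 150
  g2 <- apply_values(g, c(mdt = 150))
  expect_equal(g2$quantities$value[g2$quantities$id == "mdt"], 150)
  g3 <- load_sbml(fixture_file(g2)) # the exported file carries 150
  expect_equal(g3$quantities$value[g3$quantities$id == "mdt"], 150)
})

test_that("duplicate identifiers across categories are a load error", {
  m <- example_model("decay")
  m$quantities <- rbind(m$quantities,
                        data.frame(id = "A", value = 2, constant = TRUE))
  expect_error(validate_sbml_model(m), class = "mg_sbml_parse_error")
})
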