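test_that("constructors enforce domain invariants", {
  expect_error(metabolite("X", compartment = "vacuole"), "compartment")
  expect_error(metabolite("X", initial_conc = -1), "non-negative")
  expect_error(kinetic_law("MM1", c("A", "B"), vmax = 1, km = 1), "1 substrate")
  expect_error(kinetic_law("MM2", "A", vmax = 1, km_a = 1, km_b = 1),
               "2 substrates")
  expect_error(kinetic_law("MM1", "A", vmax = -1, km = 1), "vmax > 0")
  expect_error(kinetic_law("mass_action", "A", k = -0.1), "k >= 0")
  expect_error(reaction("R", "E", numeric()), "non-empty")
  expect_error(reaction("R", "E", c(A = -1)), "kinetic law is required")
  # needs_fba reactions carry no law
  r <- reaction("R", "E", c(A = -1), needs_fba = TRUE)
  expect_null(r$law)
  expect_error(reaction("R", "E", c(A = -1),
                        kinetic_law("MM1", "A", vmax = 1, km = 1),
                        needs_fba = TRUE), "must not carry")
})

test_that("validate_model reports violations without mutating the model", {
  toy <- make_thiamin_toy()
  expect_identical(nrow(validate_model(toy)), 0L)

  bad <- toy
  bad$reactions[[1L]]$stoichiometry <- c(X = -1, HMP_P = 1)
  rep1 <- validate_model(bad)
  expect_true(any(rep1$rule == "dangling_reference" & grepl("'X'", rep1$message)))

  bad2 <- toy
  bad2$metabolites[[5L]]$initial_conc <- -3
  expect_true(any(validate_model(bad2)$rule == "non_negative_c0"))

  # law substrate not consumed by the reaction
  bad3 <- toy
  bad3$reactions[[3L]]$stoichiometry <- c(HMP_P = 1, HMP_PP = 1)
  expect_true(any(validate_model(bad3)$rule == "substrate_sign"))

  # idempotent and side-effect-free
  snapshot <- unserialize(serialize(bad, NULL))
  invisible(validate_model(bad))
  invisible(validate_model(bad))
  expect_identical(bad, snapshot)
})

test_that("model tables round-trip through the documented schema", {
  toy <- make_thiamin_toy()
  dir <- withr::local_tempdir()
  write_model_tables(toy, dir)
  back <- load_model(file.path(dir, "reactions.tsv"),
                     file.path(dir, "metabolites.tsv"))
  expect_identical(n_reactions(back), n_reactions(toy))
  expect_identical(n_metabolites(back), n_metabolites(toy))
  expect_identical(metabolite_ids(back), metabolite_ids(toy))
  expect_identical(boundary_ids(back), boundary_ids(toy))
  for (i in seq_along(toy$reactions)) {
    expect_equal(back$reactions[[i]]$stoichiometry,
                 toy$reactions[[i]]$stoichiometry)
    expect_identical(back$reactions[[i]]$law$law_type,
                     toy$reactions[[i]]$law$law_type)
    expect_equal(back$reactions[[i]]$law$vmax, toy$reactions[[i]]$law$vmax)
  }
  expect_equal(initial_state(back), initial_state(toy))
})

test_that("loader reports schema violations with row context", {
  dir <- withr::local_tempdir()
  met <- file.path(dir, "metabolites.tsv")
  rxn <- file.path(dir, "reactions.tsv")
  writeLines(c("id\tname\tcompartment\tinitial_conc_nmol_per_L\tboundary",
               "A\tA\tcytosol\t1\t0", "B\tB\tcytosol\t0\t0"), met)
  header <- paste("id", "enzyme", "stoichiometry", "law_type", "vmax", "km",
                  "km_a", "km_b", "k", "substrates", "reversible", "needs_fba",
                  sep = "\t")

  # empty reaction table
  writeLines(header, rxn)
  expect_error(load_model(rxn, met), "no data rows")

  # missing column
  writeLines(c("id\tenzyme", "R1\tE"), rxn)
  expect_error(load_model(rxn, met), "missing column")

  # dangling metabolite named with its row
  writeLines(c(header,
               "R1\tE\t-1:A,+1:X\tMM1\t1\t1\t\t\t\tA\t0\t0"), rxn)
  expect_error(load_model(rxn, met), "'X'")

  # non-numeric parameter
  writeLines(c(header,
               "R1\tE\t-1:A,+1:B\tMM1\tfast\t1\t\t\t\tA\t0\t0"), rxn)
  expect_error(load_model(rxn, met), "row 1")

  # duplicate reaction id
  writeLines(c(header,
               "R1\tE\t-1:A,+1:B\tMM1\t1\t1\t\t\t\tA\t0\t0",
               "R1\tE\t-1:A,+1:B\tMM1\t1\t1\t\t\t\tA\t0\t0"), rxn)
  expect_error(load_model(rxn, met), "duplicate")

  # missing file
  expect_error(load_model(file.path(dir, "nope.tsv"), met), "not found")
})

test_that("comma-delimited tables are autodetected", {
  dir <- withr::local_tempdir()
  met <- file.path(dir, "m.csv"); rxn <- file.path(dir, "r.csv")
  writeLines(c("id,name,compartment,initial_conc_nmol_per_L,boundary",
               "A,A,cytosol,2,0", "B,B,cytosol,0,0"), met)
  # the stoichiometry token list itself uses ',', so the cell is quoted
  writeLines(c("id,enzyme,stoichiometry,law_type,vmax,km,km_a,km_b,k,substrates,reversible,needs_fba",
               "R1,E,\"-1:A,+1:B\",MM1,4,2,,,,A,0,0"), rxn)
  m <- load_model(rxn, met)
  expect_identical(n_reactions(m), 1L)
  expect_equal(m$reactions[[1L]]$stoichiometry, c(A = -1, B = 1))
})

test_that("the synthetic rice reference network matches its census", {
  m <- thiamin_reference_model()
  expect_identical(n_reactions(m), 34L)
  expect_identical(n_metabolites(m), 29L)
  expect_identical(nrow(validate_model(m)), 0L)
  # needs_fba flags and missing laws coincide exactly
  flagged <- vapply(m$reactions, `[[`, TRUE, "needs_fba")
  lawless <- vapply(m$reactions, function(r) is.null(r$law), TRUE)
  expect_identical(flagged, lawless)
  expect_true(sum(flagged) > 0L)
  # compartments span the full roster
  expect_setequal(unique(vapply(m$metabolites, `[[`, "", "compartment")),
                  c("plastid", "cytosol", "mitochondrion", "external"))
})
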