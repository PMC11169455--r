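test_that("identity folds reproduce the baseline bit-identically", {
  toy <- make_thiamin_toy()
  ident <- apply_perturbation(toy, perturbation_scenario(c(TH1 = 1)))
  expect_identical(ident$reactions, toy$reactions)
  cfg <- simulation_config(t_end = 500, n_output_points = 50)
  expect_identical(simulate_pathway(ident, cfg)$conc,
                   simulate_pathway(toy, cfg)$conc)
})

test_that("Vmax scaling touches exactly the targeted enzyme's reactions", {
  toy <- make_thiamin_toy()
  up <- apply_perturbation(toy, perturbation_scenario(c(THI1 = 100)))
  for (i in seq_along(toy$reactions)) {
    r0 <- toy$reactions[[i]]; r1 <- up$reactions[[i]]
    if (r0$enzyme == "THI1") {
      expect_identical(r1$law$vmax, r0$law$vmax * 100)
      expect_identical(r1$law$km, r0$law$km)  # Km untouched
    } else {
      expect_identical(r1, r0)
    }
  }
  # the input model is never mutated
  expect_identical(toy$reactions[[2L]]$law$vmax, 0.011)

  # bifunctional TH1: both active sites scale together
  both <- apply_perturbation(toy, perturbation_scenario(c(TH1 = 10)))
  th1 <- which(vapply(both$reactions, `[[`, "", "enzyme") == "TH1")
  expect_identical(length(th1), 2L)
  for (i in th1)
    expect_identical(both$reactions[[i]]$law$vmax,
                     toy$reactions[[i]]$law$vmax * 10)

  expect_error(apply_perturbation(toy, perturbation_scenario(c(NOPE = 2))),
               "valid labels")
})

test_that("scaling composes multiplicatively and knockout silences a sole producer", {
  toy <- make_thiamin_toy()
  ab <- apply_perturbation(apply_perturbation(toy,
          perturbation_scenario(c(TH1 = 4))), perturbation_scenario(c(TH1 = 25)))
  once <- apply_perturbation(toy, perturbation_scenario(c(TH1 = 100)))
  expect_identical(ab$reactions, once$reactions)

  # knockout of the only producer freezes the product (chain without drains)
  m <- pathway_model(
    list(metabolite("S", initial_conc = 5),
         metabolite("TMP", initial_conc = 0.7)),
    list(reaction("R1", "TH1", c(S = -1, TMP = 1),
                  kinetic_law("MM1", "S", vmax = 2, km = 1))))
  ko <- apply_perturbation(m, perturbation_scenario(c(TH1 = 0)))
  res <- simulate_pathway(ko, simulation_config(t_end = 100, n_output_points = 20))
  expect_true(all(res$conc[, "TMP"] == 0.7))
})

test_that("mass-action enzyme steps scale through k", {
  m <- influx_mm1_model()
  up <- apply_perturbation(m, perturbation_scenario(c(transport = 3)))
  expect_identical(up$reactions[[1L]]$law$k, m$reactions[[1L]]$law$k * 3)
})

test_that("raising a non-saturated enzyme's Vmax never lowers downstream flux", {
  # influx below both Vmax values; steady P-flux equals the influx, and
  # scaling E2 can only speed (never slow) the approach to it
  set.seed(13)
  for (i in 1:5) {
    ch <- make_mm_chain(2, seed = sample.int(1000, 1))
    cfg <- simulation_config(t_end = 3000, n_output_points = 100)
    base_p <- final_value(simulate_pathway(ch, cfg), "P")
    for (f in c(2, 10, 100)) {
      up <- apply_perturbation(ch, perturbation_scenario(c(E2 = f)))
      expect_gte(final_value(simulate_pathway(up, cfg), "P") - base_p, -1e-8)
    }
  }
})

test_that("standard scenario enumeration yields singles plus the combination", {
  toy <- make_thiamin_toy()
  sc <- enumerate_standard_scenarios(toy, c("THIC", "THI1", "TH1"), 100)
  expect_length(sc, 4L)
  expect_identical(lengths(lapply(sc, `[[`, "fold_changes")),
                   c(1L, 1L, 1L, 3L))
  expect_length(enumerate_standard_scenarios(toy, "TH1", 100), 1L)
  ps <- enumerate_standard_scenarios(toy, c("THIC", "THI1", "TH1"), 100,
                                     powerset = TRUE)
  expect_length(ps, 7L)  # 2^3 - 1
  expect_error(enumerate_standard_scenarios(toy, rep("TH1", 13), 2,
                                            powerset = TRUE), "12")
  expect_error(enumerate_standard_scenarios(toy, "XXX", 2), "unknown enzyme")
})

test_that("run_scan reports ranked outcomes with a baseline row", {
  toy <- make_thiamin_toy()
  scan <- run_scan(toy, enumerate_standard_scenarios(toy, c("THIC", "THI1", "TH1"),
                                                     100))
  rep <- scan$report
  expect_identical(nrow(rep), 5L)
  expect_true("baseline" %in% rep$scenario)
  expect_identical(sort(rep$rank), 1:5)
  expect_true(all(rep$ok))
  base <- rep[rep$scenario == "baseline", ]
  expect_equal(base$fold_vs_baseline, 1)
  # ranking by final concentration is descending
  expect_identical(order(rep$final, decreasing = TRUE), seq_len(5L))
})

test_that("per-scenario failures are flagged without aborting the scan", {
  toy <- make_thiamin_toy()
  scenarios <- list(
    perturbation_scenario(c(TH1 = 2), target_metabolite = "TMP"),
    perturbation_scenario(c(TH1 = 2), name = "bad target",
                          target_metabolite = "NOPE"))
  scan <- run_scan(toy, scenarios,
                   simulation_config(t_end = 100, n_output_points = 20))
  expect_identical(nrow(scan$report), 3L)
  bad <- scan$report[scan$report$scenario == "bad target", ]
  expect_false(bad$ok)
  expect_match(bad$error, "NOPE")
  expect_true(all(scan$report$ok[scan$report$scenario != "bad target"]))
})
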