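test_that("the builtin menu encodes the five interventions plus the bundle", {
  sc <- builtin_scenarios()
  expect_named(sc, c("fast_track", "extra_porter", "pharmacist_transport",
                     "early_equipment", "supplies_to_floor",
                     "all_improvements"))
  g <- build_default_graph()

  gf <- apply_scenario(g, sc$fast_track)
  expect_equal(mean(gf$activities$pharmacy_preparation$duration), 30)

  gp <- apply_scenario(g, sc$extra_porter)
  expect_equal(gp$resources$porter$capacity,
               g$resources$porter$capacity + 1L)

  gt <- apply_scenario(g, sc$pharmacist_transport)
  expect_false("porter_transport_medication" %in% names(gt$activities))
  expect_false("nurse_phone_call" %in% names(gt$activities))
  expect_null(gt$activities$pharmacist_counseling$start_offset)
  expect_true("pharmacy_preparation" %in%
                gt$activities$pharmacist_counseling$predecessors)

  ge <- apply_scenario(g, sc$early_equipment)
  expect_equal(mean(ge$activities$equipment_arrangement$duration), 0)
  # only a short handover remains on discharge day
  expect_lte(mean(ge$activities$equipment_handover$duration), 15)

  gs <- apply_scenario(g, sc$supplies_to_floor)
  expect_lt(mean(gs$activities$supplies_outpatient_trip$duration), 60)

  ga <- apply_scenario(g, sc$all_improvements)
  expect_equal(mean(ga$activities$pharmacy_preparation$duration), 30)
  expect_equal(mean(ga$activities$addon_preparation$duration), 30)
  expect_equal(ga$resources$porter$capacity, 2L)
  expect_false("nurse_phone_call" %in% names(ga$activities))
})

test_that("applying a scenario leaves the baseline untouched and is local", {
  g <- build_default_graph()
  sc <- builtin_scenarios()
  gf <- apply_scenario(g, sc$fast_track)
  expect_equal(mean(g$activities$pharmacy_preparation$duration), 88)
  same <- setdiff(names(g$activities), "pharmacy_preparation")
  expect_equal(gf$activities[same], g$activities[same])
  expect_equal(gf$resources, g$resources)
})

test_that("an empty scenario changes nothing and costs nothing", {
  g <- build_default_graph()
  noop <- scenario_config("noop", list())
  expect_equal(apply_scenario(g, noop), g)
  suite <- run_scenario_suite(g, list(noop = noop), n_replications = 2,
                              horizon_days = 2, seed = 6)
  expect_identical(
    suite$delta_vs_baseline_minutes[suite$scenario == "noop"], 0)
})

test_that("conflicting and unresolved overrides are configuration errors", {
  g <- build_default_graph()
  sc <- builtin_scenarios()
  dup <- scenario_config("dup", list(
    list(kind = "duration", target = "pharmacy_preparation",
         model = duration_model("fixed", 30)),
    list(kind = "duration", target = "pharmacy_preparation",
         model = duration_model("fixed", 40))))
  expect_error(apply_scenario(g, dup), "conflicting")
  bad <- scenario_config("bad", list(
    list(kind = "duration", target = "mri_scan",
         model = duration_model("fixed", 5))))
  expect_error(apply_scenario(g, bad), "mri_scan")
  # re-application is not idempotent: removed activities cannot be removed
  # twice
  g2 <- apply_scenario(g, sc$pharmacist_transport)
  expect_error(apply_scenario(g2, sc$pharmacist_transport),
               "porter_transport_medication")
})

test_that("the paired suite is ordered and internally consistent", {
  g <- build_default_graph()
  sc <- builtin_scenarios()
  suite <- run_scenario_suite(g, sc, n_replications = 4,
                              horizon_days = 10, seed = 10)
  expect_s3_class(suite, "scenario_suite")
  expect_equal(suite$scenario[1], "baseline")
  d <- suite$delta_vs_baseline_minutes[-1]
  expect_true(all(diff(d) <= 1e-9))          # Pareto order
  singles <- setdiff(suite$scenario, c("baseline", "all_improvements"))
  expect_equal(sum(suite$percent_of_total_reduction[
    suite$scenario %in% singles]), 100)
  # the bundle dominates each of its parts under common random numbers
  d_all <- suite$delta_vs_baseline_minutes[
    suite$scenario == "all_improvements"]
  expect_gte(d_all, max(suite$delta_vs_baseline_minutes[
    suite$scenario %in% singles]))
})
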