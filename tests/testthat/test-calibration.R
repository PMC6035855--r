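# Calibration tests use a tiny ward so each loss evaluation is cheap: one
# staffed activity with an unknown mean plus a fixed 50-minute tail.

toy_build <- function(p) {
  acts <- list(
    activity("order", duration_model("fixed", 0)),
    activity("task", duration_model("fixed", p$task_mean),
             predecessors = "order"),
    activity("tail", duration_model("fixed", 50), predecessors = "task"))
  process_graph(acts, list(), need_probabilities(0, 0, 0, 0),
                arrivals_per_day = 4, arrival_window = 120,
                end_activity = "tail")
}

test_that("the default target set matches the observed study moments", {
  tg <- default_targets()
  stats <- vapply(tg, `[[`, "", "statistic")
  vals <- vapply(tg, `[[`, 0, "target_value")
  tols <- vapply(tg, `[[`, 0, "tolerance")
  expect_equal(vals[stats == "baseline_mean"], 215.7)
  expect_equal(vals[stats == "baseline_sd"], 67)
  expect_equal(vals[stats == "delta:fast_track"], 36)
  expect_equal(vals[stats == "delta:extra_porter"], 8.53)
  expect_equal(vals[stats == "delta:pharmacist_transport"], 21)
  expect_equal(vals[stats == "delta:early_equipment"], 4.2)
  expect_equal(vals[stats == "delta:supplies_to_floor"], 7.36)
  expect_true(all(tols > 0))
  # delta tolerances are 25% relative
  expect_equal(tols[stats == "delta:fast_track"], 9)
})

test_that("a hidden fixed duration is recovered analytically", {
  # total = task_mean + 50 exactly, so targeting mean 92 must recover 42
  targets <- list(calibration_target("baseline_mean", 92, 1))
  res <- calibrate(init = list(task_mean = 10),
                   free_params = list(task_mean = c(0, 100)),
                   targets = targets, budget = 40L, seed = 2,
                   n_replications = 2L, n_replications_final = 2L,
                   horizon_days = 2,
                   build = toy_build,
                   scenarios_fn = function(p) list())
  expect_true(res$converged)
  expect_equal(res$par$task_mean, 42, tolerance = 1 / 42)
  expect_equal(unname(res$achieved[["baseline_mean"]]), 92, tolerance = 0.02)
})

test_that("budget one evaluates only the initial midpoint guess", {
  targets <- list(calibration_target("baseline_mean", 92, 5))
  res <- suppressWarnings(
    calibrate(init = list(task_mean = 10),
              free_params = list(task_mean = c(0, 100)),
              targets = targets, budget = 1L, seed = 2,
              n_replications = 2L, n_replications_final = 2L,
              horizon_days = 2, build = toy_build,
              scenarios_fn = function(p) list()))
  expect_equal(res$evaluations, 1L)
  expect_equal(res$par$task_mean, 50)   # the box midpoint
})

test_that("two hidden parameters are recovered from simulated moments", {
  build2 <- function(p) {
    acts <- list(
      activity("order", duration_model("fixed", 0)),
      activity("a", duration_model("fixed", p$a_mean),
               predecessors = "order"),
      activity("b", duration_model("normal", c(p$b_mean, 5)),
               predecessors = "a"))
    process_graph(acts, list(), need_probabilities(0, 0, 0, 0),
                  arrivals_per_day = 6, arrival_window = 120,
                  end_activity = "b")
  }
  truth <- list(a_mean = 30, b_mean = 20)
  target_stats <- evaluate_calibration(truth,
    list(calibration_target("baseline_mean", 1, 1)),
    n_replications = 4L, horizon_days = 3, seed = 3, build = build2,
    scenarios_fn = function(p) list())
  targets <- list(calibration_target("baseline_mean",
                                     target_stats[["baseline_mean"]], 1))
  res <- calibrate(init = truth, free_params = list(a_mean = c(10, 60)),
                   targets = targets, budget = 30L, seed = 3,
                   n_replications = 4L, n_replications_final = 4L,
                   horizon_days = 3, build = build2,
                   scenarios_fn = function(p) list())
  # the recovered sum a+b matches the truth within 2 tolerances
  expect_lt(abs(res$achieved[["baseline_mean"]] -
                  target_stats[["baseline_mean"]]), 2)
  expect_lt(abs(res$par$a_mean - truth$a_mean), 2)
})

test_that("an unreachable baseline mean is reported, not silently accepted", {
  targets <- list(calibration_target("baseline_mean", 1000, 1))
  expect_warning(
    res <- calibrate(init = list(task_mean = 10),
                     free_params = list(task_mean = c(0, 100)),
                     targets = targets, budget = 5L, seed = 2,
                     n_replications = 2L, n_replications_final = 2L,
                     horizon_days = 2, build = toy_build,
                     scenarios_fn = function(p) list()),
    "failed to meet")
  expect_false(res$converged)
})

test_that("the shipped calibrated configuration is complete", {
  p <- calibrated_params()
  expect_true(all(names(discharge_params()) %in% names(p)))
  expect_true(all(vapply(p, is.numeric, TRUE)))
  g <- build_default_graph(params = p)
  expect_length(validate_graph(g), 0L)
})
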