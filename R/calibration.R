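#' Calibration targets
#'
#' A target pins one summary statistic of the simulated process to an
#' observed value within a tolerance: the shadowed baseline mean and SD, or
#' a named scenario's paired reduction.  The calibration loss is
#' tolerance-normalised, so minute-scale and delta-scale targets mix.
#'
#' @param statistic `"baseline_mean"`, `"baseline_sd"`, or
#'   `"delta:<scenario>"`.
#' @param target_value minutes.
#' @param tolerance positive minutes.
#' @param weight non-negative loss weight.
#' @export
calibration_target <- function(statistic, target_value, tolerance,
                               weight = 1) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  structure(list(statistic = statistic, target_value = target_value,
                 tolerance = tolerance, weight = weight),
            class = "calibration_target")
}

#' Default calibration targets
#'
#' The observed baseline moments (mean 215.7 min, SD 67 min over the 38
#' shadowed discharges) and the five reported single-intervention
#' reductions (36, 8.53, 21, 4.2 and 7.36 minutes), the latter with 25%
#' relative tolerances.
#'
#' @return list of [calibration_target()] objects.
#' @export
default_targets <- function() {
  deltas <- c(fast_track = 36, extra_porter = 8.53,
              pharmacist_transport = 21, early_equipment = 4.2,
              supplies_to_floor = 7.36)
  c(list(calibration_target("baseline_mean", 215.7, 5),
         calibration_target("baseline_sd", 67, 12)),
    lapply(names(deltas), function(nm)
      calibration_target(paste0("delta:", nm), deltas[[nm]],
                         0.25 * deltas[[nm]])))
}

#' Evaluate the calibration statistics of a parameter set
#'
#' Rebuilds the graph and scenario menu from `params`, runs the paired
#' experiments and returns the achieved statistics for the given targets.
#'
#' @param params named free-parameter list (see [discharge_params()]).
#' @param targets list of [calibration_target()].
#' @param n_replications,horizon_days,seed experiment settings.
#' @param build function turning a parameter list into a
#'   [process_graph()]; defaults to [build_default_graph()].
#' @param scenarios_fn function turning a parameter list into the scenario
#'   list; defaults to [builtin_scenarios()].
#' @return named numeric vector of achieved statistics.
#' @export
evaluate_calibration <- function(params, targets,
                                 n_replications = 20L, horizon_days = 30,
                                 seed = 1L,
                                 build = function(p)
                                   build_default_graph(params = p),
                                 scenarios_fn = function(p)
                                   builtin_scenarios(params = p)) {
  stats_wanted <- vapply(targets, `[[`, "", "statistic")
  g <- build(params)
  base <- run_experiment(g, n_replications, horizon_days, seed)
  out <- c(baseline_mean = base$grand_mean_minutes,
           baseline_sd = base$mean_sd_minutes)
  delta_stats <- grep("^delta:", stats_wanted, value = TRUE)
  if (length(delta_stats)) {
    menu <- scenarios_fn(params)
    for (st in delta_stats) {
      nm <- sub("^delta:", "", st)
      if (!nm %in% names(menu))
        stop("unknown scenario in target: ", nm, call. = FALSE)
      gs <- apply_scenario(g, menu[[nm]])
      ex <- run_experiment(gs, n_replications, horizon_days, seed)
      out[st] <- base$grand_mean_minutes - ex$grand_mean_minutes
    }
  }
  out[stats_wanted]
}

calibration_loss <- function(achieved, targets) {
  sum(vapply(targets, function(tg) {
    a <- achieved[[tg$statistic]]
    tg$weight * ((a - tg$target_value) / tg$tolerance)^2
  }, 0))
}

#' Calibrate free parameters by simulated method of moments
#'
#' Derivative-free search over the free parameters: a Latin-hypercube sweep
#' of the bounded box followed by a shrinking coordinate-descent polish
#' around the best point, minimising the tolerance-normalised squared loss.
#' The search uses a reduced replication count; the optimum is re-evaluated
#' from scratch at a higher count (`n_replications_final`).  Deterministic
#' given `seed`.
#'
#' @param init full named parameter list used for parameters not being
#'   searched (defaults to [discharge_params()]).
#' @param free_params named list of `c(lower, upper)` bounds.
#' @param targets list of [calibration_target()]; default
#'   [default_targets()].
#' @param budget maximum number of loss evaluations (>= 1).
#' @param seed integer seed (drives both the Latin hypercube and the
#'   simulation streams).
#' @param n_replications,n_replications_final replications per evaluation
#'   during search and for the final re-evaluation.
#' @param horizon_days simulated horizon.
#' @inheritParams evaluate_calibration
#' @return object of class `calibration_result`: `par` (fitted parameters),
#'   `achieved` (statistics recomputed at `n_replications_final`), `loss`,
#'   `met` (logical per target at its tolerance), `evaluations`,
#'   `converged` (all targets met).
#' @export
calibrate <- function(init = discharge_params(), free_params, targets = default_targets(),
                      budget = 60L, seed = 1L,
                      n_replications = 20L, n_replications_final = 100L,
                      horizon_days = 30,
                      build = function(p) build_default_graph(params = p),
                      scenarios_fn = function(p)
                        builtin_scenarios(params = p)) {
  stopifnot(budget >= 1L, length(free_params) >= 1L)
  lo <- vapply(free_params, `[`, 0, 1)
  hi <- vapply(free_params, `[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi < lo))
    stop("each free parameter needs finite bounds lower <= upper",
         call. = FALSE)
  nmp <- names(free_params)
  evals <- 0L
  best <- list(loss = Inf, par = NULL, achieved = NULL)
  eval_point <- function(theta) {
    p <- utils::modifyList(init, as.list(stats::setNames(theta, nmp)))
    a <- evaluate_calibration(p, targets, n_replications, horizon_days,
                              seed, build, scenarios_fn)
    evals <<- evals + 1L
    l <- calibration_loss(a, targets)
    if (l < best$loss) best <<- list(loss = l, par = p, achieved = a)
    l
  }

  # phase 1: Latin hypercube over the box (deterministic given seed)
  n_lhs <- max(1L, min(budget, ceiling(0.6 * budget)))
  mid <- (lo + hi) / 2
  eval_point(mid)
  if (budget > 1L && n_lhs > 1L) {
    grid <- with_stream(seed, 0L, "calibration-lhs",
                        lhs::randomLHS(n_lhs - 1L, length(nmp)))
    for (i in seq_len(nrow(grid))) {
      if (evals >= budget) break
      eval_point(lo + grid[i, ] * (hi - lo))
    }
  }

  # phase 2: coordinate descent with shrinking steps
  theta <- vapply(nmp, function(n) best$par[[n]], 0)
  step <- (hi - lo) / 4
  while (evals < budget && any(step > 1e-9)) {
    improved <- FALSE
    for (j in seq_along(theta)) {
      if (evals >= budget) break
      for (dir in c(-1, 1)) {
        if (evals >= budget) break
        cand <- theta
        cand[j] <- min(hi[j], max(lo[j], theta[j] + dir * step[j]))
        if (cand[j] == theta[j]) next
        l0 <- best$loss
        if (eval_point(cand) < l0) { theta <- cand; improved <- TRUE; break }
      }
    }
    if (!improved) step <- step / 2
  }

  # final re-evaluation at full replication count
  achieved <- evaluate_calibration(best$par, targets,
                                   n_replications_final, horizon_days,
                                   seed, build, scenarios_fn)
  met <- vapply(targets, function(tg)
    abs(achieved[[tg$statistic]] - tg$target_value) <= tg$tolerance, TRUE)
  names(met) <- vapply(targets, `[[`, "", "statistic")
  res <- structure(list(par = best$par, achieved = achieved,
                        loss = calibration_loss(achieved, targets),
                        met = met, evaluations = evals,
                        converged = all(met)),
                   class = "calibration_result")
  if (!met[["baseline_mean"]])
    warning("calibration failed to meet the baseline-mean tolerance; ",
            "inspect the result before using it", call. = FALSE)
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> loss %.3f after %d evaluations; %s\n",
              x$loss, x$evaluations,
              if (x$converged) "all targets met"
              else paste(sum(!x$met), "target(s) not met")))
  for (nm in names(x$met))
    cat(sprintf("  %-28s %8.2f %s\n", nm, x$achieved[[nm]],
                if (x$met[[nm]]) "(met)" else "(NOT met)"))
  invisible(x)
}
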