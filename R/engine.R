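# Event-driven execution of a process_graph.
#
# The engine pre-draws every stochastic quantity of a replication from named
# substreams (see rng.R) and then runs a deterministic event calendar:
# activity completions and post-offset ready events, FIFO resource queues
# with all-or-nothing seizing, ties broken by insertion order.  Pre-drawing
# gives exact common random numbers across scenarios and makes replications
# bitwise reproducible.

compile_graph <- function(g) {
  v <- validate_graph(g)
  if (length(v))
    stop("invalid process graph:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  nm <- names(g$activities)
  n_act <- length(nm)
  idx <- stats::setNames(seq_len(n_act), nm)
  pool_nm <- names(g$resources)
  pool_cap <- vapply(g$resources, `[[`, 0L, "capacity")
  pred <- lapply(g$activities, function(a) unname(idx[a$predecessors]))
  succ <- vector("list", n_act)
  for (j in seq_len(n_act)) succ[[j]] <- integer()
  for (j in seq_len(n_act))
    for (p in pred[[j]]) succ[[p]] <- c(succ[[p]], j)
  res_pool <- lapply(g$activities, function(a)
    unname(match(names(a$resources), pool_nm)))
  res_cnt <- lapply(g$activities, function(a) as.integer(unname(a$resources)))
  cond <- vapply(g$activities, function(a)
    if (is.null(a$condition)) 0L else match(a$condition, need_flags()), 0L)
  src <- which(vapply(pred, length, 0L) == 0L)
  list(nm = nm, n_act = n_act, idx = idx,
       pred = pred, succ = succ, npred0 = vapply(pred, length, 0L),
       res_pool = res_pool, res_cnt = res_cnt,
       has_res = vapply(res_pool, length, 0L) > 0L,
       cond = cond,
       dur = lapply(g$activities, `[[`, "duration"),
       off = lapply(g$activities, `[[`, "start_offset"),
       has_off = !vapply(lapply(g$activities, `[[`, "start_offset"),
                         is.null, TRUE),
       pool_nm = pool_nm, pool_cap = pool_cap,
       source = src, end = unname(idx[g$end_activity]))
}

# arrival minutes over the horizon: Poisson counts per day, uniform within
# the morning window
draw_arrivals <- function(g, horizon_days, seed, rep) {
  with_stream(seed, rep, "arrivals", {
    counts <- stats::rpois(ceiling(horizon_days), g$arrivals_per_day)
    unlist(lapply(seq_along(counts), function(d) {
      if (counts[d] == 0L) return(numeric())
      (d - 1) * 1440 + sort(stats::runif(counts[d], 0, g$arrival_window))
    }))
  })
}

draw_tables <- function(cg, seed, rep, n_pat) {
  dur <- matrix(0, nrow = cg$n_act, ncol = n_pat)
  off <- matrix(0, nrow = cg$n_act, ncol = n_pat)
  for (j in seq_len(cg$n_act)) {
    dur[j, ] <- with_stream(seed, rep, paste0("dur:", cg$nm[j]),
                            sample_duration(cg$dur[[j]], n_pat))
    if (cg$has_off[j])
      off[j, ] <- with_stream(seed, rep, paste0("off:", cg$nm[j]),
                              sample_duration(cg$off[[j]], n_pat))
  }
  list(dur = dur, off = off)
}

#' Run one replication of the discharge simulation
#'
#' Simulates all patients whose discharge order arrives within
#' `horizon_days`; every patient is run to completion (the ward empties
#' overnight, so no warm-up period is used).  All resource queues are FIFO;
#' simultaneous events are ordered by insertion sequence, so a given
#' `(graph, seed, rep)` always yields identical records.
#'
#' @param g a validated [process_graph()].
#' @param horizon_days simulated horizon (default one month).
#' @param seed integer root seed.
#' @param rep replication index (selects the substream family).
#' @param keep_log keep per-activity start/end columns in the records.
#' @return list of class `replication_summary`: `n_discharges`,
#'   `mean_minutes`, `sd_minutes` and a `records` data.frame (one row per
#'   patient with need flags, population, arrival and total minutes).
#' @export
run_replication <- function(g, horizon_days = 30, seed = 1L, rep = 1L,
                            keep_log = TRUE) {
  stopifnot(horizon_days > 0)
  cg <- compile_graph(g)
  arr <- draw_arrivals(g, horizon_days, seed, rep)
  n_pat <- length(arr)
  if (n_pat == 0L)
    stop("no arrivals within the horizon", call. = FALSE)
  profiles <- with_stream(seed, rep, "profiles",
                          sample_profile(g$needs, n_pat))
  tabs <- draw_tables(cg, seed, rep, n_pat)
  sim <- simulate_events(cg, arr, profiles, tabs)
  build_summary(cg, arr, profiles, sim, keep_log)
}

simulate_events <- function(cg, arr, profiles, tabs) {
  n_pat <- length(arr)
  n_act <- cg$n_act
  dur <- tabs$dur; off <- tabs$off
  flag_m <- rbind(narcotics = profiles$needs_narcotics,
                  equipment = profiles$needs_equipment,
                  supplies = profiles$needs_supplies,
                  addon = profiles$gets_addon)
  # enabled[act, pat]
  enabled <- matrix(TRUE, n_act, n_pat)
  for (j in which(cg$cond > 0L)) enabled[j, ] <- flag_m[cg$cond[j], ]

  npred <- matrix(cg$npred0, n_act, n_pat)
  start_m <- matrix(NA_real_, n_act, n_pat)
  end_m <- matrix(NA_real_, n_act, n_pat)
  pool_free <- cg$pool_cap

  # event calendar (grown by doubling): type 1 = ready-to-seize, 2 = end
  cap <- 4096L
  ev_time <- numeric(cap); ev_pat <- integer(cap); ev_act <- integer(cap)
  ev_type <- integer(cap); ev_seq <- numeric(cap)
  n_ev <- 0L; seq_ctr <- 0
  push <- function(t, pat, act, type) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_time) <<- cap; length(ev_pat) <<- cap
      length(ev_act) <<- cap; length(ev_type) <<- cap
      length(ev_seq) <<- cap
    }
    seq_ctr <<- seq_ctr + 1
    ev_time[n_ev] <<- t; ev_pat[n_ev] <<- pat; ev_act[n_ev] <<- act
    ev_type[n_ev] <<- type; ev_seq[n_ev] <<- seq_ctr
  }

  # FIFO waiting list for resource-seizing activities
  wq_pat <- integer(); wq_act <- integer()

  activate <- function(pat, act, t) {
    if (!enabled[act, pat]) {
      start_m[act, pat] <<- t
      push(t, pat, act, 2L)       # zero-duration pass-through
      return(invisible())
    }
    t_ready <- t + if (cg$has_off[act]) off[act, pat] else 0
    if (cg$has_res[act]) {
      push(t_ready, pat, act, 1L)
    } else {
      start_m[act, pat] <<- t_ready
      push(t_ready + dur[act, pat], pat, act, 2L)
    }
    invisible()
  }

  dispatch <- function(t) {
    if (!length(wq_pat)) return(invisible())
    granted <- logical(length(wq_pat))
    for (k in seq_along(wq_pat)) {
      act <- wq_act[k]
      pools <- cg$res_pool[[act]]
      cnts <- cg$res_cnt[[act]]
      if (all(pool_free[pools] >= cnts)) {
        pool_free[pools] <<- pool_free[pools] - cnts
        pat <- wq_pat[k]
        start_m[act, pat] <<- t
        push(t + dur[act, pat], pat, act, 2L)
        granted[k] <- TRUE
      }
    }
    if (any(granted)) {
      wq_pat <<- wq_pat[!granted]
      wq_act <<- wq_act[!granted]
    }
    invisible()
  }

  for (i in seq_len(n_pat)) activate(i, cg$source, arr[i])

  while (n_ev > 0L) {
    ts <- ev_time[seq_len(n_ev)]
    m <- which(ts == min(ts))
    k <- if (length(m) > 1L) m[which.min(ev_seq[m])] else m
    t <- ev_time[k]; pat <- ev_pat[k]; act <- ev_act[k]; type <- ev_type[k]
    # remove by swapping the last event in
    ev_time[k] <- ev_time[n_ev]; ev_pat[k] <- ev_pat[n_ev]
    ev_act[k] <- ev_act[n_ev]; ev_type[k] <- ev_type[n_ev]
    ev_seq[k] <- ev_seq[n_ev]
    n_ev <- n_ev - 1L

    if (type == 1L) {                 # ready to seize resources
      wq_pat <- c(wq_pat, pat); wq_act <- c(wq_act, act)
      dispatch(t)
    } else {                          # completion
      end_m[act, pat] <- t
      released <- FALSE
      if (enabled[act, pat] && cg$has_res[act]) {
        pools <- cg$res_pool[[act]]
        pool_free[pools] <- pool_free[pools] + cg$res_cnt[[act]]
        released <- TRUE
      }
      for (s in cg$succ[[act]]) {
        npred[s, pat] <- npred[s, pat] - 1L
        if (npred[s, pat] == 0L) activate(pat, s, t)
      }
      if (released) dispatch(t)
    }
  }

  if (anyNA(end_m[cg$end, ])) {
    blocked <- unique(cg$nm[wq_act])
    stop("simulation deadlock: no runnable event while patients pending",
         if (length(blocked)) paste0(" (blocked at: ",
                                     paste(blocked, collapse = ", "), ")"),
         call. = FALSE)
  }
  list(start = start_m, end = end_m, enabled = enabled)
}

build_summary <- function(cg, arr, profiles, sim, keep_log) {
  total <- sim$end[cg$end, ] - arr
  rec <- data.frame(id = profiles$id,
                    arrival_minute = arr,
                    needs_narcotics = profiles$needs_narcotics,
                    needs_equipment = profiles$needs_equipment,
                    needs_supplies = profiles$needs_supplies,
                    gets_addon = profiles$gets_addon,
                    population = profiles$population,
                    total_minutes = total)
  if (keep_log) {
    for (j in seq_len(cg$n_act)) {
      s <- sim$start[j, ]; e <- sim$end[j, ]
      s[!sim$enabled[j, ]] <- NA_real_
      e[!sim$enabled[j, ]] <- NA_real_
      rec[[paste0(cg$nm[j], "_start")]] <- s
      rec[[paste0(cg$nm[j], "_end")]] <- e
    }
  }
  structure(list(n_discharges = length(total),
                 mean_minutes = mean(total),
                 sd_minutes = stats::sd(total),
                 records = rec),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("<replication_summary> %d discharges, mean %.2f min, sd %.2f min\n",
              x$n_discharges, x$mean_minutes, x$sd_minutes))
  invisible(x)
}

#' Run a replicated simulation experiment
#'
#' Runs `n_replications` independent one-month replications (replication
#' `r` uses the substream family `(seed, r)`) and summarises the means.
#'
#' @inheritParams run_replication
#' @param n_replications number of replications.
#' @param keep_records keep each replication's full records (memory-heavy).
#' @return list of class `experiment_summary`: `n_replications`,
#'   `grand_mean_minutes` (unweighted mean of replication means),
#'   `sd_of_replication_means`, `mean_sd_minutes` (average within-replication
#'   sd) and a per-replication data.frame `replications`.
#' @examples
#' \donttest{
#' g <- build_default_graph()
#' ex <- run_experiment(g, n_replications = 5, seed = 42)
#' ex$grand_mean_minutes
#' }
#' @export
run_experiment <- function(g, n_replications = 100L, horizon_days = 30,
                           seed = 1L, keep_records = FALSE) {
  stopifnot(n_replications >= 1L)
  cg <- compile_graph(g)   # validate once up front
  reps <- vector("list", n_replications)
  per <- data.frame(rep = seq_len(n_replications),
                    n_discharges = NA_integer_,
                    mean_minutes = NA_real_, sd_minutes = NA_real_)
  for (r in seq_len(n_replications)) {
    s <- run_replication(g, horizon_days = horizon_days, seed = seed,
                         rep = r, keep_log = keep_records)
    per$n_discharges[r] <- s$n_discharges
    per$mean_minutes[r] <- s$mean_minutes
    per$sd_minutes[r] <- s$sd_minutes
    if (keep_records) reps[[r]] <- s
  }
  structure(list(n_replications = n_replications,
                 grand_mean_minutes = mean(per$mean_minutes),
                 sd_of_replication_means = stats::sd(per$mean_minutes),
                 mean_sd_minutes = mean(per$sd_minutes),
                 total_discharges = sum(per$n_discharges),
                 replications = per,
                 summaries = if (keep_records) reps),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf(paste0("<experiment_summary> %d replications, grand mean %.2f min",
                     " (sd of replication means %.2f)\n"),
              x$n_replications, x$grand_mean_minutes,
              x$sd_of_replication_means))
  invisible(x)
}

#' Deterministic critical-path time of a graph
#'
#' Evaluates every activity enabled by `profile` at its distribution mean
#' (durations and start offsets), ignores resource contention, and returns
#' the completion time of the end activity by dynamic programming over a
#' topological order.  This is the engine's verification oracle: with
#' degenerate durations and unbounded resources the simulated total equals
#' this critical-path time.
#'
#' @param g a [process_graph()].
#' @param profile one row of [sample_profile()] output (or a list with the
#'   four need flags).
#' @return minutes from discharge order to the end activity.
#' @export
longest_path_time <- function(g, profile) {
  ord <- topological_order(g)
  flags <- c(narcotics = isTRUE(profile$needs_narcotics),
             equipment = isTRUE(profile$needs_equipment),
             supplies = isTRUE(profile$needs_supplies),
             addon = isTRUE(profile$gets_addon))
  done <- stats::setNames(numeric(length(ord)), ord)
  for (nmj in ord) {
    a <- g$activities[[nmj]]
    ready <- if (length(a$predecessors)) max(done[a$predecessors]) else 0
    if (!is.null(a$condition) && !flags[[a$condition]]) {
      done[nmj] <- ready
    } else {
      offm <- if (is.null(a$start_offset)) 0 else mean(a$start_offset)
      done[nmj] <- ready + offm + mean(a$duration)
    }
  }
  unname(done[g$end_activity])
}

#' Relative validation error
#'
#' Percentage error between an observed and a simulated mean,
#' `100 * (observed - simulated) / observed`, reported to two decimals.
#'
#' @param observed observed mean (minutes), must be positive.
#' @param simulated simulated mean (minutes).
#' @return percent, rounded to two decimals.
#' @examples
#' relative_error(215.7, 213.38)  # 1.08
#' @export
relative_error <- function(observed, simulated) {
  if (!is.numeric(observed) || observed <= 0)
    stop("observed mean must be > 0", call. = FALSE)
  round(100 * (observed - simulated) / observed, 2)
}
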