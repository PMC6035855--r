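#' Configuration for synthetic shadowing data
#'
#' Describes how to emulate a shadowing study of discharges (the field
#' campaign followed patients from the discharge-order signature until they
#' left the room; 38 usable observations over one month).  Two modes:
#'
#' * **graph-driven** (default): records are simulated from a
#'   [process_graph()], giving full per-activity logs;
#' * **summary**: only total durations are drawn, from a two-population
#'   truncated-normal mixture (standard vs. complex discharges) with the
#'   stated need frequencies.
#'
#' The default summary-mode populations, standard N(185, 40) and complex
#' N(278, 68), are declared assumptions (the study printed no
#' per-population parameters): with the complex share implied by
#' independent need flags (about one third), they pool to a mean near 216
#' and an SD near 67 minutes.
#'
#' @param n_patients number of shadowed discharges (default 38).
#' @param needs a [need_probabilities()].
#' @param graph a [process_graph()] for graph-driven mode (default: the
#'   shipped calibrated graph), or `NULL` for summary mode.
#' @param population_params summary-mode parameters: list with `standard`
#'   and `complex`, each `c(mean, sd)`; ignored in graph-driven mode.
#' @param dropout_rate probability that a shadowed discharge is discarded
#'   for measurement errors (the campaign lost 3 of 41; default 0 keeps
#'   exactly `n_patients`).
#' @param seed integer seed.
#' @export
shadowing_config <- function(n_patients = 38L, needs = need_probabilities(),
                             graph = build_default_graph(),
                             population_params = list(
                               standard = c(mean = 185, sd = 40),
                               complex = c(mean = 278, sd = 68)),
                             dropout_rate = 0, seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (!is.null(graph) && !inherits(graph, "process_graph"))
    stop("graph must be a process_graph or NULL", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), needs = needs,
                 graph = graph, population_params = population_params,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "shadowing_config")
}

#' Generate a synthetic shadowing dataset
#'
#' Draws discharge records per the configuration.  Graph-driven mode
#' simulates one replication and keeps the first `n_patients` completed
#' discharges (with per-activity start/end columns); summary mode draws
#' population membership from the need flags and then a truncated-normal
#' total duration.  Deterministic given the config seed.
#'
#' @param config a [shadowing_config()]; the default emulates the
#'   one-month campaign on the calibrated graph.
#' @param path optional CSV path; when given, records are also written with
#'   [write_discharge_records()].
#' @return data.frame of discharge records.
#' @examples
#' \donttest{
#' rec <- generate_shadowing(shadowing_config(graph = build_default_graph()))
#' mean(rec$total_minutes)
#' }
#' @export
generate_shadowing <- function(config = shadowing_config(), path = NULL) {
  stopifnot(inherits(config, "shadowing_config"))
  n <- config$n_patients
  if (!is.null(config$graph)) {
    g <- config$graph
    # simulate enough days that n discharges certainly complete
    days <- max(2, ceiling(1.5 * n / g$arrivals_per_day))
    s <- run_replication(g, horizon_days = days, seed = config$seed,
                         rep = 1L)
    if (s$n_discharges < n)
      stop("horizon produced too few discharges", call. = FALSE)
    rec <- utils::head(s$records, n)
  } else {
    pp <- config$population_params
    rec <- with_stream(config$seed, 1L, "shadowing", {
      prof <- sample_profile(config$needs, n)
      draw_pop <- function(par, m) {
        if (par[["sd"]] == 0) return(rep(par[["mean"]], m))
        x <- stats::rnorm(m, par[["mean"]], par[["sd"]])
        bad <- which(x < 0)
        while (length(bad)) {
          x[bad] <- stats::rnorm(length(bad), par[["mean"]], par[["sd"]])
          bad <- bad[x[bad] < 0]
        }
        x
      }
      tot <- numeric(n)
      std <- prof$population == "standard"
      tot[std] <- draw_pop(pp$standard, sum(std))
      tot[!std] <- draw_pop(pp$complex, sum(!std))
      cbind(prof[, c("id", "needs_narcotics", "needs_equipment",
                     "needs_supplies", "gets_addon", "population")],
            total_minutes = tot)
    })
  }
  if (config$dropout_rate > 0) {
    keep <- with_stream(config$seed, 2L, "dropout",
                        stats::runif(nrow(rec)) >= config$dropout_rate)
    rec <- rec[keep, , drop = FALSE]
    rec$id <- seq_len(nrow(rec))
  }
  rownames(rec) <- NULL
  if (!is.null(path)) write_discharge_records(rec, path)
  rec
}

#' Summarise patient needs and their time impact
#'
#' Per need flag: the observed frequency and the *added minutes* — the
#' difference between the mean total duration of flagged and unflagged
#' discharges — with group counts.
#'
#' @param records discharge records (from [generate_shadowing()] or
#'   [run_replication()]).
#' @return data.frame with columns `need`, `n`, `frequency`,
#'   `added_minutes`.
#' @export
summarize_needs <- function(records) {
  if (!NROW(records)) stop("no records", call. = FALSE)
  flags <- c(narcotics = "needs_narcotics", equipment = "needs_equipment",
             supplies = "needs_supplies", addon = "gets_addon")
  out <- lapply(names(flags), function(nm) {
    f <- records[[flags[[nm]]]]
    added <- if (any(f) && any(!f))
      mean(records$total_minutes[f]) - mean(records$total_minutes[!f])
    else NA_real_
    data.frame(need = nm, n = sum(f), frequency = mean(f),
               added_minutes = added)
  })
  do.call(rbind, out)
}

#' Read and write discharge-record CSV files
#'
#' One row per patient: `id`, the four need flags, `population`,
#' `arrival_minute` (graph-driven data), `total_minutes`, and optional
#' per-activity `*_start`/`*_end` columns.  The same schema is produced by
#' the simulation engine and the synthetic generator, so the analytics
#' consume either interchangeably.
#'
#' @param records data.frame of discharge records.
#' @param path CSV file path.
#' @return `write_discharge_records` returns `path` invisibly;
#'   `read_discharge_records` returns the data.frame.
#' @export
write_discharge_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_discharge_records
#' @export
read_discharge_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("needs_narcotics", "needs_equipment", "needs_supplies",
                "gets_addon"))
    if (col %in% names(rec)) rec[[col]] <- as.logical(rec[[col]])
  if ("population" %in% names(rec))
    rec$population <- factor(rec$population,
                             levels = c("standard", "complex"))
  rec
}
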