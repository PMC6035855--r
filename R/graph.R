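#' Activity specification
#'
#' One node of the discharge workflow.  An activity starts once all its
#' predecessors have finished (plus an optional random start offset), seizes
#' the listed resource pools for the whole of its service time, and releases
#' them on completion.  `condition` gates the activity on a patient-need
#' flag: for patients without the flag the activity is skipped and its
#' successors inherit the predecessors' completion time.
#'
#' @param name identifier, unique within a graph.
#' @param duration a [duration_model()].
#' @param resources named integer vector of seized capacity per pool,
#'   e.g. `c(porter = 1)`; empty for unstaffed steps.
#' @param predecessors character vector of activity names.
#' @param start_offset optional [duration_model()]: delay between the last
#'   predecessor finishing and the activity becoming ready.
#' @param condition optional flag name, one of `"narcotics"`, `"equipment"`,
#'   `"supplies"`, `"addon"`.
#' @param performer_note free-text note on who performs the step.
#' @export
activity <- function(name, duration, resources = integer(),
                     predecessors = character(), start_offset = NULL,
                     condition = NULL, performer_note = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(duration, "duration_model"))
    stop(sprintf("activity '%s': duration must be a duration_model", name),
         call. = FALSE)
  if (length(resources)) {
    if (is.null(names(resources)) || any(!nzchar(names(resources))))
      stop(sprintf("activity '%s': resources must be a named vector", name),
           call. = FALSE)
    pool_names <- names(resources)
    resources <- as.integer(resources)
    names(resources) <- pool_names
    if (any(is.na(resources) | resources < 1L))
      stop(sprintf("activity '%s': seized counts must be >= 1", name),
           call. = FALSE)
  } else resources <- integer()
  if (!is.null(start_offset) && !inherits(start_offset, "duration_model"))
    stop(sprintf("activity '%s': start_offset must be a duration_model", name),
         call. = FALSE)
  if (!is.null(condition))
    condition <- match.arg(condition, need_flags())
  structure(list(name = name, duration = duration, resources = resources,
                 predecessors = unique(as.character(predecessors)),
                 start_offset = start_offset, condition = condition,
                 performer_note = performer_note),
            class = "activity")
}

need_flags <- function() c("narcotics", "equipment", "supplies", "addon")

#' Resource pool
#'
#' @param name pool identifier.
#' @param capacity positive integer number of servers; requests are served
#'   first-in-first-out.
#' @export
resource_pool <- function(name, capacity = 1L) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1L)
    stop(sprintf("pool '%s': capacity must be >= 1", name), call. = FALSE)
  structure(list(name = name, capacity = capacity, discipline = "FIFO"),
            class = "resource_pool")
}

#' Patient-need probabilities
#'
#' Marginal probabilities of the four extra-need flags observed during
#' discharge shadowing: outpatient narcotics prescriptions (40%), special
#' equipment such as oxygen generators (16%), supplies bought at the
#' outpatient clinic (5%) and add-on medication orders (16%).  Flags are
#' drawn independently by default; `correlation` adds a shared Gaussian
#' copula factor across the flags for sensitivity analyses.
#'
#' @param p_narcotics,p_equipment,p_supplies,p_addon probabilities in
#'   `[0, 1]`.
#' @param correlation common-factor copula correlation in `[0, 1)`.
#' @export
need_probabilities <- function(p_narcotics = 0.40, p_equipment = 0.16,
                               p_supplies = 0.05, p_addon = 0.16,
                               correlation = 0) {
  p <- c(narcotics = p_narcotics, equipment = p_equipment,
         supplies = p_supplies, addon = p_addon)
  if (any(p < 0 | p > 1)) stop("need probabilities must be in [0, 1]",
                               call. = FALSE)
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)", call. = FALSE)
  structure(list(p = p, correlation = correlation),
            class = "need_probabilities")
}

#' Sample patient need profiles
#'
#' Draws need flags (one Bernoulli per flag, optionally copula-correlated)
#' and derives the population label: a discharge is *complex* when the
#' patient needs equipment, supplies or an add-on medication, otherwise
#' *standard*.
#'
#' @param needs a [need_probabilities()].
#' @param n number of patients.
#' @return data.frame with columns `id`, the four logical need flags and
#'   `population` (factor `standard`/`complex`).
#' @export
sample_profile <- function(needs, n = 1L) {
  stopifnot(inherits(needs, "need_probabilities"), n >= 1L)
  p <- needs$p
  rho <- needs$correlation
  if (rho > 0) {
    z0 <- stats::rnorm(n)
    flags <- vapply(seq_along(p), function(j) {
      z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
      z < stats::qnorm(p[j])
    }, logical(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1L)
  } else {
    flags <- vapply(seq_along(p),
                    function(j) stats::runif(n) < p[j], logical(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1L)
  }
  colnames(flags) <- names(p)
  out <- data.frame(id = seq_len(n),
                    needs_narcotics = flags[, "narcotics"],
                    needs_equipment = flags[, "equipment"],
                    needs_supplies = flags[, "supplies"],
                    gets_addon = flags[, "addon"])
  out$population <- derive_population(out)
  out
}

derive_population <- function(profiles) {
  complex <- profiles$needs_equipment | profiles$needs_supplies |
    profiles$gets_addon
  factor(ifelse(complex, "complex", "standard"),
         levels = c("standard", "complex"))
}

#' Discharge process graph
#'
#' Container for the workflow: activities, resource pools, need
#' probabilities and the arrival process (discharge orders arriving at
#' `arrivals_per_day` as a Poisson count spread uniformly over a morning
#' window of `arrival_window` minutes, matching physician rounds).
#'
#' @param activities list of [activity()] objects.
#' @param resources list of [resource_pool()] objects.
#' @param needs a [need_probabilities()].
#' @param arrivals_per_day mean discharge orders per day.
#' @param arrival_window minutes after the day start during which orders
#'   arrive.
#' @param end_activity name of the activity whose completion means the
#'   patient has left the room.
#' @param params named list of free parameters the graph was built from
#'   (kept for serialization and calibration).
#' @export
process_graph <- function(activities, resources, needs,
                          arrivals_per_day = 24, arrival_window = 480,
                          end_activity, params = list()) {
  names(activities) <- vapply(activities, `[[`, "", "name")
  names(resources) <- vapply(resources, `[[`, "", "name")
  g <- structure(list(activities = activities, resources = resources,
                      needs = needs, arrivals_per_day = arrivals_per_day,
                      arrival_window = arrival_window,
                      end_activity = end_activity, params = params),
                 class = "process_graph")
  g
}

#' @export
print.process_graph <- function(x, ...) {
  cat(sprintf("<process_graph> %d activities, %d resource pools, %g arrivals/day\n",
              length(x$activities), length(x$resources), x$arrivals_per_day))
  invisible(x)
}

#' Validate a process graph
#'
#' Checks the structural invariants: predecessor and resource references
#' resolve, no self-precedence, the precedence relation is acyclic, the end
#' activity exists, there is exactly one source activity, and pool
#' capacities are positive.  Violations are returned as data, not raised.
#'
#' @param g a [process_graph()].
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_graph <- function(g) {
  v <- character()
  acts <- g$activities
  nm <- names(acts)
  if (anyDuplicated(nm))
    v <- c(v, sprintf("duplicate activity name(s): %s",
                      paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  pools <- names(g$resources)
  for (a in acts) {
    bad <- setdiff(a$predecessors, nm)
    if (length(bad))
      v <- c(v, sprintf("activity '%s': unresolved predecessor(s) %s",
                        a$name, paste(bad, collapse = ", ")))
    if (a$name %in% a$predecessors)
      v <- c(v, sprintf("activity '%s': precedes itself", a$name))
    badp <- setdiff(names(a$resources), pools)
    if (length(badp))
      v <- c(v, sprintf("activity '%s': unresolved resource pool(s) %s",
                        a$name, paste(badp, collapse = ", ")))
  }
  for (r in g$resources)
    if (r$capacity < 1L)
      v <- c(v, sprintf("pool '%s': capacity must be >= 1", r$name))
  if (!g$end_activity %in% nm)
    v <- c(v, sprintf("end activity '%s' not defined", g$end_activity))
  src <- nm[vapply(acts, function(a) length(
    intersect(a$predecessors, nm)) == 0L, TRUE)]
  if (length(src) != 1L)
    v <- c(v, sprintf("expected exactly one source activity, found %d (%s)",
                      length(src), paste(src, collapse = ", ")))
  cyc <- find_cycle(acts)
  if (!is.null(cyc))
    v <- c(v, sprintf("precedence cycle involving {%s}",
                      paste(cyc, collapse = ", ")))
  v
}

# Kahn's algorithm; returns NULL (acyclic) or the activity names left over.
find_cycle <- function(acts) {
  nm <- names(acts)
  indeg <- vapply(acts, function(a)
    length(intersect(a$predecessors, nm)), 0L)
  succs <- stats::setNames(vector("list", length(nm)), nm)
  for (a in acts)
    for (p in intersect(a$predecessors, nm))
      succs[[p]] <- c(succs[[p]], a$name)
  queue <- nm[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    x <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (s in succs[[x]]) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) queue <- c(queue, s)
    }
  }
  if (seen == length(nm)) NULL else nm[indeg > 0L]
}

topological_order <- function(g) {
  acts <- g$activities
  nm <- names(acts)
  indeg <- vapply(acts, function(a) length(intersect(a$predecessors, nm)), 0L)
  succs <- stats::setNames(vector("list", length(nm)), nm)
  for (a in acts)
    for (p in intersect(a$predecessors, nm))
      succs[[p]] <- c(succs[[p]], a$name)
  queue <- nm[indeg == 0L]
  out <- character()
  while (length(queue)) {
    x <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, x)
    for (s in succs[[x]]) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) queue <- c(queue, s)
    }
  }
  if (length(out) != length(nm)) stop("process graph contains a cycle",
                                      call. = FALSE)
  out
}
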