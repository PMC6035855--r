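# Shared fixtures: small deterministic graphs and transforms built in code.

no_needs <- function() need_probabilities(0, 0, 0, 0)

# linear chain of fixed durations
chain_graph <- function(durs, arrivals = 3, window = 60) {
  nms <- paste0("a", seq_along(durs))
  acts <- lapply(seq_along(durs), function(i)
    activity(nms[i], duration_model("fixed", durs[i]),
             predecessors = if (i > 1L) nms[i - 1L] else character()))
  process_graph(acts, list(), no_needs(), arrivals_per_day = arrivals,
                arrival_window = window, end_activity = nms[length(nms)])
}

# two parallel branches joining at the end
fork_graph <- function(d1, d2) {
  acts <- list(
    activity("src", duration_model("fixed", 0)),
    activity("b1", duration_model("fixed", d1), predecessors = "src"),
    activity("b2", duration_model("fixed", d2), predecessors = "src"),
    activity("join", duration_model("fixed", 0),
             predecessors = c("b1", "b2")))
  process_graph(acts, list(), no_needs(), arrivals_per_day = 3,
                arrival_window = 60, end_activity = "join")
}

# replace every duration/offset by its mean and lift all resource limits,
# so the engine must reproduce the critical-path oracle exactly
degenerate_graph <- function(g) {
  for (nm in names(g$activities)) {
    a <- g$activities[[nm]]
    g$activities[[nm]]$duration <-
      duration_model("fixed", mean(a$duration))
    if (!is.null(a$start_offset))
      g$activities[[nm]]$start_offset <-
        duration_model("fixed", mean(a$start_offset))
  }
  for (nm in names(g$resources)) g$resources[[nm]]$capacity <- 10000L
  g
}

# graph whose needs are deterministic 0/1 flags
with_flags <- function(g, narc, equip, sup, addon) {
  g$needs <- need_probabilities(narc, equip, sup, addon)
  g
}

# independent longest-path oracle: exhaustive enumeration of source->end
# paths, activity contribution = mean offset + mean duration when enabled,
# 0 when gated off (pass-through)
enumerate_longest_path <- function(g, profile) {
  flags <- c(narcotics = isTRUE(profile$needs_narcotics),
             equipment = isTRUE(profile$needs_equipment),
             supplies = isTRUE(profile$needs_supplies),
             addon = isTRUE(profile$gets_addon))
  contrib <- vapply(g$activities, function(a) {
    if (!is.null(a$condition) && !flags[[a$condition]]) return(0)
    off <- if (is.null(a$start_offset)) 0 else mean(a$start_offset)
    off + mean(a$duration)
  }, 0)
  succs <- lapply(names(g$activities), function(nm)
    names(Filter(function(a) nm %in% a$predecessors, g$activities)))
  names(succs) <- names(g$activities)
  src <- names(g$activities)[vapply(g$activities, function(a)
    length(a$predecessors) == 0L, TRUE)]
  best <- -Inf
  walk <- function(node, acc) {
    acc <- acc + contrib[[node]]
    if (node == g$end_activity) { best <<- max(best, acc); return() }
    for (s in succs[[node]]) walk(s, acc)
  }
  walk(src, 0)
  best
}

profile_row <- function(narc = FALSE, equip = FALSE, sup = FALSE,
                        addon = FALSE) {
  list(needs_narcotics = narc, needs_equipment = equip,
       needs_supplies = sup, gets_addon = addon)
}
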