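#' Read and write process-graph configuration files
#'
#' A graph is stored as a plain document with sections `resources`,
#' `activities`, `needs`, `arrivals` and `params`.  JSON (via jsonlite, full
#' double precision) and YAML are supported, chosen by file extension.
#' `read_process_graph(write_process_graph(g, path))` reproduces `g`
#' exactly for JSON.
#'
#' @param g a [process_graph()].
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return `write_process_graph` returns `path` invisibly;
#'   `read_process_graph` returns a validated [process_graph()].
#' @export
write_process_graph <- function(g, path) {
  stopifnot(inherits(g, "process_graph"))
  x <- graph_to_list(g)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else stop("unsupported config extension: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_process_graph
#' @export
read_process_graph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported config extension: ", ext, call. = FALSE)
  g <- graph_from_list(x)
  v <- validate_graph(g)
  if (length(v))
    stop("invalid process-graph config:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  g
}

dm_to_list <- function(d) {
  if (is.null(d)) return(NULL)
  list(family = d$family, params = as.numeric(d$params),
       truncate_at_zero = d$truncate_at_zero)
}

dm_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  duration_model(x$family, unlist(x$params),
                 truncate_at_zero = isTRUE(x$truncate_at_zero))
}

graph_to_list <- function(g) {
  list(
    resources = lapply(unname(g$resources), function(r)
      list(name = r$name, capacity = r$capacity)),
    activities = lapply(unname(g$activities), function(a) {
      list(name = a$name,
           duration = dm_to_list(a$duration),
           resources = as.list(a$resources),
           predecessors = as.list(a$predecessors),
           start_offset = dm_to_list(a$start_offset),
           condition = a$condition,
           performer_note = a$performer_note)
    }),
    needs = c(as.list(g$needs$p), list(correlation = g$needs$correlation)),
    arrivals = list(per_day = g$arrivals_per_day,
                    window_minutes = g$arrival_window),
    end_activity = g$end_activity,
    params = g$params)
}

graph_from_list <- function(x) {
  acts <- lapply(x$activities, function(a) {
    res <- unlist(a$resources)
    activity(a$name,
             duration = dm_from_list(a$duration),
             resources = if (length(res)) res else integer(),
             predecessors = unlist(a$predecessors) %||% character(),
             start_offset = dm_from_list(a$start_offset),
             condition = a$condition,
             performer_note = a$performer_note %||% "")
  })
  pools <- lapply(x$resources, function(r) resource_pool(r$name, r$capacity))
  nd <- x$needs
  needs <- need_probabilities(nd$narcotics, nd$equipment, nd$supplies,
                              nd$addon, correlation = nd$correlation %||% 0)
  process_graph(acts, pools, needs,
                arrivals_per_day = x$arrivals$per_day,
                arrival_window = x$arrivals$window_minutes,
                end_activity = x$end_activity,
                params = x$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
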