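#' Before/after improvement report
#'
#' Control-phase summary comparing discharge durations before and after an
#' intervention: I-MR charts and normal-model capability for both phases,
#' and the percent reduction in the mean,
#' `100 * (mean_before - mean_after) / mean_before` (percentages reported
#' to one decimal, minutes to two).
#'
#' @param before,after numeric vectors of total discharge minutes (or
#'   record data.frames with a `total_minutes` column).
#' @param usl upper specification limit for the capability analysis.
#' @param scenario_table optional [run_scenario_suite()] result to embed as
#'   the improvement Pareto table.
#' @return object of class `discharge_report`: `imr_before`, `imr_after`,
#'   `capability_before`, `capability_after`, `mean_before`, `mean_after`,
#'   `percent_reduction`, `scenario_table`.
#' @export
discharge_report <- function(before, after, usl = 150,
                             scenario_table = NULL) {
  before <- extract_minutes(before)
  after <- extract_minutes(after)
  if (!length(before) || !length(after))
    stop("before/after series must be non-empty", call. = FALSE)
  mb <- mean(before)
  ma <- mean(after)
  structure(list(
    imr_before = imr_chart(before, phase_label = "before"),
    imr_after = imr_chart(after, phase_label = "after"),
    capability_before = capability(before, usl = usl),
    capability_after = capability(after, usl = usl),
    mean_before = mb, mean_after = ma,
    percent_reduction = round(100 * (mb - ma) / mb, 1),
    scenario_table = scenario_table),
    class = "discharge_report")
}

extract_minutes <- function(x) {
  if (is.data.frame(x)) x <- x$total_minutes
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing durations in report input", call. = FALSE)
  x
}

#' @export
print.discharge_report <- function(x, ...) {
  cat("== Discharge improvement report ==\n")
  cat(sprintf("mean before %.2f min, after %.2f min: %.1f%% reduction\n",
              x$mean_before, x$mean_after, x$percent_reduction))
  cat(sprintf("capability (USL %.0f): SQL %.2f -> %.2f (Z_bench %.2f -> %.2f)\n",
              x$capability_before$usl,
              round(x$capability_before$sql, 2),
              round(x$capability_after$sql, 2),
              round(x$capability_before$z_bench, 2),
              round(x$capability_after$z_bench, 2)))
  print(x$imr_before)
  print(x$imr_after)
  if (!is.null(x$scenario_table)) {
    cat("scenario Pareto table:\n")
    print(as.data.frame(x$scenario_table), digits = 4)
  }
  invisible(x)
}
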