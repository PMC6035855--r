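#' Individuals / moving-range control chart
#'
#' Computes an I-MR chart for subgroup-size-1 duration data.  Moving ranges
#' are `MR_i = |x_i - x_(i-1)|`; control limits use the standard constants
#' `E2 = 2.66` (individuals, equal to `3/d2` with `d2 = 1.128`) and
#' `D4 = 3.267` (moving range):
#' \deqn{UCL_x = \bar x + 2.66\,\overline{MR}, \quad
#'       LCL_x = \bar x - 2.66\,\overline{MR}, \quad
#'       UCL_{MR} = 3.267\,\overline{MR}.}
#' A point is flagged out of control when it falls beyond the individual
#' limits or its moving range exceeds `UCL_MR` (beyond-limit rules only; no
#' run rules).
#'
#' @param series ordered numeric vector of durations (minutes), length >= 2.
#' @param phase_label optional label such as `"before"` or `"after"`.
#' @return object of class `imr_chart`: `xbar`, `mrbar`, `ucl_x`, `lcl_x`,
#'   `ucl_mr`, `out_of_control_indices` (increasing), `series`, `mr`,
#'   `phase_label`.
#' @examples
#' imr_chart(c(200, 210, 190, 220))
#' @export
imr_chart <- function(series, phase_label = NULL) {
  series <- as.numeric(series)
  if (length(series) < 2L)
    stop("IMR chart needs at least 2 observations", call. = FALSE)
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  mr <- abs(diff(series))
  xbar <- mean(series)
  mrbar <- mean(mr)
  ucl_x <- xbar + 2.66 * mrbar
  lcl_x <- xbar - 2.66 * mrbar
  ucl_mr <- 3.267 * mrbar
  ooc_x <- which(series > ucl_x | series < lcl_x)
  ooc_mr <- which(mr > ucl_mr) + 1L   # MR_i is attached to observation i
  structure(list(xbar = xbar, mrbar = mrbar, ucl_x = ucl_x, lcl_x = lcl_x,
                 ucl_mr = ucl_mr,
                 out_of_control_indices = sort(unique(c(ooc_x, ooc_mr))),
                 series = series, mr = mr, phase_label = phase_label),
            class = "imr_chart")
}

#' @export
print.imr_chart <- function(x, ...) {
  cat(sprintf("<imr_chart>%s n = %d\n",
              if (!is.null(x$phase_label)) paste0(" [", x$phase_label, "]")
              else "", length(x$series)))
  cat(sprintf("  xbar %.2f, mrbar %.2f; I limits [%.2f, %.2f]; MR UCL %.2f\n",
              x$xbar, x$mrbar, x$lcl_x, x$ucl_x, x$ucl_mr))
  cat(sprintf("  out-of-control points: %s\n",
              if (length(x$out_of_control_indices))
                paste(x$out_of_control_indices, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Plot an I-MR chart
#'
#' Two stacked panels (individuals and moving range) with centre lines and
#' control limits; out-of-control points are marked.
#'
#' @param x an [imr_chart()].
#' @param ... passed to [plot()].
#' @export
plot.imr_chart <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  n <- length(x$series)
  ooc <- x$out_of_control_indices
  graphics::plot(seq_len(n), x$series, type = "b", pch = 20,
                 xlab = "", ylab = "minutes",
                 main = paste("Individuals", x$phase_label %||% ""), ...)
  graphics::abline(h = c(x$lcl_x, x$xbar, x$ucl_x),
                   lty = c(2, 1, 2), col = c(2, 1, 2))
  if (length(ooc))
    graphics::points(ooc, x$series[ooc], col = 2, pch = 19)
  graphics::plot(2:n, x$mr, type = "b", pch = 20, xlab = "observation",
                 ylab = "moving range", main = "Moving range")
  graphics::abline(h = c(x$mrbar, x$ucl_mr), lty = c(1, 2), col = c(1, 2))
  invisible(x)
}

#' Process capability against an upper specification limit
#'
#' Normal-model capability of the discharge process against a maximum
#' acceptable duration (`usl`, default 150 minutes): the out-of-spec
#' proportion is `P(X > USL)`, the benchmark Z is the standard-normal
#' quantile of the in-spec proportion,
#' `z_bench = (usl - mu) / sigma`, and the sigma quality level applies the
#' conventional 1.5-sigma long-term shift, `SQL = z_bench + 1.5`.
#' With a data series, `mu`/`sigma` are the overall (long-term) sample mean
#' and SD by default; `sigma = "within"` uses the short-term estimate
#' `mrbar / 1.128` from consecutive moving ranges instead.
#'
#' @param x numeric series of durations, or a single mean when `sigma`
#'   is given numerically.
#' @param usl upper specification limit in minutes.
#' @param sigma `"overall"` (default), `"within"`, or a positive number
#'   (then `x` must be the mean).
#' @return object of class `capability_result`: `usl`, `mu_hat`,
#'   `sigma_hat`, `z_bench`, `sql`, `p_above_usl`.
#' @examples
#' capability(215.7, usl = 150, sigma = 67)
#' @export
capability <- function(x, usl = 150, sigma = c("overall", "within")) {
  if (is.numeric(sigma)) {
    if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
    if (length(x) != 1L)
      stop("with numeric sigma, x must be a single mean", call. = FALSE)
    mu_hat <- x
    sigma_hat <- sigma
  } else {
    sigma <- match.arg(sigma)
    if (length(x) < 2L)
      stop("capability from data needs at least 2 observations",
           call. = FALSE)
    mu_hat <- mean(x)
    sigma_hat <- if (sigma == "overall") stats::sd(x)
                 else mean(abs(diff(x))) / 1.128
    if (sigma_hat <= 0) stop("sigma must be > 0", call. = FALSE)
  }
  z <- (usl - mu_hat) / sigma_hat
  structure(list(usl = usl, mu_hat = mu_hat, sigma_hat = sigma_hat,
                 z_bench = z, sql = sql_from_zbench(z),
                 p_above_usl = stats::pnorm(z, lower.tail = FALSE)),
            class = "capability_result")
}

#' @export
print.capability_result <- function(x, ...) {
  cat(sprintf("<capability> USL %.0f min: mu %.2f, sigma %.2f\n",
              x$usl, x$mu_hat, x$sigma_hat))
  cat(sprintf("  Z_bench %.2f, SQL %.2f, P(above USL) %.4f\n",
              round(x$z_bench, 2), round(x$sql, 2), x$p_above_usl))
  invisible(x)
}

#' Sigma quality level from a benchmark Z
#'
#' Applies the Six Sigma 1.5-sigma long-term shift convention:
#' `SQL = z + 1.5`, exactly.
#'
#' @param z benchmark Z value.
#' @return sigma quality level.
#' @examples
#' sql_from_zbench(-0.78)  # 0.72
#' sql_from_zbench(1.17)   # 2.67
#' @export
sql_from_zbench <- function(z) z + 1.5

#' Minimum sample size for estimating a mean
#'
#' `n = ceiling((z * s / e)^2)`, at least 1: the number of observations
#' needed so that a confidence interval at quantile `z` with sample SD `s`
#' has half-width at most `e`.
#'
#' @param z standard-normal quantile (1.96 for 95% confidence).
#' @param s sample standard deviation (minutes), `>= 0`.
#' @param e acceptable error bound (minutes), `> 0`.
#' @return integer sample size.
#' @examples
#' required_sample_size(1.96, 67, 30)  # 20
#' @export
required_sample_size <- function(z, s, e) {
  if (!is.numeric(e) || e <= 0) stop("error bound e must be > 0",
                                     call. = FALSE)
  if (!is.numeric(s) || s < 0) stop("sample sd s must be >= 0",
                                    call. = FALSE)
  max(1L, as.integer(ceiling((z * s / e)^2)))
}

#' Classify discharges into standard and complex populations
#'
#' With need flags available the label follows the definition directly
#' (complex iff equipment, supplies or add-on medication).  With durations
#' only, a two-component univariate Gaussian mixture is fitted by
#' expectation-maximisation, initialised deterministically from a split at
#' the lower/upper quartiles, and each record is assigned to its most
#' probable component (the higher-mean component is labelled complex).
#'
#' @param records a data.frame of discharge records (needs the flag columns
#'   `needs_equipment`, `needs_supplies`, `gets_addon`), or a numeric vector
#'   of total durations.
#' @param max_iter,tol EM iteration controls (mixture mode).
#' @return list: `labels` (factor standard/complex), `stats` (per-population
#'   n, mean, sd), `method` (`"flags"` or `"mixture"`), and for mixture mode
#'   `mixture` (weights, means, sds, loglik, degenerate flag).
#' @export
classify_populations <- function(records, max_iter = 500L, tol = 1e-8) {
  if (is.data.frame(records) &&
      all(c("needs_equipment", "needs_supplies", "gets_addon") %in%
          names(records))) {
    labels <- derive_population(records)
    x <- records$total_minutes
    stats <- pop_stats(x, labels)
    return(list(labels = labels, stats = stats, method = "flags"))
  }
  x <- if (is.data.frame(records)) records$total_minutes
       else as.numeric(records)
  if (is.null(x)) stop("records must contain total_minutes", call. = FALSE)
  if (length(x) < 4L)
    stop("mixture classification needs at least 4 records", call. = FALSE)
  fit <- em_two_normals(x, max_iter = max_iter, tol = tol)
  labels <- factor(ifelse(fit$posterior[, 2] > 0.5, "complex", "standard"),
                   levels = c("standard", "complex"))
  list(labels = labels, stats = pop_stats(x, labels), method = "mixture",
       mixture = fit[c("weights", "means", "sds", "loglik", "iterations",
                       "degenerate")])
}

pop_stats <- function(x, labels) {
  if (is.null(x)) return(NULL)
  out <- data.frame(population = levels(labels),
                    n = as.vector(table(labels)))
  out$mean <- vapply(levels(labels),
                     function(l) mean(x[labels == l]), 0)
  out$sd <- vapply(levels(labels),
                   function(l) stats::sd(x[labels == l]), 0)
  out
}

# two-component univariate normal mixture by EM with a deterministic
# quartile-split initialisation; components sorted by mean
em_two_normals <- function(x, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  if (stats::sd(x) == 0 || length(unique(x)) < 2L) {
    warning("degenerate fit: durations are (nearly) identical; ",
            "a single component describes the data")
    post <- cbind(rep(1, n), rep(0, n))
    return(list(weights = c(1, 0), means = c(mean(x), mean(x)),
                sds = c(0, 0), posterior = post, loglik = NA_real_,
                iterations = 0L, degenerate = TRUE))
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- c(q[1], q[2])
  if (mu[1] == mu[2]) mu <- range(x)
  s <- rep(max(stats::sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    g1 <- 1 - g2
    w <- c(mean(g1), mean(g2))
    mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
    s <- sqrt(c(sum(g1 * (x - mu[1])^2) / sum(g1),
                sum(g2 * (x - mu[2])^2) / sum(g2)))
    s <- pmax(s, 1e-8)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  post <- cbind(g1, g2)[, ord, drop = FALSE]
  list(weights = w[ord], means = mu[ord], sds = s[ord], posterior = post,
       loglik = ll, iterations = it,
       degenerate = any(s < 1e-6) || any(w < 1e-3))
}
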