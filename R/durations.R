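#' Activity duration models
#'
#' A `duration_model` describes the stochastic service time of one discharge
#' activity, in minutes.  Supported families:
#'
#' * `weibull`: shape `beta`, scale `eta` (minutes);
#' * `normal`: mean `mu`, sd `sigma` of the variate;
#' * `lognormal`: mean `mu`, sd `sigma` **of the variate** (not of its log);
#' * `exponential`: mean (minutes);
#' * `triangular`: `min`, `mode`, `max`;
#' * `fixed`: a degenerate point mass.
#'
#' Service times are non-negative; with `truncate_at_zero = TRUE` (default)
#' negative draws from unbounded families are discarded and redrawn, never
#' clipped to zero, so the conditional shape of the distribution is kept.
#'
#' @param family one of `"weibull"`, `"normal"`, `"lognormal"`,
#'   `"exponential"`, `"triangular"`, `"fixed"`.
#' @param params numeric parameter vector in the order listed above.
#' @param truncate_at_zero logical; resample negative draws.
#' @return An object of class `duration_model`.
#' @examples
#' dm <- duration_model("weibull", c(1.7374, 22.091))
#' mean(dm)            # eta * gamma(1 + 1/beta)
#' sample_duration(dm, 5)
#' @export
duration_model <- function(family, params, truncate_at_zero = TRUE) {
  family <- match.arg(family,
    c("weibull", "normal", "lognormal", "exponential", "triangular", "fixed"))
  params <- as.numeric(params)
  n_expect <- switch(family,
    weibull = 2L, normal = 2L, lognormal = 2L,
    exponential = 1L, triangular = 3L, fixed = 1L)
  if (length(params) != n_expect)
    stop(sprintf("family '%s' needs %d parameter(s), got %d",
                 family, n_expect, length(params)), call. = FALSE)
  if (any(!is.finite(params)))
    stop("duration model parameters must be finite", call. = FALSE)
  switch(family,
    weibull = if (any(params <= 0))
      stop("weibull shape and scale must be > 0", call. = FALSE),
    normal = if (params[2] <= 0)
      stop("normal sd must be > 0", call. = FALSE),
    lognormal = if (any(params <= 0))
      stop("lognormal mean and sd (of the variate) must be > 0", call. = FALSE),
    exponential = if (params[1] <= 0)
      stop("exponential mean must be > 0", call. = FALSE),
    triangular = {
      if (params[1] < 0 || params[1] > params[2] || params[2] > params[3])
        stop("triangular needs 0 <= min <= mode <= max", call. = FALSE)
    },
    fixed = if (params[1] < 0)
      stop("fixed duration must be >= 0", call. = FALSE))
  structure(list(family = family, params = params,
                 truncate_at_zero = isTRUE(truncate_at_zero)),
            class = "duration_model")
}

#' @export
print.duration_model <- function(x, ...) {
  cat(sprintf("<duration_model> %s(%s) min%s\n", x$family,
              paste(format(x$params, digits = 6), collapse = ", "),
              if (x$truncate_at_zero) "" else " [untruncated]"))
  invisible(x)
}

#' @export
mean.duration_model <- function(x, ...) {
  p <- x$params
  switch(x$family,
    weibull = p[2] * gamma(1 + 1 / p[1]),
    # truncated-normal mean when truncation is active
    normal = if (x$truncate_at_zero) {
      a <- -p[1] / p[2]
      p[1] + p[2] * stats::dnorm(a) / (1 - stats::pnorm(a))
    } else p[1],
    lognormal = p[1],
    exponential = p[1],
    triangular = sum(p) / 3,
    fixed = p[1])
}

# meanlog/sdlog of a lognormal given mean and sd of the variate
lnorm_pars <- function(mu, sigma) {
  sdlog2 <- log(1 + (sigma / mu)^2)
  c(meanlog = log(mu) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Sample activity durations
#'
#' Draws `n` service times (minutes) from a [duration_model()] using the
#' current R random stream.  Negative draws are resampled (not clipped) when
#' the model truncates at zero; the `fixed` family ignores the stream.
#'
#' @param d a `duration_model`.
#' @param n number of draws.
#' @return numeric vector of `n` non-negative durations.
#' @export
sample_duration <- function(d, n = 1L) {
  if (!inherits(d, "duration_model"))
    stop("invalid duration model: expected a 'duration_model' object",
         call. = FALSE)
  p <- d$params
  draw <- function(m) switch(d$family,
    weibull = stats::rweibull(m, shape = p[1], scale = p[2]),
    normal = stats::rnorm(m, mean = p[1], sd = p[2]),
    lognormal = {
      lp <- lnorm_pars(p[1], p[2])
      stats::rlnorm(m, meanlog = lp[1], sdlog = lp[2])
    },
    exponential = stats::rexp(m, rate = 1 / p[1]),
    triangular = rtri(m, p[1], p[2], p[3]),
    fixed = rep.int(p[1], m),
    stop(sprintf("unknown duration family '%s'", d$family), call. = FALSE))
  x <- draw(n)
  if (d$truncate_at_zero) {
    bad <- which(x < 0)
    while (length(bad)) {
      x[bad] <- draw(length(bad))
      bad <- bad[x[bad] < 0]
    }
  }
  x
}

# inverse-CDF triangular sampler
rtri <- function(n, a, b, c) {
  u <- stats::runif(n)
  fc <- (b - a) / (c - a)
  ifelse(u < fc,
         a + sqrt(u * (c - a) * (b - a)),
         c - sqrt((1 - u) * (c - a) * (c - b)))
}
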