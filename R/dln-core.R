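#' Delta-lognormal population parameters
#'
#' Constructs a parameter triple for a delta-lognormal population
#' \eqn{\Delta(\mu, \sigma^2, \delta)}: an observation is exactly zero with
#' probability \eqn{\delta} and otherwise lognormal, i.e.
#' \eqn{\log X \sim N(\mu, \sigma^2)}.
#'
#' These are *truth* parameters for simulation; the zero probability must lie
#' strictly inside (0, 1). Estimated zero proportions of 0 or 1 can still occur
#' in data and are handled by [group_summary()].
#'
#' @param mu Log-scale mean (real).
#' @param sigma2 Log-scale variance (positive).
#' @param delta Probability of a zero observation, in (0, 1).
#' @return An object of class `"dln_params"`.
#' @examples
#' dln_params(mu = 3, sigma2 = 1, delta = 0.1)
#' @export
dln_params <- function(mu, sigma2, delta) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0) {
    stop("'sigma2' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0 || delta >= 1) {
    stop("'delta' must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(mu = mu, sigma2 = sigma2, delta = delta),
            class = "dln_params")
}

#' @export
print.dln_params <- function(x, ...) {
  cat(sprintf("Delta-lognormal parameters: mu = %g, sigma2 = %g, delta = %g\n",
              x$mu, x$sigma2, x$delta))
  invisible(x)
}

#' Sufficient statistics of one delta-lognormal sample
#'
#' Builds a group summary from the counts and log-scale maximum-likelihood
#' estimates directly. This "summary-statistics entry mode" matters in
#' practice: published analyses are often reproducible only from printed
#' summaries, not raw records.
#'
#' The log-scale variance estimate uses the MLE divisor \eqn{n_1} (the number
#' of positive observations), not \eqn{n_1 - 1}; every downstream interval
#' formula in this package expects that convention.
#'
#' @param n Total sample size.
#' @param n0 Number of zero observations.
#' @param mu_hat Mean of the logs of the positive observations.
#' @param sigma2_hat MLE variance of the logs of the positive observations
#'   (divisor `n - n0`).
#' @return An object of class `"dln_summary"` with fields `n`, `n0`, `n1`,
#'   `mu_hat`, `sigma2_hat`, `delta_hat`.
#' @seealso [summarize_group()] to compute the summary from raw values.
#' @examples
#' north <- group_summary(n = 62, n0 = 22, mu_hat = 2.541, sigma2_hat = 0.886)
#' north
#' @export
group_summary <- function(n, n0, mu_hat, sigma2_hat) {
  stopifnot(length(n) == 1L, length(n0) == 1L,
            n == as.integer(n), n0 == as.integer(n0), n0 >= 0, n0 <= n)
  n1 <- as.integer(n) - as.integer(n0)
  if (n1 < 2L) stop("insufficient positive observations (need at least 2)",
                    call. = FALSE)
  if (!is.finite(sigma2_hat) || sigma2_hat <= 0) {
    stop("'sigma2_hat' must be positive", call. = FALSE)
  }
  if (n0 == 0L) {
    warning("no zero observations in this group (delta_hat = 0)",
            call. = FALSE)
  }
  structure(list(n = as.integer(n), n0 = as.integer(n0), n1 = n1,
                 mu_hat = mu_hat, sigma2_hat = sigma2_hat,
                 delta_hat = n0 / n),
            class = "dln_summary")
}

#' Summarize raw non-negative observations
#'
#' Computes the sufficient statistics of a delta-lognormal sample: the zero
#' count and the log-scale MLEs of the positive part. Zeros are detected by
#' exact equality with 0 (the convention for recorded rainfall amounts);
#' there is no tolerance.
#'
#' @param values Numeric vector of non-negative observations.
#' @return A `"dln_summary"` object; see [group_summary()].
#' @examples
#' summarize_group(c(0, 0, exp(1), exp(3)))
#' @export
summarize_group <- function(values) {
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be numeric with no missing entries", call. = FALSE)
  }
  if (any(values < 0)) stop("negative input: all values must be >= 0",
                            call. = FALSE)
  n <- length(values)
  pos <- values[values > 0]
  if (length(pos) < 2L) {
    stop("insufficient positive observations (need at least 2)", call. = FALSE)
  }
  y <- log(pos)
  group_summary(n = n, n0 = n - length(pos), mu_hat = mean(y),
                sigma2_hat = mean((y - mean(y))^2))
}

#' @export
print.dln_summary <- function(x, ...) {
  cat("Delta-lognormal group summary\n")
  cat(sprintf("  n = %d (zeros %d, positives %d), delta_hat = %.4f\n",
              x$n, x$n0, x$n1, x$delta_hat))
  cat(sprintf("  log-scale: mu_hat = %.4f, sigma2_hat = %.4f (MLE divisor n1)\n",
              x$mu_hat, x$sigma2_hat))
  cat(sprintf("  plug-in variance omega_hat = %.4f\n", dln_variance(x)))
  invisible(x)
}

## internal: pull (mu, sigma2, one_minus_delta) out of either object
.dln_triplet <- function(x) {
  if (inherits(x, "dln_params")) {
    list(mu = x$mu, sigma2 = x$sigma2, delta = x$delta)
  } else if (inherits(x, "dln_summary")) {
    list(mu = x$mu_hat, sigma2 = x$sigma2_hat, delta = x$delta_hat)
  } else {
    stop("expected a 'dln_params' or 'dln_summary' object", call. = FALSE)
  }
}

#' Variance of a delta-lognormal population
#'
#' Evaluates
#' \deqn{\omega = (1 - \delta)\, e^{2\mu + \sigma^2} \left[e^{\sigma^2} -
#'   (1 - \delta)\right],}
#' the population variance of \eqn{\Delta(\mu, \sigma^2, \delta)}. Applied to
#' a [group_summary()] it is the plug-in (MLE) estimate \eqn{\hat\omega}.
#' The bracket is always positive because \eqn{e^{\sigma^2} > 1 \ge 1 - \delta}.
#'
#' @param x A `"dln_params"` or `"dln_summary"` object.
#' @return The variance \eqn{\omega > 0}.
#' @examples
#' dln_variance(group_summary(62, 22, 2.541, 0.886)) # about 448.8
#' @export
dln_variance <- function(x) {
  p <- .dln_triplet(x)
  if (p$delta >= 1) stop("degenerate: all-zero population", call. = FALSE)
  (1 - p$delta) * exp(2 * p$mu + p$sigma2) * (exp(p$sigma2) - (1 - p$delta))
}

#' Log-ratio of two delta-lognormal variances
#'
#' The comparison parameter \eqn{\theta = \ln\omega_1 - \ln\omega_2};
#' \eqn{\theta = 0} means equal dispersion and \eqn{e^\theta} is the variance
#' ratio. Antisymmetric under swapping the two groups.
#'
#' @param x1,x2 `"dln_params"` or `"dln_summary"` objects for the two groups.
#' @return The log variance ratio \eqn{\theta}.
#' @examples
#' north <- group_summary(62, 22, 2.541, 0.886)
#' northeast <- group_summary(210, 65, 2.576, 1.576)
#' log_variance_ratio(north, northeast) # about -1.673
#' @export
log_variance_ratio <- function(x1, x2) {
  log(dln_variance(x1)) - log(dln_variance(x2))
}

#' Sample from a delta-lognormal distribution
#'
#' Each draw is 0 with probability `delta`, otherwise
#' \eqn{\exp(N(\mu, \sigma^2))}.
#'
#' @param n Number of observations.
#' @param params A `"dln_params"` object.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of `n` non-negative values.
#' @examples
#' rdln(10, dln_params(3, 1, 0.1), seed = 1)
#' @export
rdln <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "dln_params"), n >= 1)
  local_seed(seed)
  zero <- stats::runif(n) < params$delta
  x <- exp(stats::rnorm(n, params$mu, sqrt(params$sigma2)))
  x[zero] <- 0
  x
}

## internal: set the RNG seed for the remainder of the calling function only,
## restoring the caller's stream on exit. seed = NULL is a no-op.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  do.call(on.exit, list(quote({
    if (is.null(.dln_old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", .dln_old_seed, envir = globalenv())
    }
  }), add = TRUE), envir = env)
  assign(".dln_old_seed", old, envir = env)
  set.seed(seed)
  invisible(NULL)
}
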