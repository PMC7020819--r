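## Generalized and fiducial generalized pivotal quantities for theta.
##
## Both constructions pivot the log-scale (mu, sigma2) identically:
## sigma2 through Sum(y - ybar)^2-style chi-square inversion and mu through a
## studentized normal deviate. They differ only in how the zero proportion is
## pivoted: an arcsine variance-stabilizing transform (GCI) versus a beta
## fiducial draw (FGCI).

#' Pivotal quantity for the zero proportion (arcsine VST)
#'
#' \deqn{R_\delta = \sin^2\!\left[\arcsin\sqrt{\hat\delta} -
#'   \frac{w}{2\sqrt{n}}\right]}
#' where `w` is a standard-normal deviate. The \eqn{\sin^2} automatically
#' confines the result to \eqn{[0, 1]}; boundary values of `delta_hat` are
#' valid inputs and no clamping is applied beyond that.
#'
#' @param delta_hat Observed zero proportion, in \eqn{[0, 1]}.
#' @param n Total group sample size.
#' @param w Standard-normal deviate(s); vectorized.
#' @return Pivoted proportion(s) in \eqn{[0, 1]}.
#' @examples
#' gpq_delta(0.25, 16, 1) # sin^2(pi/6 - 1/8), about 0.1506
#' @export
gpq_delta <- function(delta_hat, n, w) {
  stopifnot(delta_hat >= 0, delta_hat <= 1, n >= 1)
  sin(asin(sqrt(delta_hat)) - w / (2 * sqrt(n)))^2
}

## internal: m draws of the pivotal quantity for ln(omega) of one group.
## fiducial = FALSE gives the GCI construction, TRUE the FGCI one.
.ln_omega_pivot <- function(s, m, fiducial) {
  n1 <- s$n1
  u <- stats::rchisq(m, df = n1 - 1)
  r_sigma2 <- (n1 - 1) * s$sigma2_hat / u   # same for both constructions
  r_mu <- s$mu_hat - stats::rnorm(m) * sqrt(r_sigma2 / n1)
  if (fiducial) {
    ## positive-class probability pivoted as a beta fiducial draw
    p <- stats::rbeta(m, n1 + 0.5, s$n0 + 0.5)
  } else {
    p <- 1 - gpq_delta(s$delta_hat, s$n, stats::rnorm(m))
  }
  ## bracket exp(r_sigma2) - p > 0 always: exp(r_sigma2) > 1 >= p
  log(p) + (2 * r_mu + r_sigma2) + log(exp(r_sigma2) - p)
}

.pivotal_draws <- function(s1, s2, m, fiducial, seed) {
  stopifnot(inherits(s1, "dln_summary"), inherits(s2, "dln_summary"), m >= 100)
  local_seed(seed)
  theta <- .ln_omega_pivot(s1, m, fiducial) - .ln_omega_pivot(s2, m, fiducial)
  if (!all(is.finite(theta))) {
    stop("internal error: non-finite pivotal draw", call. = FALSE)
  }
  structure(list(theta = theta, m = m,
                 method = if (fiducial) "fgci" else "gci"),
            class = "pivotal_draws")
}

#' Monte-Carlo draws of the generalized pivotal quantity for theta
#'
#' Each draw uses fresh auxiliary variates per group: a standard-normal
#' deviate for the arcsine-pivoted zero proportion, a chi-square
#' \eqn{\chi^2_{n_1 - 1}} variate inverting the log-scale variance MLE, and a
#' standard-normal deviate studentizing the log-scale mean.
#'
#' @param s1,s2 Group summaries ([group_summary()]).
#' @param m Number of Monte-Carlo draws (at least 100).
#' @param seed Optional integer seed.
#' @return A `"pivotal_draws"` object with element `theta` of length `m`.
#' @export
gci_draws <- function(s1, s2, m = 2500, seed = NULL) {
  .pivotal_draws(s1, s2, m, fiducial = FALSE, seed = seed)
}

#' Monte-Carlo draws of the fiducial generalized pivotal quantity for theta
#'
#' Identical to [gci_draws()] in how the log-scale mean and variance are
#' pivoted (the chi-square inversions coincide algebraically); the
#' positive-class probability is drawn from its beta fiducial distribution
#' \eqn{\mathrm{beta}(n_1 + \tfrac12, n_0 + \tfrac12)} instead of the arcsine
#' pivot. The chi-square variate enters pre-scaled by its degrees of freedom,
#' the only scaling under which the variance pivot is a valid fiducial
#' quantity (and equals the GCI one).
#'
#' @inheritParams gci_draws
#' @return A `"pivotal_draws"` object with element `theta` of length `m`.
#' @export
fgci_draws <- function(s1, s2, m = 2500, seed = NULL) {
  .pivotal_draws(s1, s2, m, fiducial = TRUE, seed = seed)
}

#' @export
print.pivotal_draws <- function(x, ...) {
  cat(sprintf("%s pivotal draws for theta: m = %d, median %.4f\n",
              toupper(x$method), x$m, stats::median(x$theta)))
  invisible(x)
}

#' Equal-tailed percentile interval from Monte-Carlo draws
#'
#' Takes the empirical \eqn{\zeta/2} and \eqn{1 - \zeta/2} quantiles of the
#' draws. Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), applied uniformly to GCI and FGCI draws so
#' that results are bit-reproducible given a seed.
#'
#' @param draws A `"pivotal_draws"` object (or any list with a numeric
#'   `theta` element).
#' @param level Nominal confidence level in (0, 1).
#' @return A [dln_interval()].
#' @export
percentile_interval <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  theta <- draws$theta
  stopifnot(is.numeric(theta), length(theta) > 0)
  q <- stats::quantile(theta, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  dln_interval(q[1], q[2], level,
               method = if (!is.null(draws$method)) draws$method else "percentile")
}

#' Generalized confidence interval for the log variance ratio
#'
#' @inheritParams gci_draws
#' @param level Nominal confidence level.
#' @return A [dln_interval()].
#' @examples
#' north <- group_summary(62, 22, 2.541, 0.886)
#' northeast <- group_summary(210, 65, 2.576, 1.576)
#' ci_gci(north, northeast, seed = 1)
#' @export
ci_gci <- function(s1, s2, level = 0.95, m = 2500, seed = NULL) {
  percentile_interval(gci_draws(s1, s2, m, seed), level)
}

#' Fiducial generalized confidence interval for the log variance ratio
#'
#' @inheritParams ci_gci
#' @return A [dln_interval()].
#' @export
ci_fgci <- function(s1, s2, level = 0.95, m = 2500, seed = NULL) {
  percentile_interval(fgci_draws(s1, s2, m, seed), level)
}
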