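#' Two-sided interval for the log variance ratio
#'
#' Light container for an interval on the \eqn{\theta = \ln(\omega_1/\omega_2)}
#' scale. The ratio-scale view `(exp(lower), exp(upper))` preserves ordering
#' because exp is monotone.
#'
#' @param lower,upper Interval endpoints on the \eqn{\theta} scale
#'   (`lower` may be `-Inf` when a MOVER component bound is undefined).
#' @param level Nominal confidence / credibility level in (0, 1).
#' @param method Short label of the generating method.
#' @return An object of class `"dln_interval"`.
#' @export
dln_interval <- function(lower, upper, level, method = "unknown") {
  stopifnot(length(lower) == 1L, length(upper) == 1L,
            level > 0, level < 1)
  if (is.nan(lower) || is.nan(upper) || is.na(lower) || is.na(upper)) {
    stop("interval endpoints must not be NA", call. = FALSE)
  }
  if (lower > upper) stop("lower must not exceed upper", call. = FALSE)
  structure(list(lower = lower, upper = upper, level = level, method = method),
            class = "dln_interval")
}

#' @export
print.dln_interval <- function(x, ...) {
  cat(sprintf("%d%% interval for theta = ln(omega1/omega2)  [%s]\n",
              round(100 * x$level), x$method))
  cat(sprintf("  theta scale: (%.4f, %.4f)\n", x$lower, x$upper))
  cat(sprintf("  ratio scale: (%.4f, %.4f), length %.4f\n",
              exp(x$lower), exp(x$upper), exp(x$upper) - exp(x$lower)))
  invisible(x)
}

#' Interval endpoints on a chosen scale
#'
#' @param x A `"dln_interval"`.
#' @param scale `"theta"` for the log-ratio scale, `"ratio"` for
#'   \eqn{e^\theta}.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
interval_bounds <- function(x, scale = c("theta", "ratio")) {
  stopifnot(inherits(x, "dln_interval"))
  scale <- match.arg(scale)
  b <- c(lower = x$lower, upper = x$upper)
  if (scale == "ratio") exp(b) else b
}

#' Interval length on a chosen scale
#'
#' @inheritParams interval_bounds
#' @return The length `upper - lower` on the requested scale.
#' @export
interval_length <- function(x, scale = c("theta", "ratio")) {
  b <- interval_bounds(x, scale)
  unname(b["upper"] - b["lower"])
}
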