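## Shared fixtures and independent oracles.

## Published two-region rainfall application, from its printed summary
## statistics (counts and log-scale MLEs).
north_summary <- function() group_summary(n = 62, n0 = 22,
                                          mu_hat = 2.541, sigma2_hat = 0.886)
northeast_summary <- function() suppressWarnings(
  group_summary(n = 210, n0 = 65, mu_hat = 2.576, sigma2_hat = 1.576))

## Brute-force HPD oracle: enumerate every contiguous window of the sorted
## sample and return the narrowest (earliest on ties).
brute_hpd <- function(x, level) {
  x <- sort(x)
  m <- length(x)
  k <- ceiling(level * m)
  best <- c(-Inf, Inf)
  for (i in 1:(m - k + 1)) {
    if (x[i + k - 1] - x[i] < best[2] - best[1]) {
      best <- c(x[i], x[i + k - 1])
    }
  }
  best
}

## Equal-tailed interval by explicit sort-and-interpolate (quantile type 7
## written out by hand), used as the percentile-interval oracle.
sort_index_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
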