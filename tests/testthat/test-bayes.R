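test_that("posterior moments match their closed forms", {
  s <- north_summary()  # n1 = 40, sigma2_hat = 0.886
  m <- 1e5

  ## Jeffreys: sigma2* ~ IG(r/2, r*s2/2) has mean r*s2/(r-2)
  post <- draw_posterior(s, dln_prior("jeffreys"), m = m, seed = 1)
  ig_mean <- 39 * 0.886 / 37
  ig_sd <- ig_mean / sqrt(39 / 2 - 2)      # sd of IG(a,b) = mean/sqrt(a-2)
  expect_equal(mean(post$sigma2_star), ig_mean,
               tolerance = 3 * ig_sd / sqrt(m) / ig_mean)
  ## zero-probability draw ~ beta(n0 + 1/2, n1 + 1/2): mean (n0+.5)/(n+1)
  expect_equal(mean(1 - post$prob_positive), 22.5 / 63, tolerance = 0.002)

  ## Jeffreys' Rule: shape constants shift to s = n1 + 1 and beta(.., n1+3/2)
  post_r <- draw_posterior(s, dln_prior("jeffreys_rule"), m = m, seed = 2)
  expect_equal(mean(post_r$sigma2_star), 41 * 0.886 / 39,
               tolerance = 0.01)
  expect_equal(mean(1 - post_r$prob_positive), 22.5 / 64,
               tolerance = 0.005)

  ## Normal-gamma: mu* is a symmetric t about mu_hat; positive-class beta
  post_ng <- draw_posterior(s, dln_prior("normal_gamma"), m = m, seed = 3)
  expect_equal(mean(post_ng$mu_star), s$mu_hat, tolerance = 0.01)
  d <- dln_prior("normal_gamma")$d
  expect_equal(mean(post_ng$prob_positive), (40 + d) / (62 + 2 * d),
               tolerance = 0.005)
  expect_equal(mean(post_ng$sigma2_star), (40 * 0.886 / 2) / (19.5 - 1),
               tolerance = 0.01)
})

test_that("Jeffreys and Jeffreys' Rule differ only through shape constants", {
  ## aligning the chi-square weight r = n1 - 1 of one group with the weight
  ## s = n1' + 1 of a group with two fewer positives reproduces the same
  ## sigma2* stream under a shared seed
  s_a <- group_summary(50, 8, 1.1, 0.9)    # n1 = 42, Jeffreys r = 41
  s_b <- group_summary(48, 8, 1.1, 0.9)    # n1 = 40, Rule s = 41
  a <- draw_posterior(s_a, dln_prior("jeffreys"), m = 500, seed = 9)
  b <- draw_posterior(s_b, dln_prior("jeffreys_rule"), m = 500, seed = 9)
  expect_identical(a$sigma2_star, b$sigma2_star)
})

test_that("ln_omega_draws is finite and reduces to the lognormal case", {
  ## sigma2* = ln 2, mu* = 0, all mass on positives -> omega* = 2
  fake <- structure(list(sigma2_star = rep(log(2), 120),
                         mu_star = rep(0, 120),
                         prob_positive = rep(1, 120),
                         prior = "jeffreys", m = 120),
                    class = "dln_posterior")
  expect_equal(ln_omega_draws(fake), rep(log(2), 120), tolerance = 1e-12)

  ## bracket positivity for every prior on a small-n summary
  s <- group_summary(12, 4, 0.3, 0.4)
  for (kind in c("jeffreys", "jeffreys_rule", "normal_gamma")) {
    post <- draw_posterior(s, dln_prior(kind), m = 5000, seed = 4)
    expect_true(all(exp(post$sigma2_star) - post$prob_positive > 0))
    expect_true(all(is.finite(ln_omega_draws(post))))
  }

  ## large-m posterior concentration: NG median of ln(omega*) near the
  ## plug-in ln(omega_hat) for the north group
  post <- draw_posterior(north_summary(), dln_prior("normal_gamma"),
                         m = 1e5, seed = 5)
  expect_equal(median(ln_omega_draws(post)), log(448.34), tolerance = 0.02)
})

test_that("the NG conditional construction reproduces the marginal t", {
  ## sampling sigma2* ~ IG(alpha_n, beta_n) then mu* | sigma2* ~
  ## N(mu_hat, sigma2*/k_n) must match the direct t(df = n1 - 1) marginal
  s <- north_summary()
  m <- 1e5
  set.seed(6)
  alpha_n <- (s$n1 - 1) / 2
  beta_n <- s$n1 * s$sigma2_hat / 2
  sigma2 <- beta_n / rgamma(m, alpha_n)
  mu_cond <- rnorm(m, s$mu_hat, sqrt(sigma2 / s$n1))
  mu_marg <- draw_posterior(s, dln_prior("normal_gamma"), m = m,
                            seed = 7)$mu_star
  ks <- suppressWarnings(ks.test(mu_cond, mu_marg))
  expect_gt(ks$p.value, 0.001)
})

test_that("hpd implements the shortest-window estimator", {
  ## all windows tie on an equally spaced grid; earliest window wins
  g <- hpd(as.numeric(0:99), 0.95)
  expect_identical(c(g$lower, g$upper), c(0, 94))

  ## right-skewed draws: strictly shorter than equal-tailed, matches the
  ## brute-force enumeration oracle
  x <- exp(qnorm(seq(0.001, 0.999, length.out = 1500)))
  h <- hpd(x, 0.9)
  expect_equal(c(h$lower, h$upper), brute_hpd(x, 0.9), tolerance = 1e-12)
  eq <- percentile_interval(list(theta = x), 0.9)
  expect_lt(interval_length(h), interval_length(eq))

  ## randomized draws against the oracle, several levels
  set.seed(8)
  for (lvl in c(0.5, 0.8, 0.95)) {
    y <- rgamma(999, shape = 2)
    h2 <- hpd(y, lvl)
    expect_equal(c(h2$lower, h2$upper), brute_hpd(y, lvl), tolerance = 1e-12)
    expect_lte(interval_length(h2),
               interval_length(percentile_interval(list(theta = y), lvl)))
    ## window mass and support containment
    expect_gte(sum(y >= h2$lower & y <= h2$upper), ceiling(lvl * 999))
    expect_gte(h2$lower, min(y)); expect_lte(h2$upper, max(y))
  }

  ## symmetric unimodal draws: HPD close to equal-tailed
  zsym <- qnorm(seq(0.0005, 0.9995, length.out = 2000))
  expect_equal(c(hpd(zsym, 0.95)$lower, hpd(zsym, 0.95)$upper),
               c(-1.96, 1.96), tolerance = 0.05)

  expect_error(hpd(rnorm(50), 0.02), "too few")
})

test_that("ci_hpd is reproducible and symmetric for identical groups", {
  s <- north_summary()
  a <- ci_hpd(s, northeast_summary(), "jeffreys", m = 2000, seed = 10)
  b <- ci_hpd(s, northeast_summary(), "jeffreys", m = 2000, seed = 10)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
  expect_identical(a$method, "hpd-jef")

  ## identical groups: interval straddles 0 (checked across seeds)
  hits <- sapply(1:20, function(k) {
    ci <- ci_hpd(s, s, "normal_gamma", m = 1000, seed = k)
    ci$lower <= 0 && 0 <= ci$upper
  })
  expect_gte(mean(hits), 0.9)
})
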