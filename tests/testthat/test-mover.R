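test_that("wilson_log_interval matches direct evaluation and brackets ln(n1/n)", {
  ## direct evaluation with z = 1.959964
  expect_equal(wilson_log_interval(22, 40), c(-0.652, -0.284),
               tolerance = 1e-3)
  expect_equal(wilson_log_interval(65, 145), c(-0.470, -0.289),
               tolerance = 1e-3)
  for (counts in list(c(22, 40), c(65, 145), c(0, 12), c(5, 7))) {
    ci <- wilson_log_interval(counts[1], counts[2])
    est <- log(counts[2] / sum(counts))
    ## at n0 = 0 the upper Wilson bound coincides with the point estimate
    ## ln(1) = 0, so containment is non-strict there
    expect_lte(ci[1], est)
    expect_gte(ci[2] + 1e-12, est)
    expect_lte(ci[2], 1e-12)  # log of a proportion
  }
})

test_that("component2_interval brackets 2*mu + sigma2 and collapses as n grows", {
  expect_equal(component2_interval(north_summary()), c(5.316, 6.787),
               tolerance = 1e-3)
  expect_equal(component2_interval(northeast_summary()), c(6.216, 7.327),
               tolerance = 1e-3)
  s <- north_summary()
  est <- 2 * s$mu_hat + s$sigma2_hat
  ci <- component2_interval(s)
  expect_lt(ci[1], est); expect_gt(ci[2], est)

  ## half-widths shrink towards zero with the number of positives
  widths <- sapply(c(40, 400, 40000), function(n1) {
    big <- group_summary(n1 + 22, 22, s$mu_hat, s$sigma2_hat)
    diff(component2_interval(big))
  })
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 0.05)
})

test_that("component3_interval uses the untransformed-argument reading", {
  expect_equal(component3_interval(north_summary()), c(-0.314, 1.087),
               tolerance = 2e-3)
  expect_equal(component3_interval(northeast_summary()), c(1.129, 1.658),
               tolerance = 1e-3)

  ## near-degenerate zero proportion: A -> exp(sigma2), interval finite
  s_many_zeros <- group_summary(1000, 995, 1.0, 2.0)
  ci <- component3_interval(s_many_zeros)
  expect_true(all(is.finite(ci)))
  expect_lt(ci[1], log(exp(2) - 5 / 1000))
  expect_gt(ci[2], log(exp(2) - 5 / 1000))

  ## small sigma2_hat: the lower bound degenerates to -Inf with a warning
  s_small <- group_summary(30, 5, 1.0, 0.2)
  expect_warning(ci2 <- component3_interval(s_small), "undefined")
  expect_identical(ci2[1], -Inf)
  expect_true(is.finite(ci2[2]))
})

test_that("the three components add up to ln(omega_hat) exactly", {
  for (s in list(north_summary(), northeast_summary(),
                 group_summary(80, 30, -1.2, 2.5))) {
    w1 <- log(1 - s$delta_hat)
    w2 <- 2 * s$mu_hat + s$sigma2_hat
    w3 <- log(exp(s$sigma2_hat) - (1 - s$delta_hat))
    expect_equal(w1 + w2 + w3, log(dln_variance(s)), tolerance = 1e-14)
  }
})

test_that("mover_ln_omega_interval reproduces the derived per-group bounds", {
  i1 <- mover_ln_omega_interval(north_summary())
  expect_equal(c(i1$lower, i1$upper), c(4.982, 7.084), tolerance = 1e-3)
  expect_lt(i1$lower, log(448.34)); expect_gt(i1$upper, log(448.34))
  i2 <- mover_ln_omega_interval(northeast_summary())
  expect_equal(c(i2$lower, i2$upper), c(7.181, 8.429), tolerance = 1e-3)
})

test_that("ci_mover reproduces the published interval and is antisymmetric", {
  s1 <- north_summary(); s2 <- northeast_summary()
  ci <- ci_mover(s1, s2)
  b <- interval_bounds(ci, "ratio")
  expect_equal(unname(b), c(0.0512, 0.5896), tolerance = 0.01)
  expect_equal(interval_length(ci, "ratio"), 0.5384, tolerance = 0.01)

  ## exact antisymmetry under group swap
  sw <- ci_mover(s2, s1)
  expect_identical(sw$lower, -ci$upper)
  expect_identical(sw$upper, -ci$lower)

  ## identical groups: symmetric about zero
  same <- ci_mover(s1, s1)
  expect_equal(same$lower, -same$upper, tolerance = 1e-12)

  ## fully deterministic: bit-identical on recomputation
  again <- ci_mover(s1, s2)
  expect_identical(c(again$lower, again$upper), c(ci$lower, ci$upper))
})
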