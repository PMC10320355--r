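test_that("prior log densities match closed forms", {
  expect_equal(prior_logpdf(prior_normal(0, 1), 0), -0.5 * log(2 * pi))
  expect_identical(prior_logpdf(prior_cauchy_plus(0, 1), -0.1), -Inf)
  # half-Cauchy density at 0 is 2/pi
  expect_equal(prior_logpdf(prior_cauchy_plus(0, 1), 0), log(2 / pi))
  # inverse-gamma(shape a, scale b): mode at b/(a+1)
  ig <- prior_invgamma(2, 0.3)
  xs <- seq(0.01, 2, length.out = 200)
  expect_equal(xs[which.max(prior_logpdf(ig, xs))], 0.3 / 3, tolerance = 0.02)
  expect_identical(prior_logpdf(ig, -1), -Inf)
})

test_that("truncated families renormalize to unit mass over their support", {
  for (pr in list(prior_cauchy_plus(0, 1), prior_cauchy_plus(0, 10),
                  prior_student_t_plus(0.35, 0.10, 3))) {
    mass <- integrate(function(x) exp(prior_logpdf(pr, x)), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("quantile functions invert the distribution functions", {
  q <- c(0.05, 0.3, 0.5, 0.8, 0.99)
  expect_equal(prior_quantile(prior_normal(1, 2), q), qnorm(q, 1, 2))
  ig <- prior_invgamma(1, 0.15)
  cdf <- vapply(prior_quantile(ig, q), function(x)
    integrate(function(t) exp(prior_logpdf(ig, t)), 0, x)$value, 0)
  expect_equal(cdf, q, tolerance = 1e-6)
  hc <- prior_cauchy_plus(0, 1)
  expect_equal(pcauchy(prior_quantile(hc, q)) * 2 - 1, q, tolerance = 1e-12)
})

test_that("omega_from_eta gives non-increasing weights starting at 1", {
  expect_equal(omega_from_eta(c(1, 0, 0)), c(1, 0, 0))
  expect_equal(omega_from_eta(c(0.5, 0.5)), c(1, 0.5))
  expect_error(omega_from_eta(c(0.5, 0.4)), "sum")
  expect_error(omega_from_eta(c(1.5, -0.5)), "nonnegative|sum")

  set.seed(11)
  draws <- prior_rng(prior_cumdirichlet(rep(1, 4)), 1e4)
  expect_equal(dim(draws), c(1e4, 4))
  expect_true(all(draws[, 1] == 1))
  expect_true(all(draws[, -1] <= draws[, -4] + 1e-12))
  expect_true(all(draws > 0 & draws <= 1))
})

test_that("prior draws follow the prior quantiles", {
  set.seed(7)
  for (pr in list(prior_normal(0.2, 0.5), prior_invgamma(1, 0.075),
                  prior_cauchy_plus(0, 1))) {
    x <- prior_rng(pr, 2e4)
    expect_equal(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
                 prior_quantile(pr, c(0.25, 0.5, 0.75)), tolerance = 0.05)
  }
})
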