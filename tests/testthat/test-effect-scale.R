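test_that("Fisher transform matches atanh with its round trip and domain", {
  expect_identical(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.5), 0.5 * log(3))
  expect_error(fisher_transform(1), "r")
  expect_error(fisher_transform(-1.2), "r")
  expect_error(inverse_fisher(Inf), "finite")
  expect_identical(inverse_fisher(0), 0)
  expect_equal(inverse_fisher(0.5 * log(3)), 0.5)

  z <- seq(-3, 3, length.out = 61)
  expect_equal(fisher_transform(inverse_fisher(z)), z, tolerance = 1e-12)
  expect_true(all(abs(inverse_fisher(c(-15, -5, 5, 15))) < 1))
  # strictly increasing, odd
  r <- seq(-0.95, 0.95, length.out = 41)
  expect_true(all(diff(fisher_transform(r)) > 0))
  expect_equal(fisher_transform(-r), -fisher_transform(r))
})

test_that("fisher_se is 1/sqrt(n-3), decreasing, and rejects n < 4", {
  expect_equal(fisher_se(103), 0.1)
  expect_equal(fisher_se(4), 1)
  expect_true(all(diff(fisher_se(4:200)) < 0))
  expect_error(fisher_se(3))
  expect_error(fisher_se(10.5))
})

test_that("d-to-z prior rescaling: fixed point, Jacobian, and unit mass", {
  p0 <- rescale_prior_d_to_z(prior_point(0))
  expect_equal(p0$params$location, 0)

  pn <- rescale_prior_d_to_z(prior_normal(0, 1), "exact")
  # |dd/dz| = 2 cosh(0) = 2 at z = 0
  expect_equal(prior_logpdf(pn, 0), dnorm(0, log = TRUE) + log(2))

  for (mapping in c("exact", "linear")) {
    for (base in list(prior_normal(0, 1), prior_student_t_plus(0.35, 0.10, 3))) {
      pr <- rescale_prior_d_to_z(base, mapping)
      mass <- integrate(function(z) exp(prior_logpdf(pr, z)),
                        -20, 20, rel.tol = 1e-10)$value
      expect_equal(mass, 1, tolerance = 1e-6)
      # quantile function inverts the CDF
      qs <- prior_quantile(pr, c(0.1, 0.5, 0.9))
      cdf <- vapply(qs, function(q)
        integrate(function(z) exp(prior_logpdf(pr, z)), -20, q,
                  rel.tol = 1e-9)$value, 0)
      expect_equal(cdf, c(0.1, 0.5, 0.9), tolerance = 1e-5)
    }
  }
})

test_that("exact and linear d-to-z mappings agree within 1% for small z", {
  z <- seq(-0.2, 0.2, length.out = 41)
  z <- z[z != 0]
  exact <- 2 * sinh(z)
  linear <- 2 * z
  expect_true(all(abs(exact - linear) / abs(exact) < 0.01))
})

test_that("heterogeneity prior rescales by tau_z = tau_d / 2", {
  pr <- rescale_prior_d_to_z(prior_invgamma(1, 0.15))
  expect_equal(pr$params$scale, 0.075)
  # quantiles exactly halved
  q <- c(0.25, 0.5, 0.9)
  expect_equal(prior_quantile(pr, q),
               prior_quantile(prior_invgamma(1, 0.15), q) / 2)
})

test_that("make_studies completes z/se_z from r/n and validates", {
  st <- make_studies(r = c(0.3, -0.1), n = c(28, 103))
  expect_equal(st$z, atanh(c(0.3, -0.1)))
  expect_equal(st$se_z, c(0.2, 0.1))
  expect_warning(make_studies(z = 0.1, n = 100, se_z = 0.2), "se_z")
  expect_error(make_studies(z = 0.1, se_z = -1), "se_z")
  expect_error(make_studies(r = 0.1), "se_z|n")
})

test_that("corpus CSV round trip preserves values and completes columns", {
  sim <- simulate_corpus(simulation_config(preset = "small", seed = 21))
  path <- tempfile(fileext = ".csv")
  write_corpus(sim$corpus, path)
  back <- read_corpus(path)
  expect_equal(back$z, sim$corpus$z, tolerance = 1e-9)
  expect_equal(back$se_z, sim$corpus$se_z, tolerance = 1e-9)
  expect_identical(back$meta_id, sim$corpus$meta_id)

  # r/n only input gets z and se_z filled in
  partial <- data.frame(article_id = 1, meta_id = 1, study_id = 1:2,
                        r = c(0.2, 0.4), n = c(52, 103))
  p2 <- tempfile(fileext = ".csv")
  write.csv(partial, p2, row.names = FALSE)
  filled <- read_corpus(p2)
  expect_equal(filled$z, atanh(c(0.2, 0.4)))
  expect_equal(filled$se_z, c(1 / 7, 0.1))
})
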