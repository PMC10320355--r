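test_that("point-effect point-tau model has the closed-form marginal", {
  set.seed(2)
  st <- make_studies(z = rnorm(6, 0.1, 0.2), se_z = runif(6, 0.1, 0.3))
  spec <- model_spec(prior_point(0), prior_point(0), bias_none(), 1, id = 1)
  f <- ln_marginal_likelihood(spec, st, fast_settings())
  expect_equal(f$ln_marg_lik, sum(dnorm(st$z, 0, st$se_z, log = TRUE)),
               tolerance = 1e-12)
  expect_identical(f$method, "closed_form")
})

test_that("conjugate normal-mean marginals match the closed form on random data", {
  set.seed(14)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    z <- rnorm(k, rnorm(1, 0, 0.3), 0.2)
    se <- runif(k, 0.05, 0.4)
    m0 <- rnorm(1, 0, 0.2)
    s0 <- runif(1, 0.1, 0.8)
    st <- make_studies(z = z, se_z = se)
    spec <- model_spec(prior_normal(m0, s0), prior_point(0), bias_none(),
                       1, id = 1)
    f <- ln_marginal_likelihood(spec, st, fast_settings())
    expect_equal(f$ln_marg_lik, conjugate_lnml(z, se, m0, s0),
                 tolerance = 1e-3)
  }
})

test_that("Monte Carlo and quadrature agree on a 2-study selection model", {
  st <- make_studies(z = c(0.35, 0.1), se_z = c(0.12, 0.25))
  wf <- weight_function(0.05, "two_sided")
  spec <- model_spec(rescale_prior_d_to_z(prior_normal(0, 1)),
                     prior_point(0), bias_selection(wf), 1, id = 1)
  q <- ln_marginal_likelihood(spec, st, integration_settings(
    method = "quadrature", seed = 1))
  m <- ln_marginal_likelihood(spec, st, integration_settings(
    method = "mc", mc_draws = 50000, seed = 1))
  expect_lt(abs(q$ln_marg_lik - m$ln_marg_lik),
            3 * (q$error + m$error) + 1e-3)
})

test_that("marginal likelihood is invariant to study order", {
  set.seed(20)
  st <- make_studies(z = rnorm(9, 0.2, 0.25), se_z = runif(9, 0.05, 0.3))
  perm <- st[sample(nrow(st)), ]
  specs <- build_ensemble()
  for (i in c(1, 10, 19, 22, 26, 28, 31)) {   # a slice across model types
    a <- ln_marginal_likelihood(specs[[i]], st, fast_settings(seed = 4))
    b <- ln_marginal_likelihood(specs[[i]], perm, fast_settings(seed = 4))
    expect_equal(a$ln_marg_lik, b$ln_marg_lik,
                 tolerance = max(1e-8, 2 * (a$error + b$error)))
  }
})

test_that("conditional effect posteriors: point mass, shrinkage, unit mass", {
  st1 <- make_studies(z = 0.25, se_z = 0.1)
  null_spec <- model_spec(prior_point(0), prior_point(0), bias_none(), 1, 1)
  eff <- conditional_effect_posterior(null_spec, st1, fast_settings())
  expect_true(eff$point_mass)
  expect_equal(eff$mean_z, 0)

  # conjugate single-study shrinkage: precision-weighted mean
  s0 <- 0.4
  spec <- model_spec(prior_normal(0, s0), prior_point(0), bias_none(), 1, 1)
  eff2 <- conditional_effect_posterior(spec, st1, fast_settings())
  shrunk <- 0.25 * (1 / 0.1^2) / (1 / 0.1^2 + 1 / s0^2)
  expect_equal(eff2$mean_z, shrunk, tolerance = 1e-4)
  # tabulated density integrates to one
  area <- sum(diff(eff2$mu) * (head(eff2$dens, -1) + tail(eff2$dens, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
})

test_that("flagged results surface instead of failing silently", {
  st <- strong_meta()
  spec <- model_spec(rescale_prior_d_to_z(prior_normal(0, 1)),
                     rescale_prior_d_to_z(prior_invgamma(1, 0.15)),
                     bias_selection(weight_function(c(0.025, 0.05, 0.5),
                                                    "one_sided")),
                     1, id = 1)
  f <- fit_model(spec, st, integration_settings(method = "mc",
                                                mc_draws = 150, seed = 2))
  expect_identical(f$method, "mc")
  expect_true(is.finite(f$ln_marg_lik))
  expect_true(is.finite(f$ln_ml_error))   # error always reported
})
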