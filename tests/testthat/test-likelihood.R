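test_that("p-values follow the standard normal tail formulas", {
  expect_equal(p_value(0, 1, "one_sided"), 0.5)
  expect_equal(p_value(0, 1, "two_sided"), 1)
  expect_equal(p_value(1.959964 * 0.2, 0.2, "two_sided"), 0.05,
               tolerance = 1e-6)
  x <- c(0.3, 1.1, 2.5)
  expect_equal(p_value(-x, 1, "one_sided"), 1 - p_value(x, 1, "one_sided"))
  expect_error(p_value(0.1, 0), "se_z")
})

test_that("random-effects likelihood reduces to normal densities", {
  st <- make_studies(z = 0, se_z = 1)
  expect_equal(ln_lik_random_effects(st, 0, 0), dnorm(0, log = TRUE))
  # tau folds into the marginal sd
  st2 <- make_studies(z = c(0.1, 0.4), se_z = c(0.2, 0.3))
  expect_equal(ln_lik_random_effects(st2, 0.2, 0.1),
               sum(dnorm(st2$z, 0.2, sqrt(0.01 + st2$se_z^2), log = TRUE)))
  # with equal se and tau = 0 the likelihood peaks at the sample mean
  st3 <- make_studies(z = c(-0.2, 0.1, 0.4), se_z = rep(0.2, 3))
  at_mean <- ln_lik_random_effects(st3, mean(st3$z), 0)
  for (mu in c(-0.3, 0, 0.2, 0.5))
    expect_lte(ln_lik_random_effects(st3, mu, 0), at_mean)
  expect_error(ln_lik_random_effects(st3, 0, -0.1), "tau")
})

test_that("selection likelihood: unit weights recover the plain likelihood", {
  set.seed(5)
  st <- make_studies(z = rnorm(10, 0.2, 0.3), se_z = runif(10, 0.05, 0.4))
  for (wf in default_weight_functions()) {
    for (rep in 1:5) {
      mu <- rnorm(1, 0, 0.4); tau <- abs(rnorm(1, 0, 0.15))
      expect_equal(ln_lik_selection(st, mu, tau, wf, rep(1, wf$J)),
                   ln_lik_random_effects(st, mu, tau), tolerance = 1e-10)
    }
  }
})

test_that("selection likelihood matches the two-interval enumeration", {
  st <- make_studies(z = 0, se_z = 1)
  wf <- weight_function(0.05, "two_sided")
  # observed p = 1 -> weight 0.5; A = 0.05 * 1 + 0.95 * 0.5 under N(0,1)
  expect_equal(ln_lik_selection(st, 0, 0, wf, c(1, 0.5)),
               log(0.5 * dnorm(0)) - log(0.05 + 0.5 * 0.95),
               tolerance = 1e-6)
  # scaling all weights cancels between numerator and normalizer
  expect_equal(ln_lik_selection(st, 0.3, 0.1, wf, c(2, 1)),
               ln_lik_selection(st, 0.3, 0.1, wf, c(1, 0.5)))
  expect_error(ln_lik_selection(st, 0, 0, wf, c(1, 0)), "omega")
})

test_that("selection likelihood handles one-sided intervals correctly", {
  # brute-force the normalizer for a single study by numeric integration
  st <- make_studies(z = 0.5, se_z = 0.25)
  wf <- weight_function(c(0.05, 0.5), "one_sided")
  omega <- c(1, 0.4, 0.1)
  mu <- 0.1; tau <- 0.2
  s <- sqrt(tau^2 + st$se_z^2)
  pfun <- function(zz) 1 - pnorm(zz / st$se_z)
  wfun <- function(zz) omega[findInterval(pfun(zz), wf$cutpoints,
                                          left.open = TRUE) + 1]
  A <- integrate(function(zz) wfun(zz) * dnorm(zz, mu, s), -20, 20,
                 subdivisions = 2000, rel.tol = 1e-10)$value
  p_obs <- pfun(st$z)
  expected <- log(wfun(st$z)) + dnorm(st$z, mu, s, log = TRUE) - log(A)
  expect_equal(ln_lik_selection(st, mu, tau, wf, omega), expected,
               tolerance = 1e-6)
})

test_that("PET/PEESE likelihood reduces to the plain likelihood at coef 0", {
  set.seed(6)
  st <- make_studies(z = rnorm(8, 0.2, 0.2), se_z = runif(8, 0.05, 0.3))
  for (order in 1:2) for (rep in 1:5) {
    mu <- rnorm(1, 0, 0.4); tau <- abs(rnorm(1, 0, 0.15))
    expect_equal(ln_lik_pet_peese(st, mu, tau, 0, order),
                 ln_lik_random_effects(st, mu, tau))
  }
  # zero residual evaluates the density at its mode
  st1 <- make_studies(z = 0.1 + 2 * 0.3, se_z = 0.3)
  expect_equal(ln_lik_pet_peese(st1, 0.1, 0, 2, 1),
               dnorm(0, 0, 0.3, log = TRUE))
  # PET and PEESE differ whenever se != se^2
  expect_false(isTRUE(all.equal(ln_lik_pet_peese(st, 0.1, 0, 1, 1),
                                ln_lik_pet_peese(st, 0.1, 0, 1, 2))))
  expect_error(ln_lik_pet_peese(st, 0, 0, 1, 3), "order")
})

test_that("C++ kernels agree with the scalar reference implementations", {
  set.seed(8)
  st <- make_studies(z = rnorm(7, 0.1, 0.3), se_z = runif(7, 0.05, 0.35))
  wfs <- default_weight_functions()
  for (rep in 1:10) {
    mu <- rnorm(1, 0, 0.5); tau <- abs(rnorm(1, 0, 0.2))
    expect_equal(robmeta:::ll_re_vec(st$z, st$se_z, mu, tau),
                 ln_lik_random_effects(st, mu, tau), tolerance = 1e-12)
    cf <- abs(rnorm(1, 0, 2)); ord <- sample(1:2, 1)
    expect_equal(robmeta:::ll_petpeese_vec(st$z, st$se_z, mu, tau, cf, ord),
                 ln_lik_pet_peese(st, mu, tau, cf, ord), tolerance = 1e-12)
    wf <- wfs[[sample(length(wfs), 1)]]
    om <- sort(runif(wf$J), decreasing = TRUE); om[1] <- 1
    expect_equal(robmeta:::ll_sel_vec(st$z, st$se_z, mu, tau, wf,
                                      matrix(om, 1)),
                 ln_lik_selection(st, mu, tau, wf, om), tolerance = 1e-10)
  }
})
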