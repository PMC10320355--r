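test_that("the full ensemble has the factorial structure and prior masses", {
  ens <- build_ensemble()
  expect_length(ens, 36)
  probs <- vapply(ens, function(s) s$prior_prob, 0)
  expect_equal(sum(probs), 1, tolerance = 1e-12)

  eff <- vapply(ens, function(s) s$effect_prior$family != "point", TRUE)
  het <- vapply(ens, function(s) s$heterogeneity_prior$family != "point", TRUE)
  bias <- vapply(ens, function(s) s$bias$kind, "")
  expect_equal(sum(probs[eff]), 0.5)
  expect_equal(sum(probs[het]), 0.5)
  expect_equal(sum(probs[bias != "none"]), 0.5)
  # per-member masses: 1/8 none, 1/96 each selection, 1/32 PET and PEESE
  expect_equal(unique(probs[bias == "none"]), 1 / 8)
  expect_equal(unique(probs[bias == "selection"]), 1 / 96)
  expect_equal(unique(probs[bias %in% c("pet", "peese")]), 1 / 32)
  # six selection models in each of the four effect x heterogeneity cells
  cells <- paste(eff, het)
  for (cl in unique(cells))
    expect_equal(sum(bias[cells == cl] == "selection"), 6)
})

test_that("the Oosterwijk effect prior variant swaps only the effect prior", {
  ens <- build_ensemble(effect_prior_alt = "oosterwijk")
  expect_length(ens, 36)
  alt <- Filter(function(s) s$effect_prior$family != "point", ens)
  base <- alt[[1]]$effect_prior$params$base
  expect_identical(base$family, "student_t_plus")
  expect_equal(base$params$location, 0.35)
  expect_equal(base$params$df, 3)
})

test_that("restricting to the bias-absent members renormalizes to the BMA", {
  bma <- restrict_to_bma(build_ensemble())
  expect_length(bma, 4)
  probs <- vapply(bma, function(s) s$prior_prob, 0)
  expect_equal(probs, rep(0.25, 4))
  eff <- vapply(bma, function(s) s$effect_prior$family != "point", TRUE)
  expect_equal(sum(probs[eff]), 0.5)
})

test_that("component probabilities partition and Bayes factors are odds ratios", {
  st <- mild_meta()
  fit <- fit_ensemble(build_ensemble(), st, fast_settings(seed = 2))
  expect_equal(sum(fit$posterior_model_probs), 1, tolerance = 1e-10)
  probs <- fit$posterior_model_probs
  eff <- vapply(build_ensemble(), function(s)
    s$effect_prior$family != "point", TRUE)
  expect_equal(fit$p_effect + sum(probs[!eff]), 1, tolerance = 1e-10)
  expect_equal(fit$bf_effect,
               (fit$p_effect / (1 - fit$p_effect)) / (0.5 / 0.5),
               tolerance = 1e-8)
  expect_equal(fit$bf_bias,
               (fit$p_bias / (1 - fit$p_bias)) / (0.5 / 0.5),
               tolerance = 1e-8)
})

test_that("a strong homogeneous signal yields near-certain effect evidence", {
  # heterogeneous standard errors: with identical se the PET/PEESE mean
  # structure is collinear with the intercept and caps p_effect below 1
  st <- strong_meta()
  fit <- fit_ensemble(build_ensemble(), st, fast_settings(seed = 2))
  expect_gt(fit$p_effect, 0.99)
  expect_gt(fit$averaged_effect_mean_z, 0.15)
  # the r-scale mean is the mixture mean of tanh(mu), close to but not
  # identical with tanh of the z mean
  expect_equal(fit$averaged_effect_mean_r, tanh(fit$averaged_effect_mean_z),
               tolerance = 0.02)
})

test_that("an uninformative study returns the prior model probabilities", {
  st <- make_studies(z = 0, se_z = 50)
  suppressWarnings({
    bma <- fit_ensemble(restrict_to_bma(build_ensemble()), st,
                        integration_settings(seed = 2))
    full <- fit_ensemble(build_ensemble(), st, integration_settings(seed = 2))
  })
  expect_equal(bma$posterior_model_probs, rep(0.25, 4), tolerance = 0.01)
  # effect and heterogeneity stay at equipoise; the bias component does
  # not (an observed p-value is informative about selection even when the
  # estimate is uninformative about the effect)
  expect_equal(full$p_effect, 0.5, tolerance = 0.01)
  expect_equal(full$p_heterogeneity, 0.5, tolerance = 0.01)
})

test_that("BMA equals the renormalized bias-absent slice of the full fit", {
  st <- mild_meta()
  setts <- fast_settings(seed = 6)
  ens <- build_ensemble()
  full <- fit_ensemble(ens, st, setts)
  bma <- fit_ensemble(restrict_to_bma(ens), st, setts)
  none <- vapply(ens, function(s) s$bias$kind == "none", TRUE)
  slice <- full$posterior_model_probs[none]
  expect_equal(bma$posterior_model_probs, slice / sum(slice),
               tolerance = 1e-6)
})

test_that("Bayes factor evidence categories use the standard bands", {
  expect_identical(categorize_evidence(11), "strong_alt")
  expect_identical(categorize_evidence(1), "undecided")
  expect_identical(categorize_evidence(0.05), "strong_null")
  expect_identical(categorize_evidence(c(3, 10, 1 / 3, 0.3, 1 / 10)),
                   c("undecided", "moderate_alt", "undecided",
                     "moderate_null", "moderate_null"))
  expect_error(categorize_evidence(0), "bf10")
})

test_that("the averaged interval covers the mixture and includes the null mass", {
  st <- mild_meta()
  fit <- fit_ensemble(build_ensemble(), st, fast_settings(seed = 2))
  ci <- fit$averaged_ci_z
  expect_lt(ci[1], ci[2])
  expect_gte(fit$averaged_effect_mean_z, ci[1])
  expect_lte(fit$averaged_effect_mean_z, ci[2])
  expect_equal(fit$averaged_ci_r, tanh(ci))
})
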