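# shared fixtures and settings for the suite; everything is generated in
# code under fixed seeds

fast_settings <- function(seed = 1)
  integration_settings(preset = "small", seed = seed)

fast_config <- function(seed = 1)
  robmeta_config(integration = fast_settings(seed))

# a small heterogeneous-precision meta-analysis with a clear positive effect
strong_meta <- function(k = 20, mu = 0.3, seed = 3) {
  withr_seed(seed)
  make_studies(z = rnorm(k, mu, 0.05), se_z = runif(k, 0.03, 0.09))
}

# moderate, noisy meta-analysis
mild_meta <- function(k = 12, seed = 9) {
  withr_seed(seed)
  make_studies(z = rnorm(k, 0.15, 0.15), se_z = runif(k, 0.08, 0.3))
}

withr_seed <- function(seed) set.seed(seed)

# closed-form log marginal likelihood for a normal effect prior,
# point tau = 0, no bias: z ~ MVN(m0 * 1, diag(se^2) + s0^2 * J)
conjugate_lnml <- function(z, se, m0, s0) {
  S <- diag(se^2, nrow = length(se)) + s0^2
  r <- z - m0
  -0.5 * (length(z) * log(2 * pi) +
            as.numeric(determinant(S)$modulus) +
            drop(t(r) %*% solve(S, r)))
}

# restricted (REML) log-likelihood of the random-effects model, for the
# profile-grid oracle
reml_ll <- function(tau2, z, se) {
  v <- se^2 + tau2
  w <- 1 / v
  mhat <- sum(w * z) / sum(w)
  -0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (z - mhat)^2))
}
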