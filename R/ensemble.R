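#' Build the 36-model publication-bias model-averaging ensemble
#'
#' The ensemble crosses three binary research hypotheses — presence of the
#' effect, presence of between-study heterogeneity, presence of publication
#' bias — each with prior probability 1/2. The bias-present half of each
#' effect-by-heterogeneity cell is split equally between the selection-model
#' family and the PET/PEESE family, then equally within family, giving
#' 2 x 2 x (1 + 6 + 2) = 36 models with prior probabilities 1/8 (no bias),
#' 1/96 (each selection model), and 1/32 (PET and PEESE).
#'
#' Effect and heterogeneity priors are stated on the Cohen's d scale and
#' rescaled to the Fisher z analysis scale (see [rescale_prior_d_to_z()]):
#' effect absent is a point mass at zero, effect present defaults to
#' `Normal(0, 1)` on d (alternatively the Oosterwijk prior
#' `Student-t+(0.35, 0.10, 3)`); heterogeneity absent is `tau = 0`,
#' heterogeneity present is `Inverse-Gamma(1, 0.15)` on d. The PET and PEESE
#' coefficients have `Cauchy+(0, 1)` and `Cauchy+(0, 5)` priors on d,
#' enforcing a positive relationship between standard error and effect size.
#'
#' @param effect_prior_alt Continuous effect prior on the d scale, or one of
#'   the shortcuts `"normal"` / `"oosterwijk"`.
#' @param prior_rescale `"exact"` or `"linear"` d-to-z mapping for the
#'   effect prior (see [rescale_prior_d_to_z()]).
#' @param weight_functions List of [weight_function()]s for the selection
#'   models; defaults to [default_weight_functions()].
#' @param tau_prior_alt Heterogeneity prior on the d scale.
#' @param pet_prior_d,peese_prior_d Coefficient priors on the d scale.
#' @return A list of 36 [model_spec()]s whose prior probabilities sum to 1.
#' @export
build_ensemble <- function(effect_prior_alt = "normal",
                           prior_rescale = c("exact", "linear"),
                           weight_functions = default_weight_functions(),
                           tau_prior_alt = prior_invgamma(1, 0.15),
                           pet_prior_d = prior_cauchy_plus(0, 1),
                           peese_prior_d = prior_cauchy_plus(0, 5)) {
  prior_rescale <- match.arg(prior_rescale)
  if (is.character(effect_prior_alt))
    effect_prior_alt <- switch(match.arg(effect_prior_alt, c("normal", "oosterwijk")),
                               normal = prior_normal(0, 1),
                               oosterwijk = prior_student_t_plus(0.35, 0.10, 3))
  stopifnot(inherits(effect_prior_alt, "robmeta_prior"),
            !is_point_prior(effect_prior_alt))
  n_wf <- length(weight_functions)
  effect_priors <- list(null = prior_point(0),
                        alt = rescale_prior_d_to_z(effect_prior_alt, prior_rescale))
  tau_priors <- list(null = prior_point(0),
                     alt = rescale_prior_d_to_z(tau_prior_alt))
  biases <- c(list(list(b = bias_none(), p = 1 / 2, lab = "none")),
              lapply(weight_functions, function(wf)
                list(b = bias_selection(wf), p = 1 / 4 / n_wf,
                     lab = sprintf("sel_%s_%s", wf$sidedness,
                                   paste(wf$cutpoints, collapse = ",")))),
              list(list(b = bias_pet(rescale_coef_prior_d_to_z(pet_prior_d, 1)),
                        p = 1 / 8, lab = "pet"),
                   list(b = bias_peese(rescale_coef_prior_d_to_z(peese_prior_d, 2)),
                        p = 1 / 8, lab = "peese")))
  specs <- list()
  id <- 0L
  for (ef in c("null", "alt")) for (tf in c("null", "alt")) for (bs in biases) {
    id <- id + 1L
    specs[[id]] <- model_spec(
      effect_prior = effect_priors[[ef]],
      heterogeneity_prior = tau_priors[[tf]],
      bias = bs$b,
      prior_prob = 0.5 * 0.5 * 0.5 * bs$p / 0.5,  # P(effect) x P(tau) x P(bias cell share)
      id = id,
      label = sprintf("effect_%s.tau_%s.%s", ef, tf, bs$lab))
  }
  specs
}

#' Restrict an ensemble to its publication-bias-unadjusted members
#'
#' Drops every model with a bias component and renormalizes the prior model
#' probabilities, so the prior probability of the effect being present is
#' again 1/2. The result is an ordinary Bayesian model-averaged
#' meta-analysis (BMA) over the 2 x 2 effect-by-heterogeneity factorial.
#'
#' @param ensemble A list of [model_spec()]s from [build_ensemble()].
#' @export
restrict_to_bma <- function(ensemble) {
  keep <- Filter(function(s) s$bias$kind == "none", ensemble)
  if (!length(keep)) stop("ensemble has no bias-absent members")
  tot <- sum(vapply(keep, function(s) s$prior_prob, 0))
  lapply(keep, function(s) { s$prior_prob <- s$prior_prob / tot; s })
}

is_effect_model <- function(s) !is_point_prior(s$effect_prior)
is_het_model <- function(s) !is_point_prior(s$heterogeneity_prior)
is_bias_model <- function(s) s$bias$kind != "none"

inclusion_bf <- function(post_p, prior_p) {
  if (post_p >= 1) return(Inf)
  if (post_p <= 0) return(0)
  (post_p / (1 - post_p)) / (prior_p / (1 - prior_p))
}

#' Fit a model ensemble and model-average the results
#'
#' Fits every member (see [fit_model()]), converts prior model probabilities
#' and marginal likelihoods into posterior model probabilities via
#' log-sum-exp, and derives component posterior probabilities and inclusion
#' Bayes factors for effect, heterogeneity and publication bias, plus the
#' model-averaged posterior of the mean effect: a probability-weighted
#' mixture of the conditional posteriors, with point-effect models
#' contributing a point mass at zero.
#'
#' The r-scale estimate is the posterior mean of `tanh(mu)` under the
#' mixture (not `tanh` of the z-scale mean); both are returned. The 95%
#' interval is the central interval of the mixture, point mass included.
#'
#' @param ensemble List of [model_spec()]s.
#' @param studies Study data frame.
#' @param settings [integration_settings()].
#' @return A `robmeta_ensemble_fit` with elements `fitted`, `model_table`,
#'   `posterior_model_probs`, `p_effect`, `p_heterogeneity`, `p_bias`,
#'   `bf_effect`, `bf_heterogeneity`, `bf_bias`, `averaged_effect_mean_z`,
#'   `averaged_effect_mean_r`, `averaged_ci_z`, `averaged_ci_r`, `mixture`.
#' @export
fit_ensemble <- function(ensemble, studies, settings = integration_settings()) {
  check_studies(studies)
  if (nrow(studies) < 3)
    warning("fewer than 3 studies; model-averaged results rest heavily on the priors")
  fitted <- lapply(ensemble, fit_model, studies = studies, settings = settings)
  lnml <- vapply(fitted, function(f) f$ln_marg_lik, 0)
  prior_p <- vapply(ensemble, function(s) s$prior_prob, 0)
  if (abs(sum(prior_p) - 1) > 1e-8)
    stop("ensemble prior model probabilities must sum to 1")
  if (all(!is.finite(lnml))) stop("all ensemble members failed to fit")
  lp <- log(prior_p) + lnml
  post <- exp(lp - log_sum_exp(lp))
  post[post < 1e-300] <- 0
  post <- post / sum(post)

  comp <- function(sel) {
    pp <- sum(prior_p[sel]); qq <- sum(post[sel])
    list(prior = pp, post = qq, bf = inclusion_bf(qq, pp))
  }
  eff <- comp(vapply(ensemble, is_effect_model, TRUE))
  het <- comp(vapply(ensemble, is_het_model, TRUE))
  bia <- comp(vapply(ensemble, is_bias_model, TRUE))

  mix <- mixture_effect_posterior(fitted, post, settings)
  mean_z <- sum(post * vapply(fitted, function(f) f$effect$mean_z, 0))
  mean_r <- sum(post * vapply(fitted, function(f) f$effect$mean_r, 0))

  flagged <- which(vapply(fitted, function(f) isTRUE(f$flagged), TRUE))
  tab <- data.frame(
    id = vapply(ensemble, function(s) s$id, 0L),
    label = vapply(ensemble, function(s) s$label %||% "", ""),
    prior_prob = prior_p, ln_marg_lik = lnml, posterior_prob = post,
    method = vapply(fitted, function(f) f$method, ""),
    ln_ml_error = vapply(fitted, function(f) f$ln_ml_error, 0))

  structure(list(fitted = fitted, model_table = tab,
                 posterior_model_probs = post,
                 p_effect = eff$post, p_heterogeneity = het$post, p_bias = bia$post,
                 prior_p_effect = eff$prior, prior_p_heterogeneity = het$prior,
                 prior_p_bias = bia$prior,
                 bf_effect = eff$bf, bf_heterogeneity = het$bf, bf_bias = bia$bf,
                 averaged_effect_mean_z = mean_z,
                 averaged_effect_mean_r = mean_r,
                 averaged_ci_z = mix$ci_z, averaged_ci_r = tanh(mix$ci_z),
                 mixture = mix,
                 warnings = if (length(flagged))
                   sprintf("members with uncertain marginal likelihood: %s",
                           paste(flagged, collapse = ",")) else character(0)),
            class = "robmeta_ensemble_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## model-averaged posterior of mu on a common z grid; point-effect models
## contribute point masses (virtually always at z = 0)
mixture_effect_posterior <- function(fitted, post, settings) {
  cont <- which(vapply(fitted, function(f) !isTRUE(f$effect$point_mass), TRUE) &
                  post > 0)
  pts <- which(vapply(fitted, function(f) isTRUE(f$effect$point_mass), TRUE) &
                 post > 0)
  point_loc <- 0; point_mass <- 0
  if (length(pts)) {
    locs <- vapply(fitted[pts], function(f) f$effect$mean_z, 0)
    point_loc <- locs[1]
    point_mass <- sum(post[pts])
  }
  if (!length(cont)) {
    return(list(grid = point_loc, dens = NA_real_, point_mass = point_mass,
                point_loc = point_loc, ci_z = c(point_loc, point_loc)))
  }
  rng <- range(unlist(lapply(fitted[cont], function(f) range(f$effect$mu))))
  rng <- range(c(rng, point_loc))
  grid <- seq(rng[1], rng[2], length.out = 2L * settings$density_points)
  dens <- rep(0, length(grid))
  for (i in cont) {
    di <- stats::approx(fitted[[i]]$effect$mu, fitted[[i]]$effect$dens,
                        xout = grid, yleft = 0, yright = 0)$y
    area <- trapz_area(grid, di)
    if (area > 0) dens <- dens + post[i] * di / area
  }
  ci <- mixture_ci(grid, dens, point_loc, point_mass, c(0.025, 0.975))
  list(grid = grid, dens = dens, point_mass = point_mass,
       point_loc = point_loc, ci_z = ci)
}

trapz_area <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

## central quantiles of continuous density + one point mass
mixture_ci <- function(grid, dens, point_loc, point_mass, probs) {
  inc <- c(0, cumsum(diff(grid) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2))
  cont_mass <- max(inc)
  if (cont_mass > 0) inc <- inc * (1 - point_mass) / cont_mass
  at_loc <- stats::approx(grid, inc, xout = point_loc, ties = "ordered",
                          yleft = 0, yright = max(inc))$y
  vapply(probs, function(q) {
    if (point_mass > 0 && q >= at_loc && q <= at_loc + point_mass)
      return(point_loc)
    qc <- if (q > at_loc + point_mass) q - point_mass else q
    qc <- min(max(qc, 0), max(inc))
    stats::approx(inc, grid, xout = qc, ties = "ordered")$y
  }, 0)
}

#' Evidence category of a Bayes factor
#'
#' Standard rule-of-thumb bands: `BF > 10` strong and `BF > 3` moderate
#' evidence for the alternative; reciprocals for the null; in between,
#' undecided.
#'
#' @param bf10 Positive Bayes factors for the alternative versus the null.
#' @return Character vector with levels `strong_null`, `moderate_null`,
#'   `undecided`, `moderate_alt`, `strong_alt`.
#' @export
categorize_evidence <- function(bf10) {
  if (any(is.na(bf10)) || any(bf10 <= 0)) stop("bf10 must be > 0")
  ifelse(bf10 < 1 / 10, "strong_null",
    ifelse(bf10 < 1 / 3, "moderate_null",
      ifelse(bf10 <= 3, "undecided",
        ifelse(bf10 <= 10, "moderate_alt", "strong_alt"))))
}

#' @export
print.robmeta_ensemble_fit <- function(x, digits = 3, ...) {
  cat("Model-averaged meta-analysis (", nrow(x$model_table), " models)\n", sep = "")
  cat(sprintf("  P(effect | data) = %.3f   BF_effect = %.3g\n",
              x$p_effect, x$bf_effect))
  cat(sprintf("  P(heterogeneity | data) = %.3f   BF_het = %.3g\n",
              x$p_heterogeneity, x$bf_heterogeneity))
  cat(sprintf("  P(bias | data) = %.3f   BF_bias = %.3g\n",
              x$p_bias, x$bf_bias))
  cat(sprintf("  mean effect: z = %.*f, r = %.*f, 95%% CI on r [%.*f, %.*f]\n",
              digits, x$averaged_effect_mean_z, digits, x$averaged_effect_mean_r,
              digits, x$averaged_ci_r[1], digits, x$averaged_ci_r[2]))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}
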