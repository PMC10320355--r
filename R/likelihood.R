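#' p-value of a primary study on the Fisher z scale
#'
#' One-sided p-values test against the positive direction (the direction
#' publication selection is assumed to favour after corpus orientation);
#' two-sided p-values are the usual `2 * (1 - Phi(|z|/se))`.
#'
#' @param z Fisher z estimates.
#' @param se_z Standard errors, > 0.
#' @param sidedness `"one_sided"` or `"two_sided"`.
#' @export
p_value <- function(z, se_z, sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  if (any(se_z <= 0)) stop("se_z must be > 0")
  stat <- z / se_z
  if (sidedness == "one_sided") stats::pnorm(stat, lower.tail = FALSE)
  else 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
}

#' Step weight functions over p-value intervals
#'
#' A weight function partitions (0, 1] into `J = length(cutpoints) + 1`
#' p-value intervals; each interval carries a publication weight `omega`,
#' with `omega[1] = 1` for the most significant interval and non-increasing
#' weights thereafter. A p-value equal to a cutpoint falls in the more
#' significant interval.
#'
#' @param cutpoints Strictly increasing p-value cut-offs in (0, 1).
#' @param sidedness `"one_sided"` or `"two_sided"`: which p-value the
#'   cut-offs apply to.
#' @export
weight_function <- function(cutpoints, sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1 || any(diff(cutpoints) <= 0) ||
      any(cutpoints <= 0 | cutpoints >= 1))
    stop("cutpoints must be strictly increasing and inside (0,1)")
  structure(list(cutpoints = cutpoints, sidedness = sidedness,
                 J = length(cutpoints) + 1L),
            class = "robmeta_weightfun")
}

#' The default set of six selection weight functions
#'
#' Two two-sided weight functions (cut-offs at .05; .05 and .10) and four
#' one-sided ones (.05; .025 and .05; .05 and .5; .025, .05 and .5),
#' combining significance and marginal-significance thresholds with the
#' direction of the effect.
#'
#' @return A list of six [weight_function()] objects.
#' @export
default_weight_functions <- function() {
  list(weight_function(c(0.05), "two_sided"),
       weight_function(c(0.05, 0.10), "two_sided"),
       weight_function(c(0.05), "one_sided"),
       weight_function(c(0.025, 0.05), "one_sided"),
       weight_function(c(0.05, 0.5), "one_sided"),
       weight_function(c(0.025, 0.05, 0.5), "one_sided"))
}

#' Cumulative-sum map from Dirichlet interval masses to step weights
#'
#' `omega_j = sum(eta[j:J])`, so `omega[1] = 1` and `omega` is
#' non-increasing. With `eta ~ Dirichlet(1, ..., 1)` this is the cumulative
#' unit Dirichlet prior on the weights, which favours smaller weights at
#' larger p-values.
#'
#' @param eta A simplex vector, or a matrix whose rows are simplex vectors.
#' @return Weights in the same shape as `eta`.
#' @export
omega_from_eta <- function(eta) {
  if (is.matrix(eta)) {
    if (any(eta < 0) || any(abs(rowSums(eta) - 1) > 1e-8))
      stop("eta rows must be nonnegative and sum to 1")
    out <- pmin(t(apply(eta, 1, function(e) rev(cumsum(rev(e))))), 1)
    out[, 1] <- 1   # exact unit weight for the most significant interval
    out
  } else {
    if (any(eta < 0) || abs(sum(eta) - 1) > 1e-8)
      stop("eta must be nonnegative and sum to 1")
    out <- pmin(rev(cumsum(rev(eta))), 1)
    out[1] <- 1
    out
  }
}

## interval index of each p-value: 1 = most significant; boundary p goes to
## the more significant interval
p_interval_index <- function(p, wf) {
  findInterval(p, wf$cutpoints, left.open = TRUE) + 1L
}

## Pr(p-value falls in each interval | z_i ~ N(mu, s_i)), for one draw of
## (mu, tau) across all studies: returns K x J matrix.
## Cut-offs on p map to thresholds on z via the sidedness-appropriate
## inverse; interval probabilities are normal CDF differences under the
## marginal distribution N(mu, s), s = sqrt(tau^2 + se^2).
interval_probs <- function(se, s, mu, wf) {
  K <- length(se)
  J <- wf$J
  out <- matrix(0, K, J)
  if (wf$sidedness == "one_sided") {
    ## interval j <=> z in [t_j, t_{j-1}), t_j = se * qnorm(1 - a_j)
    tq <- stats::qnorm(1 - wf$cutpoints)           # decreasing
    b <- cbind(Inf, outer(se, tq), -Inf)           # K x (J+1)
    for (j in seq_len(J))
      out[, j] <- stats::pnorm((b[, j] - mu) / s) -
                  stats::pnorm((b[, j + 1L] - mu) / s)
  } else {
    tq <- stats::qnorm(1 - wf$cutpoints / 2)
    b <- cbind(Inf, outer(se, tq), 0)              # |z| thresholds
    for (j in seq_len(J))
      out[, j] <- (stats::pnorm((b[, j] - mu) / s) -
                   stats::pnorm((b[, j + 1L] - mu) / s)) +
                  (stats::pnorm((-b[, j + 1L] - mu) / s) -
                   stats::pnorm((-b[, j] - mu) / s))
  }
  pmax(out, 0)
}

#' Random-effects log-likelihood on the Fisher z scale
#'
#' `sum_i log phi(z_i; mu, sqrt(tau^2 + se_i^2))` — the marginal likelihood
#' of the normal-normal random-effects model with the true-effect
#' distribution integrated out.
#'
#' @param studies Data frame with columns `z` and `se_z` (see
#'   [make_studies()]).
#' @param mu Mean effect on the z scale.
#' @param tau Between-study standard deviation on the z scale, >= 0.
#' @export
ln_lik_random_effects <- function(studies, mu, tau) {
  check_studies(studies)
  if (tau < 0) stop("tau must be >= 0")
  s <- sqrt(tau^2 + studies$se_z^2)
  sum(stats::dnorm(studies$z, mu, s, log = TRUE))
}

#' Selection-model (weighted) log-likelihood
#'
#' Vevea-Hedges style weighted likelihood: each study's density is
#' multiplied by the step weight of its observed p-value and divided by the
#' per-study normalizing constant `A_i = sum_j omega_j Pr(p in interval j |
#' mu, tau, se_i)`.
#'
#' @inheritParams ln_lik_random_effects
#' @param wf A [weight_function()].
#' @param omega Weight vector of length `wf$J` with positive entries;
#'   `omega[1]` is the weight of the most significant interval. Only the
#'   ratios of weights matter.
#' @export
ln_lik_selection <- function(studies, mu, tau, wf, omega) {
  check_studies(studies)
  stopifnot(inherits(wf, "robmeta_weightfun"), length(omega) == wf$J)
  if (tau < 0) stop("tau must be >= 0")
  if (any(omega <= 0)) stop("all omega must be > 0")
  se <- studies$se_z
  s <- sqrt(tau^2 + se^2)
  idx <- p_interval_index(p_value(studies$z, se, wf$sidedness), wf)
  A <- drop(interval_probs(se, s, mu, wf) %*% omega)
  sum(log(omega[idx]) + stats::dnorm(studies$z, mu, s, log = TRUE) - log(A))
}

#' PET/PEESE meta-regression log-likelihood
#'
#' Regression of the effect on the standard error (PET, `order = 1`) or the
#' squared standard error (PEESE, `order = 2`):
#' `sum_i log phi(z_i; mu + coef * se_i^order, sqrt(tau^2 + se_i^2))`.
#' The intercept `mu` is the bias-corrected effect.
#'
#' @inheritParams ln_lik_random_effects
#' @param coef Regression coefficient, >= 0 under the half-Cauchy prior.
#' @param order 1 for PET, 2 for PEESE.
#' @export
ln_lik_pet_peese <- function(studies, mu, tau, coef, order) {
  check_studies(studies)
  if (!order %in% c(1, 2)) stop("order must be 1 (PET) or 2 (PEESE)")
  if (tau < 0) stop("tau must be >= 0")
  s <- sqrt(tau^2 + studies$se_z^2)
  sum(stats::dnorm(studies$z, mu + coef * studies$se_z^order, s, log = TRUE))
}

check_studies <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) < 1)
    stop("studies must be a data frame with at least one row")
  if (!all(c("z", "se_z") %in% names(studies)))
    stop("studies must have columns z and se_z")
  if (any(studies$se_z <= 0)) stop("all se_z must be > 0")
  invisible(TRUE)
}

## ---- vectorized internals (over N parameter draws) ---------------------
## z, se: length K; mu, tau: length N; return length N log-likelihoods.
## Hot loops live in src/likelihoods.cpp; the scalar operations above are
## the reference implementations the C++ kernels are tested against.

LN_SQRT_2PI <- 0.918938533204672742

ll_re_vec <- function(z, se, mu, tau) {
  ll_re_cpp(z, se, rep_len(mu, length(mu)), rep_len(tau, length(mu)))
}

ll_petpeese_vec <- function(z, se, mu, tau, coef, order) {
  N <- max(length(mu), length(coef))
  ll_petpeese_cpp(z, se, rep_len(mu, N), rep_len(tau, N),
                  rep_len(coef, N), as.integer(order))
}

## omega: N x J matrix
ll_sel_vec <- function(z, se, mu, tau, wf, omega) {
  one_sided <- wf$sidedness == "one_sided"
  cut_q <- if (one_sided) stats::qnorm(1 - wf$cutpoints)
           else stats::qnorm(1 - wf$cutpoints / 2)
  idx <- p_interval_index(p_value(z, se, wf$sidedness), wf)
  N <- length(mu)
  ll_sel_cpp(z, se, mu, rep_len(tau, N), omega, cut_q,
             as.integer(idx), one_sided)
}
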