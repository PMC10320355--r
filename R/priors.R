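#' Prior distribution specifications
#'
#' Constructors for the prior families used by the model ensemble: point
#' masses, normal, inverse-gamma (for heterogeneity), half/truncated Cauchy
#' and Student-t (for positive regression coefficients and shifted effect
#' priors), and the cumulative unit Dirichlet prior over step-function
#' weights. Each returns a lightweight `robmeta_prior` object understood by
#' [prior_logpdf()], [prior_quantile()] and [prior_rng()].
#'
#' Truncated families are renormalized over their support `[lower, Inf)`.
#' The inverse-gamma uses the shape/scale parameterization with density
#' `b^a / Gamma(a) * x^(-a-1) * exp(-b/x)`.
#'
#' @param location,mean,sd,shape,scale,df,lower Family parameters; scales,
#'   shapes and degrees of freedom must be positive.
#' @param alpha Concentration vector of the Dirichlet prior on the interval
#'   masses `eta`; cumulative tail sums of `eta` give the non-increasing
#'   step weights `omega` with `omega[1] = 1`.
#' @return An object of class `robmeta_prior`.
#' @name priors
NULL

new_prior <- function(family, params, label = NULL) {
  structure(list(family = family, params = params, label = label),
            class = "robmeta_prior")
}

#' @rdname priors
#' @export
prior_point <- function(location = 0) {
  stopifnot(is.finite(location))
  new_prior("point", list(location = location))
}

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  new_prior("normal", list(mean = mean, sd = sd))
}

#' @rdname priors
#' @export
prior_invgamma <- function(shape = 1, scale = 0.15) {
  stopifnot(shape > 0, scale > 0)
  new_prior("inverse_gamma", list(shape = shape, scale = scale))
}

#' @rdname priors
#' @export
prior_cauchy_plus <- function(location = 0, scale = 1, lower = 0) {
  stopifnot(scale > 0, is.finite(location))
  new_prior("cauchy_plus", list(location = location, scale = scale, lower = lower))
}

#' @rdname priors
#' @export
prior_student_t_plus <- function(location = 0.35, scale = 0.10, df = 3, lower = 0) {
  stopifnot(scale > 0, df > 0, is.finite(location))
  new_prior("student_t_plus",
            list(location = location, scale = scale, df = df, lower = lower))
}

#' @rdname priors
#' @export
prior_cumdirichlet <- function(alpha) {
  stopifnot(length(alpha) >= 2, all(alpha > 0))
  new_prior("cumulative_dirichlet", list(alpha = as.numeric(alpha)))
}

#' @export
print.robmeta_prior <- function(x, ...) {
  p <- paste(names(x$params), vapply(x$params, function(v)
    paste(signif(unlist(v), 4), collapse = ","), ""), sep = "=", collapse = ", ")
  cat(sprintf("<prior %s(%s)>\n", x$family, p))
  invisible(x)
}

is_point_prior <- function(prior) identical(prior$family, "point")

## truncation mass below the lower bound, on the untruncated scale
trunc_p0 <- function(prior) {
  with(prior$params, switch(prior$family,
    cauchy_plus = stats::pcauchy(lower, location, scale),
    student_t_plus = stats::pt((lower - location) / scale, df),
    stop("not a truncated family")))
}

#' Log prior density
#'
#' @param prior A `robmeta_prior`.
#' @param x Numeric vector of evaluation points (for the cumulative Dirichlet
#'   family, a matrix of `eta` rows is required instead; see
#'   [omega_from_eta()]).
#' @return Log density at `x`; `-Inf` outside the support. Point priors are
#'   degenerate: `prior_logpdf()` returns `0` at the atom and `-Inf`
#'   elsewhere (log of a unit point mass, not a density).
#' @export
prior_logpdf <- function(prior, x) {
  stopifnot(inherits(prior, "robmeta_prior"))
  p <- prior$params
  switch(prior$family,
    point = ifelse(x == p$location, 0, -Inf),
    normal = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    inverse_gamma = ifelse(x > 0,
      p$shape * log(p$scale) - lgamma(p$shape) -
        (p$shape + 1) * log(x) - p$scale / x, -Inf),
    cauchy_plus = ifelse(x >= p$lower,
      stats::dcauchy(x, p$location, p$scale, log = TRUE) -
        log1p(-trunc_p0(prior)), -Inf),
    student_t_plus = ifelse(x >= p$lower,
      stats::dt((x - p$location) / p$scale, p$df, log = TRUE) - log(p$scale) -
        log1p(-trunc_p0(prior)), -Inf),
    d_to_z = prior_logpdf_d_to_z(prior, x),
    stop("prior_logpdf not defined for family '", prior$family, "'"))
}

#' Prior quantile function
#'
#' @param prior A univariate continuous `robmeta_prior` (or a point prior,
#'   which returns its atom).
#' @param q Probabilities in `[0, 1]`.
#' @export
prior_quantile <- function(prior, q) {
  stopifnot(inherits(prior, "robmeta_prior"), all(q >= 0 & q <= 1))
  p <- prior$params
  switch(prior$family,
    point = rep(p$location, length(q)),
    normal = stats::qnorm(q, p$mean, p$sd),
    inverse_gamma = 1 / stats::qgamma(1 - q, p$shape, rate = p$scale),
    cauchy_plus = {
      p0 <- trunc_p0(prior)
      stats::qcauchy(p0 + q * (1 - p0), p$location, p$scale)
    },
    student_t_plus = {
      p0 <- trunc_p0(prior)
      p$location + p$scale * stats::qt(p0 + q * (1 - p0), p$df)
    },
    d_to_z = d_to_z_inverse(prior_quantile(prior$params$base, q),
                            prior$params$mapping),
    stop("prior_quantile not defined for family '", prior$family, "'"))
}

#' Draw from a prior
#'
#' Uses the current RNG state. For the cumulative Dirichlet family a matrix
#' of `omega` rows is returned (see [omega_from_eta()]); otherwise a numeric
#' vector.
#'
#' @param prior A `robmeta_prior`.
#' @param n Number of draws.
#' @export
prior_rng <- function(prior, n) {
  stopifnot(inherits(prior, "robmeta_prior"))
  if (prior$family == "cumulative_dirichlet") {
    a <- prior$params$alpha
    g <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)), nrow = n)
    eta <- g / rowSums(g)
    return(omega_from_eta(eta))
  }
  prior_quantile(prior, stats::runif(n))
}

## ---- d-scale to Fisher-z-scale prior rescaling -------------------------

## Mappings between Cohen's d and Fisher z for the same underlying
## correlation: exactly d = 2 r / sqrt(1 - r^2) with r = tanh(z), which
## simplifies to d = 2 sinh(z); the linearization is d = 2 z.
d_to_z_forward <- function(z, mapping) {   # z -> d
  switch(mapping, exact = 2 * sinh(z), linear = 2 * z,
         stop("unknown mapping '", mapping, "'"))
}
d_to_z_inverse <- function(d, mapping) {   # d -> z
  switch(mapping, exact = asinh(d / 2), linear = d / 2,
         stop("unknown mapping '", mapping, "'"))
}
d_to_z_logjac <- function(z, mapping) {    # log |dd/dz|
  switch(mapping, exact = log(2) + log(cosh(z)), linear = rep(log(2), length(z)),
         stop("unknown mapping '", mapping, "'"))
}

prior_logpdf_d_to_z <- function(prior, z) {
  m <- prior$params$mapping
  prior_logpdf(prior$params$base, d_to_z_forward(z, m)) + d_to_z_logjac(z, m)
}

#' Re-express a Cohen's d scale prior on the Fisher z analysis scale
#'
#' Effect size priors are stated on the Cohen's d scale, while the
#' likelihoods operate on Fisher z. The exact change of variables uses
#' `d = 2 sinh(z)` (equivalently `d = 2 r / sqrt(1 - r^2)`, `r = tanh(z)`),
#' applied to densities with the full Jacobian; the linear alternative uses
#' the small-effect approximation `d = 2 z`. Point masses map their
#' location. Heterogeneity priors (`inverse_gamma` on the standard deviation
#' tau) are rescaled by the local linearization `tau_z = tau_d / 2` in both
#' modes, since a distribution on a scale parameter has no exact pushforward
#' under a nonlinear mean map.
#'
#' @param prior A `robmeta_prior` on the d scale (point, normal, truncated
#'   Student-t, or inverse-gamma for tau).
#' @param mapping `"exact"` or `"linear"`.
#' @return A `robmeta_prior` on the z scale.
#' @export
rescale_prior_d_to_z <- function(prior, mapping = c("exact", "linear")) {
  mapping <- match.arg(mapping)
  stopifnot(inherits(prior, "robmeta_prior"))
  switch(prior$family,
    point = prior_point(d_to_z_inverse(prior$params$location, mapping)),
    inverse_gamma = prior_invgamma(prior$params$shape, prior$params$scale / 2),
    normal = ,
    student_t_plus = ,
    cauchy_plus = new_prior("d_to_z", list(base = prior, mapping = mapping),
                            label = paste0(prior$family, "_on_z")),
    stop("rescale_prior_d_to_z does not support family '", prior$family, "'"))
}

#' Rescale a PET/PEESE coefficient prior from the d scale to the z scale
#'
#' Under the small-effect linearization `d = 2 z` (so `se_d = 2 se_z`), a
#' meta-regression `d = mu_d + c_d * se_d^k` maps to
#' `z = mu_z + 2^(k-1) c_d * se_z^k`: the PET coefficient (k = 1) is scale
#' free, while the PEESE coefficient (k = 2) doubles. Applied to the
#' half-Cauchy scale parameter.
#'
#' @param prior A `cauchy_plus` (or `student_t_plus`) prior on the d scale.
#' @param order 1 for PET, 2 for PEESE.
#' @export
rescale_coef_prior_d_to_z <- function(prior, order) {
  stopifnot(order %in% c(1, 2),
            prior$family %in% c("cauchy_plus", "student_t_plus"))
  if (order == 1) return(prior)
  p <- prior$params
  p$scale <- 2 * p$scale
  new_prior(prior$family, p)
}
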