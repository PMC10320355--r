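#' Specify one ensemble member
#'
#' A model is the combination of an effect prior (point mass at zero or a
#' continuous prior on the mean effect mu, z scale), a heterogeneity prior
#' (point mass at zero or inverse-gamma on tau, z scale), and a publication
#' bias component: none, a selection model with a step weight function under
#' the cumulative unit Dirichlet prior, or a PET/PEESE meta-regression with
#' a positive-truncated coefficient prior.
#'
#' @param effect_prior,heterogeneity_prior `robmeta_prior` objects on the
#'   Fisher z scale.
#' @param bias A list created by [bias_none()], [bias_selection()],
#'   [bias_pet()] or [bias_peese()].
#' @param prior_prob Prior model probability in (0, 1].
#' @param id Integer identifier within the ensemble.
#' @param label Human-readable label.
#' @export
model_spec <- function(effect_prior, heterogeneity_prior, bias,
                       prior_prob, id = NA_integer_, label = NULL) {
  stopifnot(inherits(effect_prior, "robmeta_prior"),
            inherits(heterogeneity_prior, "robmeta_prior"),
            is.list(bias), !is.null(bias$kind),
            prior_prob > 0, prior_prob <= 1)
  if (!heterogeneity_prior$family %in% c("point", "inverse_gamma"))
    stop("heterogeneity prior must be a point mass or inverse-gamma")
  structure(list(effect_prior = effect_prior,
                 heterogeneity_prior = heterogeneity_prior,
                 bias = bias, prior_prob = prior_prob,
                 id = id, label = label),
            class = "robmeta_model_spec")
}

#' @rdname model_spec
#' @export
bias_none <- function() list(kind = "none")

#' @rdname model_spec
#' @param wf A [weight_function()].
#' @param omega_prior Prior on the weights; only the cumulative unit
#'   Dirichlet (`prior_cumdirichlet(rep(1, J))`) supports the deterministic
#'   quadrature path.
#' @export
bias_selection <- function(wf, omega_prior = prior_cumdirichlet(rep(1, wf$J))) {
  stopifnot(inherits(wf, "robmeta_weightfun"),
            length(omega_prior$params$alpha) == wf$J)
  list(kind = "selection", wf = wf, omega_prior = omega_prior)
}

#' @rdname model_spec
#' @param coef_prior Prior on the regression coefficient (z scale).
#' @export
bias_pet <- function(coef_prior = prior_cauchy_plus(0, 1)) {
  list(kind = "pet", coef_prior = coef_prior, order = 1)
}

#' @rdname model_spec
#' @export
bias_peese <- function(coef_prior = prior_cauchy_plus(0, 10)) {
  list(kind = "peese", coef_prior = coef_prior, order = 2)
}

#' @export
print.robmeta_model_spec <- function(x, ...) {
  cat(sprintf("<model %s: effect=%s, tau=%s, bias=%s, prior_prob=%.5g>\n",
              ifelse(is.na(x$id), "", x$id),
              x$effect_prior$family, x$heterogeneity_prior$family,
              x$bias$kind, x$prior_prob))
  invisible(x)
}

## number of free (continuous) dimensions of a model
model_dims <- function(spec) {
  d <- as.integer(!is_point_prior(spec$effect_prior)) +
       as.integer(!is_point_prior(spec$heterogeneity_prior))
  d + switch(spec$bias$kind, none = 0L,
             selection = spec$bias$wf$J - 1L,
             pet = , peese = 1L)
}

#' Numerical integration settings
#'
#' Controls how log marginal likelihoods and conditional posteriors are
#' computed. Models with at most 3 free dimensions use deterministic
#' tensor-product Gauss-Legendre quadrature on prior-quantile-transformed
#' coordinates (so the prior is absorbed into the measure and the integrand
#' is the likelihood alone); higher-dimensional models use prior-draw Monte
#' Carlo with a reported standard error on the log scale. The `"small"`
#' preset trades some Monte Carlo precision for speed.
#'
#' @param method `"auto"` (dimension-based choice), `"quadrature"` or
#'   `"mc"`.
#' @param mc_draws Number of prior draws for Monte Carlo integration.
#' @param nodes Gauss-Legendre nodes per dimension for 1-, 2- and
#'   3-dimensional quadrature.
#' @param rel_tol Threshold on the refinement error of the log marginal
#'   likelihood before a result is flagged.
#' @param seed Base seed; each model uses `seed + id` so results are
#'   reproducible and order-independent.
#' @param density_points Grid size for tabulated conditional posteriors.
#' @param preset `"default"` or `"small"`; the latter overrides `mc_draws`
#'   and `nodes` with cheaper values.
#' @export
integration_settings <- function(method = c("auto", "quadrature", "mc"),
                                 mc_draws = 20000, nodes = c(64, 32, 20),
                                 rel_tol = 0.01, seed = 1,
                                 density_points = 256,
                                 preset = c("default", "small")) {
  method <- match.arg(method)
  preset <- match.arg(preset)
  if (preset == "small") {
    if (missing(mc_draws)) mc_draws <- 4000
    if (missing(nodes)) nodes <- c(40, 24, 12)
  }
  stopifnot(mc_draws >= 100, length(nodes) == 3, all(nodes >= 4), seed == round(seed))
  structure(list(method = method, mc_draws = as.integer(mc_draws),
                 nodes = as.integer(nodes), rel_tol = rel_tol,
                 seed = as.integer(seed),
                 density_points = as.integer(density_points), preset = preset),
            class = "robmeta_integration_settings")
}

log_sum_exp <- function(x, w = NULL) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  if (is.null(w)) m + log(sum(exp(x - m))) else m + log(sum(w * exp(x - m)))
}

## evaluate the model log-likelihood at parameter draws
## mu, tau: length N; extra: N x (J-1)/1 matrix of bias coordinates in
## native parameterization (omega tail weights or regression coefficient)
model_ll <- function(spec, z, se, mu, tau, extra) {
  switch(spec$bias$kind,
    none = ll_re_vec(z, se, mu, tau),
    selection = {
      omega <- cbind(1, extra)
      ll_sel_vec(z, se, mu, tau, spec$bias$wf, omega)
    },
    pet = , peese =
      ll_petpeese_vec(z, se, mu, tau, drop(extra), spec$bias$order))
}

## exponent of the power substitution v = t^gamma that concentrates
## selection-model quadrature nodes and Monte Carlo proposals near zero
## weights, where the weighted likelihood can spike
OMEGA_TILT <- 4

## sequential-maximum transform: iid uniforms v (G x (J-1)) to the
## descending order statistics omega[2:J] of J-1 uniforms —
## omega_{k+1} = omega_k * v_k^(1/(J-1-k+1)) — smooth, unlike sorting
v_to_omega_tail <- function(V) {
  Jm1 <- ncol(V)
  out <- V
  for (k in seq_len(Jm1))
    out[, k] <- V[, k]^(1 / (Jm1 - k + 1))
  if (Jm1 > 1L)
    for (k in 2:Jm1) out[, k] <- out[, k - 1L] * out[, k]
  out
}

## map unit-cube coordinates (G x dims) to native parameters
## returns list(mu, tau, extra, logjac); ordering of dims: mu, tau, bias
cube_to_params <- function(spec, U) {
  G <- nrow(U)
  col <- 0L
  logjac <- rep(0, G)
  if (!is_point_prior(spec$effect_prior)) {
    col <- col + 1L
    mu <- prior_quantile(spec$effect_prior, U[, col])
  } else mu <- rep(spec$effect_prior$params$location, G)
  if (!is_point_prior(spec$heterogeneity_prior)) {
    col <- col + 1L
    tau <- prior_quantile(spec$heterogeneity_prior, U[, col])
  } else tau <- rep(spec$heterogeneity_prior$params$location, G)
  extra <- NULL
  if (spec$bias$kind == "selection") {
    Jm1 <- spec$bias$wf$J - 1L
    Tm <- U[, col + seq_len(Jm1), drop = FALSE]
    V <- Tm^OMEGA_TILT
    logjac <- log(OMEGA_TILT) * Jm1 + (OMEGA_TILT - 1) * rowSums(log(Tm))
    extra <- v_to_omega_tail(V)
  } else if (spec$bias$kind %in% c("pet", "peese")) {
    extra <- matrix(prior_quantile(spec$bias$coef_prior, U[, col + 1L]), ncol = 1)
  }
  list(mu = mu, tau = tau, extra = extra, logjac = logjac)
}

## selection models support the sorted-uniform quadrature path only under
## the unit Dirichlet
quadrable <- function(spec) {
  spec$bias$kind != "selection" ||
    all(spec$bias$omega_prior$params$alpha == 1)
}

## Per-dimension window of the unit cube that carries the likelihood mass,
## found by a coarse tensor scan. The prior-quantile transform alone cannot
## resolve likelihoods that are sharp relative to the prior (a precise
## meta-analysis concentrates the posterior of mu on a sliver of the prior),
## so quadrature nodes are placed inside the windowed box; the excluded
## region is at least e^25 below the peak and contributes negligibly.
quad_windows <- function(spec, z, se, dims, n_coarse = 21, drop = 25) {
  u_c <- seq(1e-4, 1 - 1e-4, length.out = n_coarse)
  G <- as.matrix(expand.grid(rep(list(seq_len(n_coarse)), dims)))
  U <- matrix(u_c[G], nrow(G), dims)
  par <- cube_to_params(spec, U)
  ll <- model_ll(spec, z, se, par$mu, par$tau, par$extra) + par$logjac
  ll[!is.finite(ll)] <- -Inf
  top <- max(ll)
  step <- u_c[2] - u_c[1]
  t(vapply(seq_len(dims), function(d) {
    prof <- vapply(seq_len(n_coarse), function(k)
      suppressWarnings(max(ll[G[, d] == k])), 0)
    keep <- which(prof >= top - drop)
    c(max(0, u_c[min(keep)] - step), min(1, u_c[max(keep)] + step))
  }, c(0, 1)))
}

quad_eval <- function(spec, z, se, n_nodes, dims, windows, want_effect) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), dims)))
  lo <- windows[, 1]; wid <- windows[, 2] - windows[, 1]
  U <- matrix(gl$x[idx], nrow(idx), dims)
  U <- sweep(sweep(U, 2, wid, "*"), 2, lo, "+")
  logw <- matrix(log(gl$w[idx]), nrow(idx), dims)
  logw <- rowSums(sweep(logw, 2, log(wid), "+"))
  par <- cube_to_params(spec, U)
  ll <- model_ll(spec, z, se, par$mu, par$tau, par$extra) + par$logjac
  lnml <- log_sum_exp(ll + logw)
  out <- list(ln_marg_lik = lnml)
  if (want_effect && !is_point_prior(spec$effect_prior)) {
    ## mu is the first cube dimension; aggregate over the others
    mu_idx <- idx[, 1]
    lw_mu <- log(gl$w) + log(wid[1])
    h <- vapply(seq_len(n_nodes), function(k) {
      sel <- mu_idx == k
      log_sum_exp(ll[sel] + logw[sel]) - lw_mu[k]
    }, 0)                                   # ln h(u_k): inner integral
    mass <- exp(h + lw_mu - lnml)           # posterior mass per mu node
    mass <- mass / sum(mass)
    u_mu <- lo[1] + wid[1] * gl$x
    mu_k <- prior_quantile(spec$effect_prior, u_mu)
    dens <- exp(h - lnml + prior_logpdf(spec$effect_prior, mu_k))
    out$effect <- list(point_mass = FALSE,
                       mean_z = sum(mass * mu_k),
                       mean_r = sum(mass * tanh(mu_k)),
                       mu = mu_k,
                       dens = dens / trapz_area(mu_k, dens))
  }
  out
}

## support of a univariate prior (used to clip integration windows)
prior_support <- function(prior) {
  p <- prior$params
  switch(prior$family,
    normal = c(-Inf, Inf),
    inverse_gamma = c(0, Inf),
    cauchy_plus = , student_t_plus = c(p$lower, Inf),
    d_to_z = d_to_z_inverse(prior_support(p$base), p$mapping),
    point = rep(p$location, 2),
    c(-Inf, Inf))
}
## Conditional quadrature for models with a "linear" parameter — the mean
## effect mu, or the PET/PEESE coefficient when mu is a point mass. Given
## the other parameters (tau, coefficient, selection weights), the
## likelihood in the linear parameter is a sharp normal around a weighted
## least-squares centre that moves with those parameters (the PET/PEESE
## mu/coefficient ridge being the worst case), so it gets its own
## Gauss-Legendre window around the conditional centre — shifted by the
## selection term's local gradient where applicable — intersected with the
## prior's bulk. A fixed tensor grid in prior-quantile space cannot track
## this structure.
quad_eval_cmu <- function(spec, z, se, n_mu, n_outer, want_effect,
                          density_points) {
  K <- length(z)
  tau_free <- !is_point_prior(spec$heterogeneity_prior)
  has_coef <- spec$bias$kind %in% c("pet", "peese")
  has_sel <- spec$bias$kind == "selection"
  lin_is_mu <- !is_point_prior(spec$effect_prior)
  stopifnot(lin_is_mu || has_coef)
  mu0 <- if (lin_is_mu) NA_real_ else spec$effect_prior$params$location
  x_design <- if (lin_is_mu) rep(1, K) else se^spec$bias$order
  lin_prior <- if (lin_is_mu) spec$effect_prior else spec$bias$coef_prior
  n_omega <- if (has_sel) spec$bias$wf$J - 1L else 0L
  coef_outer <- has_coef && lin_is_mu
  outer_dims <- as.integer(tau_free) + as.integer(coef_outer) + n_omega
  sup <- prior_support(lin_prior)
  pr_rng <- prior_quantile(lin_prior, c(1e-6, 1 - 1e-6))

  ## conditional centre/scale of the linear parameter given the rest
  cond_lin <- function(tau, coef) {
    G <- length(tau)
    s2 <- outer(se^2, tau^2, "+")                    # K x G
    wts <- 1 / s2
    offset <- if (lin_is_mu) {
      if (has_coef) outer(se^spec$bias$order, coef) else matrix(0, K, G)
    } else matrix(mu0, K, G)
    rw <- wts * (z - offset) * x_design
    denom <- colSums(wts * x_design^2)
    list(m = colSums(rw) / denom, sd = 1 / sqrt(denom))
  }
  ll_at <- function(lin, tau, coef, omega) {
    if (lin_is_mu) {
      extra <- if (has_coef) matrix(coef, ncol = 1) else omega
      model_ll(spec, z, se, lin, tau, extra)
    } else {
      model_ll(spec, z, se, rep(mu0, length(lin)), tau, matrix(lin, ncol = 1))
    }
  }
  ## unit-cube coordinates for the outer dims -> native parameters
  outer_params <- function(U) {
    G <- nrow(U)
    logjac <- rep(0, G)
    col <- 0L
    if (tau_free) { col <- col + 1L
      tau <- prior_quantile(spec$heterogeneity_prior, U[, col])
    } else tau <- rep(spec$heterogeneity_prior$params$location, G)
    coef <- rep(0, G); omega <- NULL
    if (coef_outer) coef <- prior_quantile(spec$bias$coef_prior, U[, col + 1L])
    if (has_sel) {
      Tm <- U[, col + seq_len(n_omega), drop = FALSE]
      logjac <- log(OMEGA_TILT) * n_omega + (OMEGA_TILT - 1) * rowSums(log(Tm))
      omega <- v_to_omega_tail(Tm^OMEGA_TILT)
    }
    list(tau = tau, coef = coef, omega = omega, logjac = logjac)
  }
  profiled_ll <- function(op) {
    cm <- cond_lin(op$tau, op$coef)
    lin <- pmin(pmax(cm$m, sup[1]), sup[2])
    ll_at(lin, op$tau, op$coef, op$omega) + op$logjac
  }
  ## coarse scan -> per-dim windows on the outer cube
  windows <- NULL
  if (outer_dims > 0L) {
    u_c <- seq(1e-4, 1 - 1e-4, length.out = 21)
    Gc <- as.matrix(expand.grid(rep(list(seq_len(21)), outer_dims)))
    llc <- profiled_ll(outer_params(matrix(u_c[Gc], nrow(Gc), outer_dims)))
    llc[!is.finite(llc)] <- -Inf
    top <- max(llc)
    step <- u_c[2] - u_c[1]
    windows <- t(vapply(seq_len(outer_dims), function(d) {
      prof <- vapply(seq_len(21), function(k)
        suppressWarnings(max(llc[Gc[, d] == k])), 0)
      keep <- which(prof >= top - 25)
      c(max(0, u_c[min(keep)] - step), min(1, u_c[max(keep)] + step))
    }, c(0, 1)))
  }
  outer_pts <- function(n_nodes) {
    if (outer_dims == 0L)
      return(c(outer_params(matrix(numeric(0), 1, 0)), list(logw = 0)))
    gl <- pracma::gaussLegendre(n_nodes, 0, 1)
    idx <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), outer_dims)))
    lo <- windows[, 1]; wid <- windows[, 2] - windows[, 1]
    U <- matrix(gl$x[idx], nrow(idx), outer_dims)
    U <- sweep(sweep(U, 2, wid, "*"), 2, lo, "+")
    logw <- rowSums(sweep(matrix(log(gl$w[idx]), nrow(idx), outer_dims),
                          2, log(wid), "+"))
    op <- outer_params(U)
    op$logw <- logw + op$logjac
    op
  }

  eval_at <- function(n_lin_nodes, n_outer_nodes, collect) {
    op <- outer_pts(n_outer_nodes)
    G <- length(op$tau)
    cm <- cond_lin(op$tau, op$coef)
    centre <- cm$m
    if (has_sel) {
      ## selection reweighting shifts the conditional mode by roughly
      ## sigma^2 times the gradient of the log selection term; estimate it
      ## by central differences and widen the window to cover both centres
      l0 <- pmin(pmax(cm$m, sup[1]), sup[2])
      d <- cm$sd / 2
      g <- (ll_at(l0 + d, op$tau, op$coef, op$omega) -
            ll_at(l0 - d, op$tau, op$coef, op$omega)) / (2 * d)
      shift <- pmin(pmax(g * cm$sd^2, -30 * cm$sd), 30 * cm$sd)
      centre <- cm$m + shift
    }
    lo <- pmax(pmin(cm$m, centre) - 10 * cm$sd, max(sup[1], pr_rng[1]))
    hi <- pmin(pmax(cm$m, centre) + 10 * cm$sd, min(sup[2], pr_rng[2]))
    bad <- hi <= lo
    if (any(bad)) {            # likelihood bulk outside the prior: keep the
      anchor <- pmin(pmax(centre, sup[1]), sup[2])    # nearest support edge
      lo[bad] <- pmax(anchor[bad] - 10 * cm$sd[bad], sup[1])
      hi[bad] <- pmin(anchor[bad] + 10 * cm$sd[bad], sup[2])
    }
    gl <- pracma::gaussLegendre(n_lin_nodes, 0, 1)
    ## N = G * n_lin evaluation points, the linear parameter varying fastest
    lin <- rep(lo, each = n_lin_nodes) +
      rep(hi - lo, each = n_lin_nodes) * gl$x
    tau <- rep(op$tau, each = n_lin_nodes)
    coef <- rep(op$coef, each = n_lin_nodes)
    omega <- if (has_sel) op$omega[rep(seq_len(G), each = n_lin_nodes), ,
                                   drop = FALSE] else NULL
    logw <- rep(op$logw, each = n_lin_nodes) +
      rep(log(hi - lo), each = n_lin_nodes) + log(gl$w) +
      prior_logpdf(lin_prior, lin)
    tot <- ll_at(lin, tau, coef, omega) + logw
    tot[!is.finite(tot)] <- -Inf
    lnml <- log_sum_exp(tot)
    out <- list(ln_marg_lik = lnml)
    if (collect && lin_is_mu) {
      w <- exp(tot - lnml)
      out$mean_z <- sum(w * lin)
      out$mean_r <- sum(w * tanh(lin))
      ## density on a common grid, from the outer points carrying the mass
      Wg <- colSums(matrix(w, n_lin_nodes, G))
      ord <- order(Wg, decreasing = TRUE)
      keep <- ord[seq_len(which(cumsum(Wg[ord]) >= 0.999)[1])]
      grid <- seq(min(lo[keep]), max(hi[keep]), length.out = density_points)
      ng <- length(grid)
      mu_d <- rep(grid, times = length(keep))
      tau_d <- rep(op$tau[keep], each = ng)
      coef_d <- rep(op$coef[keep], each = ng)
      omega_d <- if (has_sel) op$omega[rep(keep, each = ng), , drop = FALSE]
                 else NULL
      ll_d <- ll_at(mu_d, tau_d, coef_d, omega_d) +
        rep(op$logw[keep], each = ng)
      hmat <- matrix(exp(ll_d - lnml), ng, length(keep))
      dens <- rowSums(hmat) * exp(prior_logpdf(lin_prior, grid))
      out$mu <- grid
      out$dens <- dens / trapz_area(grid, dens)
    }
    out
  }
  n_out <- if (outer_dims >= 2L) n_outer[2] else n_outer[1]
  full <- eval_at(n_mu, n_out, TRUE)
  half <- eval_at(max(8L, n_mu %/% 2L), max(6L, n_out %/% 2L), FALSE)
  eff <- if (lin_is_mu)
    list(point_mass = FALSE, mean_z = full$mean_z, mean_r = full$mean_r,
         mu = full$mu, dens = full$dens)
  else list(point_mass = TRUE, mean_z = mu0, mean_r = tanh(mu0))
  list(ln_marg_lik = full$ln_marg_lik,
       err = abs(full$ln_marg_lik - half$ln_marg_lik),
       effect = eff)
}

## crude location/scale of the pooled effect used to build the defensive
## importance proposal for mu: fixed-effect mean with a DerSimonian-Laird
## heterogeneity allowance, scale inflated threefold
pooled_guess <- function(z, se) {
  wts <- 1 / se^2
  mhat <- sum(wts * z) / sum(wts)
  K <- length(z)
  tau2 <- 0
  if (K > 1) {
    Q <- sum(wts * (z - mhat)^2)
    denom <- sum(wts) - sum(wts^2) / sum(wts)
    if (denom > 0) tau2 <- max(0, (Q - (K - 1)) / denom)
  }
  list(m = mhat, s = max(0.02, 3 * sqrt(1 / sum(wts) + tau2 / K)))
}

mc_eval <- function(spec, z, se, n_draws, want_effect, density_points) {
  G <- n_draws
  ln_q_adj <- 0
  if (!is_point_prior(spec$effect_prior)) {
    ## defensive importance mixture: half prior, half a normal around the
    ## pooled estimate, so sharp likelihoods keep a usable effective sample
    pg <- pooled_guess(z, se)
    from_prior <- stats::runif(G) < 0.5
    mu <- ifelse(from_prior, prior_rng(spec$effect_prior, G),
                 stats::rnorm(G, pg$m, pg$s))
    ln_pi <- prior_logpdf(spec$effect_prior, mu)
    ln_q <- log(0.5 * exp(ln_pi) + 0.5 * stats::dnorm(mu, pg$m, pg$s))
    ln_q_adj <- ln_pi - ln_q
    ln_q_adj[ln_pi == -Inf] <- -Inf
  } else mu <- rep(spec$effect_prior$params$location, G)
  if (!is_point_prior(spec$heterogeneity_prior))
    tau <- prior_rng(spec$heterogeneity_prior, G)
  else tau <- rep(spec$heterogeneity_prior$params$location, G)
  extra <- NULL
  if (spec$bias$kind == "selection") {
    if (all(spec$bias$omega_prior$params$alpha == 1)) {
      ## defensive tilt toward small weights, mirroring the quadrature
      ## substitution: half the draws use v = u^gamma
      Jm1 <- spec$bias$wf$J - 1L
      u <- matrix(stats::runif(G * Jm1), G, Jm1)
      tilted <- stats::runif(G) < 0.5
      V <- u
      V[tilted, ] <- u[tilted, , drop = FALSE]^OMEGA_TILT
      q_v <- 0.5 + 0.5 * apply(V, 1, function(v)
        prod(v^(1 / OMEGA_TILT - 1)) / OMEGA_TILT^Jm1)
      ln_q_adj <- ln_q_adj - log(q_v)
      extra <- v_to_omega_tail(V)
    } else {
      extra <- prior_rng(spec$bias$omega_prior, G)[, -1, drop = FALSE]
    }
  } else if (spec$bias$kind %in% c("pet", "peese")) {
    extra <- matrix(prior_rng(spec$bias$coef_prior, G), ncol = 1)
  }
  ll <- model_ll(spec, z, se, mu, tau, extra) + ln_q_adj
  ll[!is.finite(ll)] <- -Inf
  m <- max(ll)
  w <- exp(ll - m)
  lnml <- m + log(mean(w))
  se_ln <- stats::sd(w) / (mean(w) * sqrt(G))
  out <- list(ln_marg_lik = lnml, mc_se = se_ln)
  if (want_effect && !is_point_prior(spec$effect_prior)) {
    wn <- w / sum(w)
    ess <- 1 / sum(wn^2)
    mz <- sum(wn * mu)
    sdw <- sqrt(max(sum(wn * (mu - mz)^2), 1e-12))
    bw <- max(0.9 * sdw * ess^(-1 / 5), 1e-4)
    d <- suppressWarnings(
      stats::density(mu, weights = wn, bw = bw, n = density_points))
    out$effect <- list(point_mass = FALSE,
                       mean_z = mz,
                       mean_r = sum(wn * tanh(mu)),
                       mu = d$x, dens = d$y / trapz_area(d$x, d$y))
  }
  out
}

## run `code` under a temporary deterministic RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Fit a single ensemble member
#'
#' Computes the log marginal likelihood `ln integral L(data|theta) pi(theta)
#' dtheta` over the model's free parameters (0 to 5 dimensional) and the
#' conditional posterior of the mean effect mu. Models without free
#' parameters are evaluated in closed form; models with at most 3 free
#' dimensions use deterministic quadrature with a refinement-based error
#' estimate; higher-dimensional models (selection models with 3-4 weight
#' steps plus free mu/tau) use prior-draw Monte Carlo with a reported
#' standard error. Results whose error estimate exceeds `rel_tol` are
#' flagged, never silently accepted.
#'
#' @param spec A [model_spec()].
#' @param studies Study data frame (see [make_studies()]).
#' @param settings [integration_settings()].
#' @param want_effect Compute the tabulated conditional posterior of mu?
#' @return A `robmeta_fitted_model`: the spec plus `ln_marg_lik`,
#'   `ln_ml_error`, `method`, `flagged`, and an `effect` posterior summary
#'   (`point_mass`, `mean_z`, `mean_r`, and a `mu`/`dens` table for
#'   continuous-effect models).
#' @export
fit_model <- function(spec, studies, settings = integration_settings(),
                      want_effect = TRUE) {
  check_studies(studies)
  stopifnot(inherits(spec, "robmeta_model_spec"))
  z <- studies$z; se <- studies$se_z
  dims <- model_dims(spec)
  method <- settings$method
  if (method == "auto")
    method <- if (dims <= 3 && quadrable(spec)) "quadrature" else "mc"
  if (method == "quadrature" && !quadrable(spec))
    stop("quadrature requires the unit Dirichlet weight prior")

  if (dims == 0L) {
    mu0 <- spec$effect_prior$params$location
    tau0 <- spec$heterogeneity_prior$params$location
    lnml <- ll_re_vec(z, se, mu0, tau0)
    res <- list(ln_marg_lik = lnml, err = 0, method = "closed_form")
    eff <- list(point_mass = TRUE, mean_z = mu0, mean_r = tanh(mu0))
  } else if (method == "quadrature" &&
             (!is_point_prior(spec$effect_prior) ||
                spec$bias$kind %in% c("pet", "peese"))) {
    cm <- quad_eval_cmu(spec, z, se,
                        n_mu = min(settings$nodes[1], 32L),
                        n_outer = settings$nodes[2:3],
                        want_effect = want_effect,
                        density_points = settings$density_points)
    res <- list(ln_marg_lik = cm$ln_marg_lik, err = cm$err, method = "quadrature")
    eff <- cm$effect
  } else if (method == "quadrature") {
    n_nodes <- settings$nodes[min(dims, 3)]
    if (dims > 3) n_nodes <- max(6L, settings$nodes[3] %/% 2L)
    win <- quad_windows(spec, z, se, dims)
    full <- quad_eval(spec, z, se, n_nodes, dims, win, want_effect)
    half <- quad_eval(spec, z, se, max(4L, n_nodes %/% 2L), dims, win, FALSE)
    err <- abs(full$ln_marg_lik - half$ln_marg_lik)
    if (err > settings$rel_tol && dims <= 3) {   # one refinement pass
      finer <- quad_eval(spec, z, se, 2L * n_nodes, dims, win, want_effect)
      err <- abs(finer$ln_marg_lik - full$ln_marg_lik)
      full <- finer
    }
    res <- list(ln_marg_lik = full$ln_marg_lik, err = err, method = "quadrature")
    eff <- full$effect
  } else {
    mcres <- with_seed(settings$seed + (if (is.na(spec$id)) 0L else spec$id),
                       mc_eval(spec, z, se, settings$mc_draws, want_effect,
                               settings$density_points))
    res <- list(ln_marg_lik = mcres$ln_marg_lik, err = mcres$mc_se, method = "mc")
    eff <- mcres$effect
  }
  if (is.null(eff))
    eff <- list(point_mass = is_point_prior(spec$effect_prior),
                mean_z = if (is_point_prior(spec$effect_prior))
                  spec$effect_prior$params$location else NA_real_,
                mean_r = if (is_point_prior(spec$effect_prior))
                  tanh(spec$effect_prior$params$location) else NA_real_)
  structure(list(spec = spec,
                 ln_marg_lik = res$ln_marg_lik,
                 ln_ml_error = res$err,
                 method = res$method,
                 flagged = is.finite(res$err) &&
                   res$err > (if (res$method == "mc") 0.1
                              else 5 * settings$rel_tol),
                 effect = eff),
            class = "robmeta_fitted_model")
}

#' Log marginal likelihood of one model
#'
#' Thin wrapper around [fit_model()] returning only the log marginal
#' likelihood and its error estimate.
#'
#' @inheritParams fit_model
#' @export
ln_marginal_likelihood <- function(spec, studies, settings = integration_settings()) {
  f <- fit_model(spec, studies, settings, want_effect = FALSE)
  list(ln_marg_lik = f$ln_marg_lik, error = f$ln_ml_error, method = f$method)
}

#' Conditional posterior of the mean effect under one model
#'
#' @inheritParams fit_model
#' @return For point-effect models, a point mass at the prior location;
#'   otherwise a normalized tabulated density of mu on the z scale with its
#'   posterior mean.
#' @export
conditional_effect_posterior <- function(spec, studies,
                                         settings = integration_settings()) {
  fit_model(spec, studies, settings, want_effect = TRUE)$effect
}
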