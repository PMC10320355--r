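#' Orient a meta-analysis toward a positive pooled effect
#'
#' The PET/PEESE priors and the one-sided selection models assume
#' publication selection favours the positive direction, so each
#' meta-analysis is flipped to a positive random-effects estimate before
#' fitting; the flag allows reports to restore the original sign.
#'
#' @param studies Study data frame.
#' @return `list(studies, flipped)`.
#' @export
orient_meta <- function(studies) {
  check_studies(studies)
  est <- fit_re_ma(studies)$estimate_z
  flipped <- est < 0
  if (flipped) {
    studies$z <- -studies$z
    if (!is.null(studies$r)) studies$r <- -studies$r
  }
  list(studies = studies, flipped = flipped)
}

#' Random-effects meta-analysis (REML)
#'
#' Standard normal-normal random-effects fit on the Fisher z scale via
#' [metafor::rma()] with REML heterogeneity estimation. A single study (or
#' an REML failure) falls back to an equal-effects fit with `tau = 0` and a
#' warning.
#'
#' @param studies Study data frame.
#' @param method `tau^2` estimator passed to metafor (default `"REML"`).
#' @return `list(estimate_z, tau_z, se)`.
#' @export
fit_re_ma <- function(studies, method = "REML") {
  check_studies(studies)
  if (nrow(studies) == 1) {
    warning("single study: equal-effects fallback with tau = 0")
    return(list(estimate_z = studies$z[1], tau_z = 0, se = studies$se_z[1]))
  }
  fit <- tryCatch(
    metafor::rma(yi = studies$z, sei = studies$se_z, method = method,
                 control = list(threshold = 1e-10, maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("REML fit failed; falling back to DerSimonian-Laird")
    fit <- metafor::rma(yi = studies$z, sei = studies$se_z, method = "DL")
  }
  list(estimate_z = as.numeric(fit$beta), tau_z = sqrt(fit$tau2),
       se = fit$se)
}

#' Analysis configuration
#'
#' Bundles the modelling choices for [analyze_one()] and
#' [analyze_corpus()]: the continuous effect prior (standard normal on d or
#' the Oosterwijk prior), the d-to-z prior rescaling mode, the weight
#' function set, integration settings, and the corpus summary thresholds.
#'
#' @param effect_prior `"normal"` or `"oosterwijk"`.
#' @param prior_rescale `"exact"` or `"linear"`.
#' @param weight_functions List of [weight_function()]s.
#' @param integration [integration_settings()].
#' @param p_change_threshold Probability change below which a meta-analysis
#'   counts as robust (default 0.05).
#' @param r_adj_threshold Absolute r-scale adjustment below which an
#'   estimate counts as essentially unadjusted (default 0.03).
#' @param rema_method `tau^2` estimator for the random-effects comparator.
#' @export
robmeta_config <- function(effect_prior = c("normal", "oosterwijk"),
                           prior_rescale = c("exact", "linear"),
                           weight_functions = default_weight_functions(),
                           integration = integration_settings(),
                           p_change_threshold = 0.05,
                           r_adj_threshold = 0.03,
                           rema_method = "REML") {
  structure(list(effect_prior = match.arg(effect_prior),
                 prior_rescale = match.arg(prior_rescale),
                 weight_functions = weight_functions,
                 integration = integration,
                 p_change_threshold = p_change_threshold,
                 r_adj_threshold = r_adj_threshold,
                 rema_method = rema_method),
            class = "robmeta_config")
}

#' Load an analysis configuration from YAML
#'
#' Recognized fields: `effect_prior`, `prior_rescale`, `integration`
#' (`method`, `mc_draws`, `nodes`, `rel_tol`, `seed`, `preset`),
#' `thresholds` (`p_change`, `r_adj`), `rema_method`.
#'
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  ints <- y$integration %||% list()
  int_args <- Filter(Negate(is.null),
                     list(method = ints$method, mc_draws = ints$mc_draws,
                          nodes = ints$nodes, rel_tol = ints$rel_tol,
                          seed = ints$seed, preset = ints$preset))
  robmeta_config(
    effect_prior = y$effect_prior %||% "normal",
    prior_rescale = y$prior_rescale %||% "exact",
    integration = do.call(integration_settings, int_args),
    p_change_threshold = y$thresholds$p_change %||% 0.05,
    r_adj_threshold = y$thresholds$r_adj %||% 0.03,
    rema_method = y$rema_method %||% "REML")
}

#' Analyse one meta-analysis with reMA, BMA and the full ensemble
#'
#' Orients the meta-analysis toward a positive pooled effect, fits the
#' random-effects comparator, the bias-unadjusted model average (BMA) and
#' the full publication-bias ensemble, and assembles the per-meta-analysis
#' comparison record. Estimates are reported with the original sign
#' restored; adjustment columns (`adj_vs_rema_r`, `adj_vs_bma_r`,
#' `adj_vs_bma_z`) are on the oriented (positive-effect) scale, so negative
#' values always mean a correction toward or past zero.
#'
#' @param studies Study data frame for one meta-analysis.
#' @param config [robmeta_config()].
#' @param meta_id,article_id Identifiers copied into the record.
#' @return A one-row data frame (`MetaRecord`).
#' @export
analyze_one <- function(studies, config = robmeta_config(),
                        meta_id = NA_integer_, article_id = NA_integer_) {
  or <- orient_meta(studies)
  st <- or$studies
  sgn <- if (or$flipped) -1 else 1

  rema <- fit_re_ma(st, config$rema_method)
  full <- build_ensemble(effect_prior_alt = config$effect_prior,
                         prior_rescale = config$prior_rescale,
                         weight_functions = config$weight_functions)
  bma_specs <- restrict_to_bma(full)
  fit_full <- fit_ensemble(full, st, config$integration)
  fit_bma <- fit_ensemble(bma_specs, st, config$integration)

  adj_vs_rema_r <- fit_full$averaged_effect_mean_r - tanh(rema$estimate_z)
  adj_vs_bma_r <- fit_full$averaged_effect_mean_r - fit_bma$averaged_effect_mean_r
  adj_vs_bma_z <- fit_full$averaged_effect_mean_z - fit_bma$averaged_effect_mean_z
  data.frame(
    meta_id = meta_id, article_id = article_id,
    k = nrow(st),
    orientation_flipped = or$flipped,
    rema_est_z = sgn * rema$estimate_z,
    rema_est_r = sgn * tanh(rema$estimate_z),
    rema_tau_z = rema$tau_z,
    bma_est_z = sgn * fit_bma$averaged_effect_mean_z,
    bma_est_r = sgn * fit_bma$averaged_effect_mean_r,
    bma_p_effect = fit_bma$p_effect,
    bma_bf10 = fit_bma$bf_effect,
    robma_est_z = sgn * fit_full$averaged_effect_mean_z,
    robma_est_r = sgn * fit_full$averaged_effect_mean_r,
    robma_p_effect = fit_full$p_effect,
    robma_bf10 = fit_full$bf_effect,
    robma_p_bias = fit_full$p_bias,
    adj_vs_rema_r = adj_vs_rema_r,
    adj_vs_bma_r = adj_vs_bma_r,
    adj_vs_bma_z = adj_vs_bma_z,
    delta_p_effect = fit_full$p_effect - fit_bma$p_effect,
    evidence_category_before = categorize_evidence(fit_bma$bf_effect),
    evidence_category_after = categorize_evidence(fit_full$bf_effect),
    ## adjusted past zero into the opposite direction (the anomaly a
    ## near-null estimate can show after aggressive correction)
    sign_reversal = fit_full$averaged_effect_mean_r < 0,
    flagged = length(fit_full$warnings) > 0 || length(fit_bma$warnings) > 0,
    stringsAsFactors = FALSE)
}

#' Analyse every meta-analysis in a corpus
#'
#' @param corpus Study-level corpus data frame (see [read_corpus()]).
#' @param config [robmeta_config()].
#' @param progress Print one line per meta-analysis?
#' @return A data frame of `MetaRecord` rows; meta-analyses whose ensemble
#'   fit failed are kept with `failed = TRUE` and excluded by the summary
#'   functions.
#' @export
analyze_corpus <- function(corpus, config = robmeta_config(), progress = FALSE) {
  stopifnot(all(c("meta_id", "article_id", "z", "se_z") %in% names(corpus)))
  ids <- unique(corpus$meta_id)
  recs <- lapply(ids, function(id) {
    st <- corpus[corpus$meta_id == id, , drop = FALSE]
    t0 <- proc.time()[3]
    rec <- tryCatch(
      analyze_one(st, config, meta_id = id, article_id = st$article_id[1]),
      error = function(e) {
        warning("meta ", id, " failed: ", conditionMessage(e))
        data.frame(meta_id = id, article_id = st$article_id[1],
                   k = nrow(st), failed_reason = conditionMessage(e))
      })
    rec$failed <- is.null(rec$robma_est_r)
    if (progress)
      message(sprintf("meta %s: k=%d, %.1fs", id, nrow(st),
                      proc.time()[3] - t0))
    rec
  })
  out <- do.call(rbind, lapply(recs, pad_record,
                               cols = record_columns()))
  rownames(out) <- NULL
  out
}

record_columns <- function() {
  c("meta_id", "article_id", "k", "orientation_flipped",
    "rema_est_z", "rema_est_r", "rema_tau_z",
    "bma_est_z", "bma_est_r", "bma_p_effect", "bma_bf10",
    "robma_est_z", "robma_est_r", "robma_p_effect", "robma_bf10",
    "robma_p_bias", "adj_vs_rema_r", "adj_vs_bma_r", "adj_vs_bma_z",
    "delta_p_effect", "evidence_category_before", "evidence_category_after",
    "sign_reversal", "flagged", "failed", "failed_reason")
}

pad_record <- function(rec, cols) {
  for (cl in setdiff(cols, names(rec))) rec[[cl]] <- NA
  rec[, cols]
}

iqr_string <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sprintf("(%.2f, %.2f)", q[1], q[2])
}

#' Corpus-level summary of evidence inflation and effect overestimation
#'
#' Medians and interquartile ranges of the posterior probability of the
#' effect before (BMA) and after (full ensemble) bias adjustment, evidence
#' category percentages before and after, the proportion of meta-analyses
#' whose probability changed by at most `p_change_threshold`, medians/IQRs
#' of the three estimates and of the adjustments, and the proportion of
#' estimates adjusted (versus BMA) by less than `r_adj_threshold` on the
#' correlation scale.
#'
#' @param records Data frame from [analyze_corpus()].
#' @param p_change_threshold,r_adj_threshold See [robmeta_config()].
#' @return A `robmeta_corpus_summary` list.
#' @export
summarize_corpus <- function(records, p_change_threshold = 0.05,
                             r_adj_threshold = 0.03) {
  n_failed <- sum(isTRUE_vec(records$failed))
  records <- records[!isTRUE_vec(records$failed), , drop = FALSE]
  if (nrow(records) < 1) stop("no unflagged records to summarize")
  lev <- c("strong_null", "moderate_null", "undecided",
           "moderate_alt", "strong_alt")
  pct <- function(x) {
    tab <- table(factor(x, levels = lev))
    stats::setNames(100 * as.numeric(tab) / length(x), lev)
  }
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    n_meta = nrow(records),
    n_failed = n_failed,
    p_effect_before = qs(records$bma_p_effect),
    p_effect_after = qs(records$robma_p_effect),
    categories_before_pct = pct(records$evidence_category_before),
    categories_after_pct = pct(records$evidence_category_after),
    prop_p_unchanged = mean(abs(records$delta_p_effect) <= p_change_threshold),
    est_rema = qs(records$rema_est_r),
    est_bma = qs(records$bma_est_r),
    est_robma = qs(records$robma_est_r),
    adj_vs_rema = qs(records$adj_vs_rema_r),
    adj_vs_bma = qs(records$adj_vs_bma_r),
    prop_small_adj_vs_bma = mean(abs(records$adj_vs_bma_r) < r_adj_threshold),
    n_sign_reversals = sum(records$sign_reversal),
    p_change_threshold = p_change_threshold,
    r_adj_threshold = r_adj_threshold),
    class = "robmeta_corpus_summary")
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' @export
print.robmeta_corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus summary (%d meta-analyses)\n", x$n_meta))
  cat(sprintf("  median P(effect): %.2f -> %.2f after bias adjustment\n",
              x$p_effect_before[2], x$p_effect_after[2]))
  cat(sprintf("  |delta P| <= %.2f for %.1f%% of meta-analyses\n",
              x$p_change_threshold, 100 * x$prop_p_unchanged))
  cat(sprintf("  median r: reMA %.2f, BMA %.2f, adjusted %.2f\n",
              x$est_rema[2], x$est_bma[2], x$est_robma[2]))
  cat(sprintf("  median adjustment vs reMA %.3f, vs BMA %.3f; |adj| < %.2f for %.1f%%\n",
              x$adj_vs_rema[2], x$adj_vs_bma[2], x$r_adj_threshold,
              100 * x$prop_small_adj_vs_bma))
  invisible(x)
}

#' Bayesian regression of the bias adjustment on heterogeneity
#'
#' Predicts the z-scale adjustment attributable to publication bias
#' (`adj_vs_bma_z`) from the REML heterogeneity estimate, with the
#' unadjusted (BMA) effect size as a covariate. Coefficients carry a
#' unit-information conjugate normal prior (`beta | sigma^2 ~ N(0, n sigma^2
#' (X'X)^-1)`, Jeffreys prior on the common `sigma^2`), so marginal
#' likelihoods — and hence per-coefficient inclusion Bayes factors by
#' comparison against the model dropping that column — are available in
#' closed form. The effect-size covariate is centred; heterogeneity is left
#' raw so the intercept is the expected adjustment of a homogeneous
#' (`tau = 0`) meta-analysis with an average unadjusted effect.
#' Standardized slopes are reported alongside raw ones.
#'
#' @param records Data frame from [analyze_corpus()].
#' @return A `robmeta_het_regression` with a per-coefficient table
#'   (estimate, 95% credible interval, inclusion BF10).
#' @export
heterogeneity_regression <- function(records) {
  records <- records[!isTRUE_vec(records$failed), , drop = FALSE]
  n <- nrow(records)
  if (n < 3) stop("need at least 3 records")
  if (n < 10) warning("fewer than 10 records; regression will be fragile")
  y <- records$adj_vs_bma_z
  tau <- records$rema_tau_z
  est <- records$bma_est_z - mean(records$bma_est_z)
  X <- cbind(intercept = 1, tau = tau, unadjusted_est = est)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear predictors")
  full <- gprior_lm(y, X)
  bf <- vapply(seq_len(ncol(X)), function(j)
    exp(full$ln_marg - gprior_lm(y, X[, -j, drop = FALSE])$ln_marg), 0)
  tab <- data.frame(term = colnames(X),
                    estimate = full$mean,
                    ci_lo = full$ci[, 1], ci_hi = full$ci[, 2],
                    bf10 = bf)
  sds <- c(1, stats::sd(tau), stats::sd(est))
  tab$estimate_std <- tab$estimate * sds / stats::sd(y)
  structure(list(table = tab, n = n, sigma = sqrt(full$s2)),
            class = "robmeta_het_regression")
}

## conjugate linear model: beta | s2 ~ N(0, n s2 (X'X)^-1), p(s2) ~ 1/s2
gprior_lm <- function(y, X) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, y))
  shrink <- n / (n + 1)
  bn <- shrink * bhat
  Sn <- drop(crossprod(y) - shrink * t(bhat) %*% XtX %*% bhat)
  ln_marg <- -(p / 2) * log(n + 1) - (n / 2) * log(Sn)  # + const(n), cancels in BFs
  Vn <- shrink * solve(XtX)
  s2 <- Sn / n
  se <- sqrt(s2 * diag(Vn))
  tq <- stats::qt(0.975, n)
  list(mean = drop(bn), ci = cbind(drop(bn) - tq * se, drop(bn) + tq * se),
       ln_marg = ln_marg, s2 = s2)
}

#' @export
print.robmeta_het_regression <- function(x, ...) {
  cat(sprintf("Heterogeneity regression (n = %d)\n", x$n))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Three-level hierarchical model of the bias adjustment
#'
#' The r-scale adjustments (one per meta-analysis per comparator method,
#' `vs_rema` and `vs_bma`) are modelled as a per-method fixed effect plus
#' random intercepts for articles and for meta-analyses nested within them:
#' meta-analyses from one article, and adjustments of one meta-analysis
#' under different comparators, are correlated. Weakly informative priors:
#' `Normal(0, 1)` on the fixed effects, `half-t(3, 0, 0.5)` on the three
#' standard deviations. Fitted by Gibbs/MCMC through JAGS with fixed seeds;
#' chains must satisfy R-hat < 1.01 on the reported fixed effects (and
#' < 1.05 on the intercept scales) or an error is raised.
#'
#' @param records Data frame from [analyze_corpus()].
#' @param n_iter,n_burn,n_chains MCMC controls.
#' @param seed Base seed for the chains.
#' @return A `robmeta_three_level` with `beta` (per-method posterior mean
#'   and 95% credible interval), `sd_article`, `sd_meta`, `sd_resid`, and
#'   convergence diagnostics.
#' @export
three_level_adjustment_model <- function(records, n_iter = 4000,
                                         n_burn = 2000, n_chains = 3,
                                         seed = 1) {
  records <- records[!isTRUE_vec(records$failed), , drop = FALSE]
  if (length(unique(records$article_id)) < 2)
    stop("need at least 2 articles")
  long <- rbind(
    data.frame(y = records$adj_vs_rema_r, method = "vs_rema",
               meta = records$meta_id, article = records$article_id),
    data.frame(y = records$adj_vs_bma_r, method = "vs_bma",
               meta = records$meta_id, article = records$article_id))
  methods <- sort(unique(long$method))
  dat <- list(y = long$y,
              method = match(long$method, methods),
              meta = match(long$meta, unique(long$meta)),
              article = match(long$article, unique(long$article)),
              N = nrow(long), M = length(methods),
              n_meta = length(unique(long$meta)),
              n_article = length(unique(long$article)))
  ## Gibbs-friendly parameterization: multiplicative parameter expansion
  ## for the intercept scales (sd = |xi|/sqrt(prec_eta) has exactly the
  ## half-t(3, 0, 0.5) prior) and post-sweeping of the intercept means into
  ## the fixed effects, whose raw coordinates otherwise random-walk along
  ## the unidentified overall-level direction
  model_str <- "
  model {
    for (i in 1:N) {
      y[i] ~ dnorm(beta[method[i]] + xi_a * eta_a[article[i]] +
                   xi_b * eta_b[meta[i]], prec_e)
    }
    for (j in 1:M) { beta[j] ~ dnorm(0, 1) }
    for (j in 1:n_article) { eta_a[j] ~ dnorm(0, prec_eta_a) }
    for (j in 1:n_meta) { eta_b[j] ~ dnorm(0, prec_eta_b) }
    xi_a ~ dnorm(0, pow(0.5, -2)); prec_eta_a ~ dgamma(1.5, 1.5)
    xi_b ~ dnorm(0, pow(0.5, -2)); prec_eta_b ~ dgamma(1.5, 1.5)
    sd_a <- abs(xi_a) / sqrt(prec_eta_a)
    sd_b <- abs(xi_b) / sqrt(prec_eta_b)
    sd_e ~ dt(0, pow(0.5, -2), 3) T(0,)
    prec_e <- pow(sd_e, -2)
    for (j in 1:M) {
      beta_sw[j] <- beta[j] + xi_a * mean(eta_a[]) + xi_b * mean(eta_b[])
    }
  }"
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed + ch))
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = n_chains, quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta_sw", "sd_a", "sd_b", "sd_e"),
                              n.iter = n_iter, progress.bar = "none")
  gd <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
  rhat <- gd$psrf[, 1]
  ## strict convergence on the reported fixed effects; the intercept scales
  ## are nuisance parameters whose Gibbs mixing is slower when they collapse
  ## toward zero, so they get a looser (still tight) bound
  beta_rhat <- rhat[grep("^beta", names(rhat))]
  sd_rhat <- rhat[grep("^sd", names(rhat))]
  if (any(beta_rhat > 1.01, na.rm = TRUE) || any(sd_rhat > 1.05, na.rm = TRUE))
    stop("three-level model did not converge: max R-hat = ",
         signif(max(rhat, na.rm = TRUE), 4))
  sm <- summary(samp)
  q <- sm$quantiles
  beta_rows <- grep("^beta", rownames(q))
  beta <- data.frame(method = methods,
                     mean = sm$statistics[beta_rows, "Mean"],
                     ci_lo = q[beta_rows, "2.5%"],
                     ci_hi = q[beta_rows, "97.5%"])
  rownames(beta) <- NULL
  structure(list(beta = beta,
                 sd_article = sm$statistics["sd_a", "Mean"],
                 sd_meta = sm$statistics["sd_b", "Mean"],
                 sd_resid = sm$statistics["sd_e", "Mean"],
                 rhat = rhat, n_iter = n_iter, n_chains = n_chains),
            class = "robmeta_three_level")
}

#' @export
print.robmeta_three_level <- function(x, ...) {
  cat("Three-level adjustment model\n")
  print(x$beta, row.names = FALSE, digits = 3)
  cat(sprintf("  sd_article %.3f, sd_meta %.3f, sd_resid %.3f (max R-hat %.3f)\n",
              x$sd_article, x$sd_meta, x$sd_resid, max(x$rhat)))
  invisible(x)
}
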