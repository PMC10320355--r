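#' Significance-based publication selection rule
#'
#' Mirrors the step weight-function form of the selection models: the
#' p-value axis is partitioned by `cutpoints`, and a study falling in
#' interval `j` is published with probability `publish_probs[j]`
#' (most-significant interval first).
#'
#' @param cutpoints p-value cut-offs in (0, 1), strictly increasing.
#' @param publish_probs Per-interval publication probabilities in (0, 1],
#'   length `length(cutpoints) + 1`.
#' @param sidedness Which p-value the cut-offs apply to.
#' @export
selection_spec <- function(cutpoints = 0.05, publish_probs = c(1, 0.3),
                           sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  wf <- weight_function(cutpoints, sidedness)
  publish_probs <- as.numeric(publish_probs)
  if (length(publish_probs) != wf$J)
    stop("need length(cutpoints) + 1 publication probabilities")
  if (any(publish_probs <= 0 | publish_probs > 1))
    stop("publish_probs must be in (0, 1]")
  structure(list(wf = wf, publish_probs = publish_probs),
            class = "robmeta_selection")
}

#' @rdname selection_spec
#' @export
selection_none <- function() {
  structure(list(wf = weight_function(0.05, "two_sided"),
                 publish_probs = c(1, 1)),
            class = "robmeta_selection")
}

#' @rdname selection_spec
#' @export
selection_strong <- function() selection_spec(0.05, c(1, 0.05), "two_sided")

dist_spec <- function(kind, ...) list(kind = kind, ...)

draw_dist <- function(spec, n) {
  switch(spec$kind,
    point = rep(spec$value, n),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    invgamma = 1 / stats::rgamma(n, spec$shape, rate = spec$scale),
    uniform_int = {
      v <- spec$min:spec$max
      if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
    },
    lognormal_int = pmax(spec$min,
                         round(stats::rlnorm(n, spec$meanlog, spec$sdlog))),
    stop("unknown distribution kind '", spec$kind, "'"))
}

#' Configuration of a synthetic meta-analysis corpus
#'
#' Describes a corpus of articles, each containing several meta-analyses,
#' each containing `K` primary studies generated from a random-effects model
#' on the Fisher z scale and filtered by significance-based publication
#' selection. The `"corpus"` preset matches the scale of a typical large
#' meta-science corpus (90 articles with 4-5 meta-analyses each, roughly
#' 400 meta-analyses); `"small"` (10 articles, 2 meta-analyses each,
#' K <= 20) keeps test runs fast.
#'
#' True effects are drawn from `mu_z_dist` (default `Normal(0.15, 0.15)` on
#' the z scale, covering null-ish to medium effects), heterogeneity from
#' `tau_z_dist` (default `Inverse-Gamma(1, 0.075)`, the empirical
#' heterogeneity prior on the z scale), and per-study sample sizes from
#' `n_dist` (default log-normal around 60, a typical psychology cell size).
#'
#' @param n_articles Number of articles.
#' @param metas_per_article Integer range `c(lo, hi)`.
#' @param K Studies-per-meta-analysis range `c(lo, hi)` (published count).
#' @param mu_z_dist,tau_z_dist,n_dist Distribution specs
#'   (`list(kind = ..., ...)`).
#' @param selection A [selection_spec()].
#' @param seed Mandatory integer seed.
#' @param preset `"corpus"` or `"small"`.
#' @export
simulation_config <- function(n_articles = NULL, metas_per_article = NULL,
                              K = NULL,
                              mu_z_dist = dist_spec("normal", mean = 0.15, sd = 0.15),
                              tau_z_dist = dist_spec("invgamma", shape = 1, scale = 0.075),
                              n_dist = dist_spec("lognormal_int", meanlog = log(60),
                                                 sdlog = 0.5, min = 8),
                              selection = selection_none(),
                              seed,
                              preset = c("corpus", "small")) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("seed is mandatory")
  defaults <- switch(preset,
    corpus = list(n_articles = 90, metas = c(4, 5), K = c(5, 50)),
    small = list(n_articles = 10, metas = c(2, 2), K = c(5, 20)))
  n_articles <- n_articles %||% defaults$n_articles
  metas_per_article <- metas_per_article %||% defaults$metas
  K <- K %||% defaults$K
  stopifnot(n_articles >= 1, length(metas_per_article) == 2,
            metas_per_article[1] <= metas_per_article[2],
            length(K) == 2, K[1] >= 1, K[1] <= K[2],
            inherits(selection, "robmeta_selection"),
            seed == round(seed))
  structure(list(n_articles = as.integer(n_articles),
                 metas_per_article = as.integer(metas_per_article),
                 K = as.integer(K),
                 mu_z_dist = mu_z_dist, tau_z_dist = tau_z_dist,
                 n_dist = n_dist, selection = selection,
                 seed = as.integer(seed)),
            class = "robmeta_sim_config")
}

#' Simulate one meta-analysis under publication selection
#'
#' Draws primary studies from the random-effects model `theta_i ~
#' Normal(mu, tau)`, `z_i ~ Normal(theta_i, 1/sqrt(n_i - 3))`, computes each
#' study's p-value under the selection rule's sidedness, and publishes it
#' with the probability of its p-value interval, until `K_target` studies
#' are published (the published count is fixed by design, matching how real
#' meta-analyses are observed). Uses the current RNG state.
#'
#' @param true_mu_z,true_tau_z True mean effect and heterogeneity (z scale).
#' @param K_target Number of published studies required.
#' @param n_dist Sample size distribution spec.
#' @param selection A [selection_spec()].
#' @param max_attempts Safety cap on generated studies (default
#'   `100 * K_target`).
#' @return `list(studies = <data frame>, truth = <list>)`, the truth record
#'   carrying `true_mu_z`, `true_tau_z`, `n_generated`, `n_published`.
#' @export
simulate_meta_analysis <- function(true_mu_z, true_tau_z, K_target, n_dist,
                                   selection = selection_none(),
                                   max_attempts = 100 * K_target) {
  stopifnot(true_tau_z >= 0, K_target >= 1)
  wf <- selection$wf
  z_pub <- numeric(0); n_pub <- integer(0)
  generated <- 0L
  while (length(z_pub) < K_target) {
    if (generated >= max_attempts) {
      rates <- selection$publish_probs
      stop(sprintf(paste0("publication selection accepted only %d/%d studies in %d ",
                          "attempts; smallest interval probability is %.3g"),
                   length(z_pub), K_target, generated, min(rates)))
    }
    m <- min(max(2L * K_target, 16L), max_attempts - generated)
    n_i <- draw_dist(n_dist, m)
    theta <- stats::rnorm(m, true_mu_z, true_tau_z)
    se_i <- 1 / sqrt(n_i - 3)
    z_i <- stats::rnorm(m, theta, se_i)
    idx <- p_interval_index(p_value(z_i, se_i, wf$sidedness), wf)
    keep <- stats::runif(m) < selection$publish_probs[idx]
    need <- K_target - length(z_pub)
    ord <- which(keep)
    if (length(ord) > need) {
      last <- ord[need]
      generated <- generated + last
      ord <- ord[seq_len(need)]
    } else generated <- generated + m
    z_pub <- c(z_pub, z_i[ord])
    n_pub <- c(n_pub, n_i[ord])
  }
  studies <- make_studies(z = z_pub, n = as.integer(n_pub))
  truth <- list(true_mu_z = true_mu_z, true_tau_z = true_tau_z,
                n_generated = generated, n_published = length(z_pub))
  list(studies = studies, truth = truth)
}

#' Simulate a full corpus of meta-analyses
#'
#' Deterministic given `config$seed`: articles contain a uniform number of
#' meta-analyses in `metas_per_article`, each with its own true effect,
#' heterogeneity and published study count.
#'
#' @param config A [simulation_config()].
#' @return `list(corpus = <study-level data frame>, truth = <per-meta truth
#'   table>)` in the corpus CSV schema (see [read_corpus()]).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "robmeta_sim_config"))
  with_seed(config$seed, {
    corpus <- list(); truth <- list()
    meta_id <- 0L
    sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    for (art in seq_len(config$n_articles)) {
      n_meta <- sample_range(config$metas_per_article)
      for (j in seq_len(n_meta)) {
        meta_id <- meta_id + 1L
        mu <- draw_dist(config$mu_z_dist, 1)
        tau <- abs(draw_dist(config$tau_z_dist, 1))
        K <- sample_range(config$K)
        sim <- tryCatch(
          simulate_meta_analysis(mu, tau, K, config$n_dist, config$selection),
          error = function(e)
            stop("meta ", meta_id, ": ", conditionMessage(e), call. = FALSE))
        st <- sim$studies
        st$article_id <- art
        st$meta_id <- meta_id
        corpus[[meta_id]] <- st[, corpus_cols]
        truth[[meta_id]] <- data.frame(meta_id = meta_id, article_id = art,
                                       true_mu_z = mu, true_tau_z = tau,
                                       K = K,
                                       n_generated = sim$truth$n_generated,
                                       n_published = sim$truth$n_published)
      }
    }
    list(corpus = do.call(rbind, corpus), truth = do.call(rbind, truth))
  })
}
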