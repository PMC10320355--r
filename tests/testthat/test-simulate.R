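test_that("without selection every generated study is published", {
  set.seed(31)
  sim <- simulate_meta_analysis(0.2, 0.05, 25,
                                list(kind = "uniform_int", min = 20, max = 200),
                                selection_none())
  expect_equal(nrow(sim$studies), 25)
  expect_equal(sim$truth$n_published, sim$truth$n_generated)
  expect_equal(sim$studies$se_z, 1 / sqrt(sim$studies$n - 3))
})

test_that("huge samples and zero heterogeneity pin estimates to the truth", {
  set.seed(32)
  sim <- simulate_meta_analysis(0.3, 0, 30,
                                list(kind = "point", value = 1e6),
                                selection_none())
  expect_true(all(abs(sim$studies$z - 0.3) < 0.01))
})

test_that("strong null-effect selection leaves mostly significant studies", {
  # two-sided cut at .05, publish probabilities (1, 0.05), true effect 0:
  # significant fraction among published = .05 / (.05 + .05 * .95) = 0.513
  set.seed(33)
  sim <- simulate_meta_analysis(0, 0, 4000,
                                list(kind = "uniform_int", min = 30, max = 100),
                                selection_strong())
  sig <- p_value(sim$studies$z, sim$studies$se_z, "two_sided") <= 0.05
  expect_equal(mean(sig), 0.05 / (0.05 + 0.05 * 0.95), tolerance = 0.08)
  expect_gt(sim$truth$n_generated, sim$truth$n_published)
})

test_that("an impossible selection configuration aborts with context", {
  set.seed(34)
  expect_error(
    simulate_meta_analysis(0, 0, 50,
                           list(kind = "uniform_int", min = 10, max = 20),
                           selection_spec(0.001, c(1, 0.0001), "two_sided"),
                           max_attempts = 2000),
    "attempts")
})

test_that("corpus simulation is deterministic and matches the schema", {
  cfg <- simulation_config(preset = "small", seed = 17)
  a <- simulate_corpus(cfg)
  b <- simulate_corpus(cfg)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_corpus(a$corpus, f1); write_corpus(b$corpus, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(names(a$corpus),
                   c("article_id", "meta_id", "study_id", "r", "n", "z", "se_z"))
  expect_equal(nrow(a$truth), length(unique(a$corpus$meta_id)))
  expect_true(all(a$truth$n_published <= a$truth$n_generated))
})

test_that("the corpus preset reproduces the reference corpus shape", {
  cfg <- simulation_config(seed = 41)   # corpus preset: 90 articles, 4-5 metas
  sim <- simulate_corpus(cfg)
  expect_equal(length(unique(sim$corpus$article_id)), 90)
  n_meta <- nrow(sim$truth)
  expect_gte(n_meta, 360); expect_lte(n_meta, 450)
  expect_true(all(table(sim$corpus$meta_id) >= 5))
})

test_that("published effects are unbiased without selection, inflated with it", {
  base <- list(n_articles = 30, metas_per_article = c(2, 2), K = c(20, 20),
               mu_z_dist = list(kind = "point", value = 0.1),
               tau_z_dist = list(kind = "point", value = 0.05),
               preset = "small")
  none <- simulate_corpus(do.call(simulation_config,
                                  c(base, list(selection = selection_none(),
                                               seed = 51))))
  onesided <- simulate_corpus(do.call(simulation_config,
    c(base, list(selection = selection_spec(0.05, c(1, 0.1), "one_sided"),
                 seed = 51))))
  zbar_none <- mean(none$corpus$z)
  se_grand <- sd(none$corpus$z) / sqrt(nrow(none$corpus))
  expect_lt(abs(zbar_none - 0.1), 2 * se_grand)
  expect_gt(mean(onesided$corpus$z), 0.1)
})
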