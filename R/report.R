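#' Render corpus-level report files
#'
#' Writes the per-meta-analysis record table, the corpus summary as both a
#' key-value CSV and a markdown document, and three figures: the posterior
#' probability of the effect before versus after bias adjustment with
#' marginal densities, the estimate scatters against both unadjusted
#' comparators, and the densities of estimates and adjustments. Text
#' outputs use fixed numeric formatting so identical inputs yield identical
#' bytes.
#'
#' @param records Data frame from [analyze_corpus()].
#' @param summary A [summarize_corpus()] result (computed if `NULL`).
#' @param dir Output directory (created if needed).
#' @param figures Also render PDF figures?
#' @return Invisibly, the paths written.
#' @export
report <- function(records, summary = NULL, dir = "robmeta_report",
                   figures = TRUE) {
  if (is.null(summary)) summary <- summarize_corpus(records)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             summary_csv = file.path(dir, "summary.csv"),
             summary_md = file.path(dir, "summary.md"))

  fr <- records
  for (cl in names(fr))
    if (is.numeric(fr[[cl]]) && !is.integer(fr[[cl]]))
      fr[[cl]] <- sprintf("%.10g", fr[[cl]])
  utils::write.csv(fr, paths["records"], row.names = FALSE, quote = TRUE)

  kv <- summary_keyvalues(summary)
  utils::write.csv(data.frame(key = names(kv),
                              value = sprintf("%.10g", kv)),
                   paths["summary_csv"], row.names = FALSE, quote = FALSE)
  writeLines(summary_markdown(summary), paths["summary_md"])

  if (figures) {
    ok <- records[!isTRUE_vec(records$failed), , drop = FALSE]
    paths <- c(paths,
               fig1 = file.path(dir, "fig1_probability.pdf"),
               fig2 = file.path(dir, "fig2_estimates.pdf"),
               fig3 = file.path(dir, "fig3_densities.pdf"))
    grDevices::pdf(paths["fig1"], width = 6, height = 6)
    plot_probability_change(ok); grDevices::dev.off()
    grDevices::pdf(paths["fig2"], width = 9, height = 4.8)
    plot_estimate_scatters(ok); grDevices::dev.off()
    grDevices::pdf(paths["fig3"], width = 9, height = 4.8)
    plot_adjustment_densities(ok); grDevices::dev.off()
  }
  invisible(paths)
}

summary_keyvalues <- function(s) {
  c(n_meta = s$n_meta, n_failed = s$n_failed,
    p_effect_before_q25 = s$p_effect_before[1],
    p_effect_before_median = s$p_effect_before[2],
    p_effect_before_q75 = s$p_effect_before[3],
    p_effect_after_q25 = s$p_effect_after[1],
    p_effect_after_median = s$p_effect_after[2],
    p_effect_after_q75 = s$p_effect_after[3],
    stats::setNames(s$categories_before_pct,
                    paste0("pct_before_", names(s$categories_before_pct))),
    stats::setNames(s$categories_after_pct,
                    paste0("pct_after_", names(s$categories_after_pct))),
    prop_p_unchanged = s$prop_p_unchanged,
    est_rema_median = s$est_rema[2], est_bma_median = s$est_bma[2],
    est_robma_median = s$est_robma[2],
    adj_vs_rema_median = s$adj_vs_rema[2],
    adj_vs_bma_median = s$adj_vs_bma[2],
    prop_small_adj_vs_bma = s$prop_small_adj_vs_bma,
    n_sign_reversals = s$n_sign_reversals)
}

summary_markdown <- function(s) {
  fmt <- function(x) sprintf("%.3f", x)
  lev <- names(s$categories_before_pct)
  c(sprintf("# Corpus summary (%d meta-analyses, %d failed fits excluded)",
            s$n_meta, s$n_failed),
    "",
    "## Evidence for the presence of the effect",
    "",
    "| quantity | unadjusted (BMA) | bias-adjusted |",
    "|---|---|---|",
    sprintf("| median P(effect) | %s | %s |",
            fmt(s$p_effect_before[2]), fmt(s$p_effect_after[2])),
    sprintf("| IQR | (%s, %s) | (%s, %s) |",
            fmt(s$p_effect_before[1]), fmt(s$p_effect_before[3]),
            fmt(s$p_effect_after[1]), fmt(s$p_effect_after[3])),
    "",
    sprintf("Posterior probability changed by at most %.2f for %.1f%% of meta-analyses.",
            s$p_change_threshold, 100 * s$prop_p_unchanged),
    "",
    "| evidence category | before (%) | after (%) |",
    "|---|---|---|",
    sprintf("| %s | %.1f | %.1f |", lev,
            s$categories_before_pct, s$categories_after_pct),
    "",
    "## Effect size estimates (r scale)",
    "",
    "| method | median | IQR |",
    "|---|---|---|",
    sprintf("| reMA | %s | (%s, %s) |", fmt(s$est_rema[2]),
            fmt(s$est_rema[1]), fmt(s$est_rema[3])),
    sprintf("| BMA | %s | (%s, %s) |", fmt(s$est_bma[2]),
            fmt(s$est_bma[1]), fmt(s$est_bma[3])),
    sprintf("| bias-adjusted | %s | (%s, %s) |", fmt(s$est_robma[2]),
            fmt(s$est_robma[1]), fmt(s$est_robma[3])),
    "",
    "| adjustment | median | IQR |",
    "|---|---|---|",
    sprintf("| vs reMA | %s | (%s, %s) |", fmt(s$adj_vs_rema[2]),
            fmt(s$adj_vs_rema[1]), fmt(s$adj_vs_rema[3])),
    sprintf("| vs BMA | %s | (%s, %s) |", fmt(s$adj_vs_bma[2]),
            fmt(s$adj_vs_bma[1]), fmt(s$adj_vs_bma[3])),
    "",
    sprintf("Adjustment versus BMA smaller than r = %.2f for %.1f%% of meta-analyses; %d sign reversals.",
            s$r_adj_threshold, 100 * s$prop_small_adj_vs_bma,
            s$n_sign_reversals))
}

plot_probability_change <- function(records) {
  graphics::layout(matrix(c(2, 4, 1, 3), 2, 2), widths = c(4, 1),
                   heights = c(1, 4))
  op <- graphics::par(mar = c(4, 4, 0.5, 0.5))
  on.exit({ graphics::par(op); graphics::layout(1) })
  graphics::plot(records$bma_p_effect, records$robma_p_effect,
                 xlim = 0:1, ylim = 0:1, pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "P(effect), unadjusted (BMA)",
                 ylab = "P(effect), bias-adjusted")
  graphics::abline(0, 1, lty = 3)
  graphics::par(mar = c(0.5, 4, 0.5, 0.5))
  dx <- stats::density(records$bma_p_effect, from = 0, to = 1)
  graphics::plot(dx, type = "l", axes = FALSE, main = "", xlab = "", ylab = "")
  graphics::par(mar = c(4, 0.5, 0.5, 0.5))
  dy <- stats::density(records$robma_p_effect, from = 0, to = 1)
  graphics::plot(dy$y, dy$x, type = "l", axes = FALSE, main = "",
                 xlab = "", ylab = "")
}

plot_estimate_scatters <- function(records) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(op))
  rng <- range(c(records$rema_est_r, records$bma_est_r, records$robma_est_r))
  for (cmp in c("rema_est_r", "bma_est_r")) {
    graphics::plot(records[[cmp]], records$robma_est_r, xlim = rng, ylim = rng,
                   pch = 19, col = grDevices::adjustcolor("steelblue", 0.6),
                   xlab = sprintf("estimate r (%s)",
                                  if (cmp == "rema_est_r") "reMA" else "BMA"),
                   ylab = "bias-adjusted estimate r")
    graphics::abline(0, 1, lty = 3)
  }
}

plot_adjustment_densities <- function(records) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(op))
  d1 <- stats::density(records$rema_est_r)
  d2 <- stats::density(records$bma_est_r)
  d3 <- stats::density(records$robma_est_r)
  graphics::plot(d1, type = "l", col = "grey40", main = "estimates",
                 xlab = "r", ylim = range(0, d1$y, d2$y, d3$y))
  graphics::lines(d2, col = "steelblue")
  graphics::lines(d3, col = "firebrick")
  graphics::legend("topright", c("reMA", "BMA", "adjusted"), bty = "n",
                   col = c("grey40", "steelblue", "firebrick"), lty = 1)
  a1 <- stats::density(records$adj_vs_rema_r)
  a2 <- stats::density(records$adj_vs_bma_r)
  graphics::plot(a1, type = "l", col = "grey40", main = "adjustments",
                 xlab = "difference in r", ylim = range(0, a1$y, a2$y))
  graphics::lines(a2, col = "steelblue")
  graphics::legend("topleft", c("adjusted - reMA", "adjusted - BMA"),
                   bty = "n", col = c("grey40", "steelblue"), lty = 1)
}
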