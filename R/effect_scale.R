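#' Fisher z transformation of a correlation
#'
#' All meta-analytic modelling in this package happens on the Fisher z
#' scale, where the sampling distribution of a correlation is approximately
#' normal with variance `1/(n - 3)` and the estimate is orthogonal to its
#' standard error (an assumption of the PET/PEESE components). Estimates are
#' transformed back to the correlation scale for interpretation.
#'
#' @param r Correlations, strictly inside (-1, 1).
#' @return `atanh(r)`.
#' @seealso [inverse_fisher()], [fisher_se()]
#' @export
fisher_transform <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_transform requires -1 < r < 1")
  atanh(r)
}

#' Back-transform Fisher z to the correlation scale
#'
#' @param z Finite Fisher z values.
#' @return `tanh(z)`, always strictly inside (-1, 1).
#' @export
inverse_fisher <- function(z) {
  if (any(!is.finite(z))) stop("inverse_fisher requires finite z")
  tanh(z)
}

#' Standard error of Fisher z from the sample size
#'
#' @param n Integer sample sizes, at least 4.
#' @return `1/sqrt(n - 3)`.
#' @export
fisher_se <- function(n) {
  if (any(!is.finite(n)) || any(n < 4) || any(n != round(n)))
    stop("fisher_se requires integer n >= 4")
  1 / sqrt(n - 3)
}

#' Assemble a set of primary studies
#'
#' Builds the study-level data frame consumed by all model fitting
#' functions. Either correlations with sample sizes or Fisher z effects with
#' standard errors must be supplied; missing columns are completed using
#' `z = atanh(r)` and `se_z = 1/sqrt(n - 3)`. When both `n` and `se_z` are
#' given, the supplied `se_z` wins and a warning is issued.
#'
#' @param r Correlations in (-1, 1), or `NULL`.
#' @param n Sample sizes (integer, >= 4), or `NULL`.
#' @param z Fisher z effects, or `NULL`.
#' @param se_z Standard errors of z (> 0), or `NULL`.
#' @param article_id,meta_id,study_id Optional identifiers (1-based).
#' @return A data frame with columns `article_id, meta_id, study_id, r, n,
#'   z, se_z`.
#' @export
make_studies <- function(r = NULL, n = NULL, z = NULL, se_z = NULL,
                         article_id = 1L, meta_id = 1L, study_id = NULL) {
  if (is.null(z)) {
    if (is.null(r)) stop("either z or r must be supplied")
    z <- fisher_transform(r)
  }
  k <- length(z)
  if (is.null(se_z)) {
    if (is.null(n)) stop("either se_z or n must be supplied")
    se_z <- fisher_se(n)
  } else if (!is.null(n)) {
    warning("both n and se_z supplied; using se_z")
  }
  if (any(se_z <= 0) || any(!is.finite(se_z))) stop("se_z must be > 0")
  if (length(se_z) != k) stop("z and se_z lengths differ")
  if (is.null(r)) r <- tanh(z)
  if (is.null(n)) n <- NA_integer_
  data.frame(article_id = rep_len(article_id, k),
             meta_id = rep_len(meta_id, k),
             study_id = if (is.null(study_id)) seq_len(k) else study_id,
             r = rep_len(r, k), n = rep_len(n, k),
             z = z, se_z = se_z)
}

corpus_cols <- c("article_id", "meta_id", "study_id", "r", "n", "z", "se_z")

#' Read or write a study-level corpus CSV
#'
#' The corpus schema is one row per primary study with columns
#' `article_id, meta_id, study_id, r, n, z, se_z` (header mandatory; either
#' `(r, n)` or `(z, se_z)` must be present per row; missing entries are
#' completed via the Fisher transform identities).
#'
#' @param path File path.
#' @param corpus A corpus data frame (for writing).
#' @return `read_corpus()` returns the completed data frame.
#' @export
read_corpus <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("article_id", "meta_id", "study_id"), names(x))
  if (length(miss)) stop("corpus CSV missing columns: ", paste(miss, collapse = ", "))
  if (is.null(x$z)) x$z <- NA_real_
  if (is.null(x$se_z)) x$se_z <- NA_real_
  if (is.null(x$r)) x$r <- NA_real_
  if (is.null(x$n)) x$n <- NA_integer_
  fill_z <- is.na(x$z)
  if (any(fill_z & is.na(x$r))) stop("rows with neither z nor r")
  x$z[fill_z] <- fisher_transform(x$r[fill_z])
  fill_se <- is.na(x$se_z)
  if (any(fill_se & is.na(x$n))) stop("rows with neither se_z nor n")
  x$se_z[fill_se] <- fisher_se(x$n[fill_se])
  x$r[is.na(x$r)] <- tanh(x$z[is.na(x$r)])
  x[, corpus_cols]
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(all(corpus_cols %in% names(corpus)))
  utils::write.csv(format_corpus_numeric(corpus[, corpus_cols]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## fixed-precision formatting keeps corpus CSVs byte-stable across platforms
format_corpus_numeric <- function(x) {
  for (cl in c("r", "z", "se_z"))
    if (is.numeric(x[[cl]])) x[[cl]] <- sprintf("%.10g", x[[cl]])
  x
}
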