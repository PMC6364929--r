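#' Classify each article as significant or not
#'
#' An individual test counts as significant when it reports an exact value
#' strictly below \code{alpha}, a "P < x" bound with x at or below
#' \code{alpha}, or a qualitative "significant" statement. Bounds of the
#' form "P > x" and qualitative "NS" are nonsignificant. An article is
#' significant if at least one of its tests is -- the conservative
#' article-level rule.
#'
#' @param ds A \code{literature_dataset}.
#' @param alpha Significance level (default 0.05).
#' @return Named logical vector over article ids.
#' @export
classify_articles <- function(ds, alpha = 0.05) {
  validate_dataset(ds)
  t <- ds$tests
  sig_test <- (t$report_kind == "exact" & t$value < alpha) |
    (t$report_kind == "bound_less" & t$value <= alpha) |
    (t$report_kind == "qualitative_sig")
  flags <- vapply(split(sig_test, t$article_id), any, logical(1))
  flags[ds$articles$article_id]
}

#' Expected number of significant articles under the null
#'
#' @param n Number of articles.
#' @param null_prop Null per-article probability of significance
#'   (0.05 when every article reports one test at alpha = 0.05).
#' @return \code{n * null_prop}.
#' @examples
#' expected_significant(250, 0.05)  # 12.5
#' @export
expected_significant <- function(n, null_prop) {
  stopifnot(n >= 0)
  n * null_prop
}

#' Article-level significance census
#'
#' Counts the articles reporting at least one significant
#' confound-balance test and compares that count against the proportion
#' expected by chance under randomisation (5% at alpha = 0.05) with a
#' one-sided exact binomial test for a deficit of significant articles.
#'
#' @param ds A \code{literature_dataset}.
#' @param alpha Per-test significance level.
#' @param null_prop Null proportion of significant articles.
#' @param confidence Level for the one-sided Clopper-Pearson bound.
#' @return Object of class \code{"census_result"}: list with
#'   \code{n_articles}, \code{n_significant}, \code{expected_significant},
#'   \code{binom} (a \code{binom_test_result}), \code{alpha},
#'   \code{null_prop}.
#' @export
census_test <- function(ds, alpha = 0.05, null_prop = 0.05,
                        confidence = 0.95) {
  flags <- classify_articles(ds, alpha)
  n <- length(flags)
  if (n == 0L) stop("dataset contains no articles")
  k <- sum(flags)
  structure(list(n_articles = n, n_significant = k,
                 expected_significant = expected_significant(n, null_prop),
                 binom = binom_test_less(k, n, null_prop, confidence),
                 alpha = alpha, null_prop = null_prop),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf(
    "Significance census: %d of %d articles significant (%.1f%%)\n",
    x$n_significant, x$n_articles,
    100 * x$n_significant / x$n_articles))
  cat(sprintf("  expected under %.0f%% null: %.1f articles\n",
              100 * x$null_prop, x$expected_significant))
  print(x$binom)
  invisible(x)
}

# sample one test row index per article, `iterations` times;
# returns integer matrix [n_articles x iterations]
.draw_one_per_article <- function(test_article_ids, article_ids, iterations) {
  idx_by_article <- split(seq_along(test_article_ids), test_article_ids)
  idx_by_article <- idx_by_article[article_ids]
  out <- matrix(0L, nrow = length(article_ids), ncol = iterations)
  for (i in seq_along(idx_by_article)) {
    idx <- idx_by_article[[i]]
    out[i, ] <- if (length(idx) == 1L) rep.int(idx, iterations)
                else sample(idx, iterations, replace = TRUE)
  }
  out
}

#' Census over repeated one-test-per-article draws
#'
#' Articles report different numbers of tests, so the plain census mixes
#' articles with very different chances of showing at least one
#' significant result. This procedure repeatedly draws a single test per
#' article at random, reruns the one-sided binomial census on each draw,
#' and summarises the distribution of significant-article counts and of
#' the census P-values (median and SD, the reporting convention used for
#' iterated tests).
#'
#' @param ds A \code{literature_dataset}.
#' @param iterations Number of resampling iterations (default 10000).
#' @param seed Integer seed (mandatory).
#' @param alpha Per-test significance level.
#' @param null_prop Null proportion.
#' @param exact_only If TRUE, only exact reports are drawable; by default
#'   every reported test (including qualitative ones) can be drawn.
#' @return Object of class \code{"resample_result"}: list with
#'   \code{iterations}, \code{counts} (table of significant-article counts
#'   across iterations), \code{modal_count} (ties broken toward the
#'   smaller count), \code{median_p}, \code{sd_p}, \code{seed}.
#' @export
resample_census <- function(ds, iterations = 10000, seed, alpha = 0.05,
                            null_prop = 0.05, exact_only = FALSE) {
  validate_dataset(ds)
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  stopifnot(iterations >= 1)
  t <- ds$tests
  if (exact_only) {
    t <- t[t$report_kind == "exact", , drop = FALSE]
    if (!nrow(t)) stop("no exact reports to resample")
  }
  article_ids <- sort(unique(t$article_id))
  n_articles <- length(article_ids)
  sig_test <- (t$report_kind == "exact" & t$value < alpha) |
    (t$report_kind == "bound_less" & t$value <= alpha) |
    (t$report_kind == "qualitative_sig")
  set.seed(seed)
  draws <- .draw_one_per_article(t$article_id, article_ids, iterations)
  counts <- colSums(matrix(sig_test[draws], nrow = n_articles))
  # census p depends only on the count: evaluate once per distinct count
  uc <- sort(unique(counts))
  p_by_count <- vapply(uc, function(k)
    binom_test_less(k, n_articles, null_prop)$p_value, numeric(1))
  p <- p_by_count[match(counts, uc)]
  count_tab <- table(factor(counts, levels = 0:max(counts)))
  modal <- as.integer(names(count_tab)[which.max(count_tab)])
  structure(list(iterations = as.integer(iterations),
                 n_articles = n_articles,
                 counts = count_tab, modal_count = modal,
                 median_p = stats::median(p),
                 sd_p = if (iterations > 1) stats::sd(p) else 0,
                 seed = as.integer(seed), alpha = alpha,
                 null_prop = null_prop),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "One-test-per-article resampled census (%d iterations, %d articles)\n",
    x$iterations, x$n_articles))
  cat(sprintf("  modal significant count: %d (%.1f%%)\n",
              x$modal_count, 100 * x$modal_count / x$n_articles))
  cat(sprintf("  census P across iterations: median %.4g, SD %.3g\n",
              x$median_p, if (is.na(x$sd_p)) 0 else x$sd_p))
  invisible(x)
}
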