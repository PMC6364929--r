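# bin index for reported P-values: left-closed, right-open bins of equal
# width, last bin closed at 1. A small tolerance keeps printed values like
# 0.05 or 0.15 (not exactly representable in binary) on their intended edge.
.p_bin <- function(p, n_bins) {
  pmin(n_bins, 1L + floor(p * n_bins + 1e-9))
}

#' Build a P-curve (binned distribution of exact P-values)
#'
#' Counts the exact reported P-values of a dataset in \code{n_bins}
#' equal-width bins of [0, 1] (20 by default, the conventional width of
#' 0.05). Bins are left-closed and right-open, the last closed at 1, and
#' binning uses the reported (rounded) value -- what a reader of the
#' article sees -- so a value printed "0.05" falls in [0.05, 0.10).
#' The dataset must already be filtered to exact values
#' (\code{\link{filter_exact_pvalues}}).
#'
#' @param ds A \code{literature_dataset} containing only exact reports.
#' @param n_bins Number of bins (default 20).
#' @return Object of class \code{"pcurve"}: list with \code{bin_edges}
#'   (length \code{n_bins + 1}), \code{counts}, \code{n_values},
#'   \code{n_articles}.
#' @export
build_pcurve <- function(ds, n_bins = 20) {
  validate_dataset(ds)
  stopifnot(n_bins >= 1)
  if (any(ds$tests$report_kind != "exact"))
    stop("dataset contains non-exact reports; apply filter_exact_pvalues first")
  bins <- .p_bin(ds$tests$value, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  structure(list(bin_edges = seq(0, 1, length.out = n_bins + 1),
                 counts = counts,
                 n_values = nrow(ds$tests),
                 n_articles = nrow(ds$articles)),
            class = "pcurve")
}

#' @export
print.pcurve <- function(x, ...) {
  cat(sprintf("P-curve: %d exact P-values from %d articles in %d bins\n",
              x$n_values, x$n_articles, length(x$counts)))
  cat(sprintf("  uniform expectation: %.2f per bin\n",
              uniform_bin_expectation(x$n_values, length(x$counts))))
  invisible(x)
}

#' Convert a P-curve to a plottable table
#'
#' @param x A \code{pcurve}.
#' @param ... Unused.
#' @return data.frame with columns \code{bin_low}, \code{bin_high},
#'   \code{count}, \code{expected} (flat reference line).
#' @export
as.data.frame.pcurve <- function(x, ...) {
  n_bins <- length(x$counts)
  data.frame(bin_low = x$bin_edges[-(n_bins + 1)],
             bin_high = x$bin_edges[-1],
             count = x$counts,
             expected = uniform_bin_expectation(x$n_values, n_bins))
}

#' Flat reference line of a P-curve
#'
#' Expected count per bin if P-values were uniform over [0, 1]:
#' \code{n_items / n_bins} (e.g. 188 articles over 20 bins = 9.4 per bin).
#'
#' @param n_items Number of P-values (or articles, for a one-per-article
#'   curve).
#' @param n_bins Number of bins.
#' @return Expected count per bin.
#' @export
uniform_bin_expectation <- function(n_items, n_bins) {
  stopifnot(n_bins >= 1, n_items >= 0)
  n_items / n_bins
}

# one-sided upper-tail exact binomial p: P(X >= a) for X ~ Binom(n, 0.5)
.binom_upper_tail_half <- function(a, n) {
  if (n == 0L) return(NA_real_)
  sum(binomial_pmf(a:n, n, 0.5))
}

#' Adjacent-bin test just above the significance threshold
#'
#' Tests whether P-values pile up in the bin immediately above 0.05
#' ([0.05, 0.10)) relative to the next bin ([0.10, 0.15)) -- the
#' footprint expected if initially significant confound-balance tests are
#' nudged just past the threshold. Because articles contribute unequal
#' numbers of tests, the test is iterated: each iteration draws one exact
#' P-value per article, counts draws a in [0.05, 0.10) and b in
#' [0.10, 0.15), and runs a one-sided exact binomial test of a successes
#' in a + b trials against 0.5 (alternative: the lower bin is richer).
#' Iterations with no draw in either bin are non-informative; they are
#' excluded from the median/SD and their frequency is reported.
#'
#' @param ds A \code{literature_dataset} of exact reports only.
#' @param iterations Number of one-per-article draws (default 10000).
#' @param seed Integer seed (mandatory).
#' @return Object of class \code{"bin_comparison_result"}: list with
#'   \code{iterations}, \code{lower_counts}, \code{upper_counts}
#'   (per-iteration draws in each bin), \code{median_p}, \code{sd_p},
#'   \code{n_noninformative}, \code{seed}.
#' @export
adjacent_bin_test <- function(ds, iterations = 10000, seed) {
  validate_dataset(ds)
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  stopifnot(iterations >= 1)
  if (any(ds$tests$report_kind != "exact"))
    stop("dataset contains non-exact reports; apply filter_exact_pvalues first")
  t <- ds$tests
  article_ids <- sort(unique(t$article_id))
  bins20 <- .p_bin(t$value, 20L)
  in_lower <- bins20 == 2L   # [0.05, 0.10)
  in_upper <- bins20 == 3L   # [0.10, 0.15)
  set.seed(seed)
  draws <- .draw_one_per_article(t$article_id, article_ids, iterations)
  a <- colSums(matrix(in_lower[draws], nrow = length(article_ids)))
  b <- colSums(matrix(in_upper[draws], nrow = length(article_ids)))
  informative <- (a + b) > 0
  # p depends only on (a, a+b); evaluate each distinct pair once
  key <- paste(a, a + b)
  uk <- !duplicated(key) & informative
  p_by_key <- vapply(which(uk), function(i)
    .binom_upper_tail_half(a[i], a[i] + b[i]), numeric(1))
  names(p_by_key) <- key[uk]
  p <- rep(NA_real_, iterations)
  p[informative] <- p_by_key[key[informative]]
  p_inf <- p[informative]
  structure(list(iterations = as.integer(iterations),
                 n_articles = length(article_ids),
                 lower_counts = a, upper_counts = b,
                 p_values = p,
                 median_p = if (length(p_inf)) stats::median(p_inf) else NA_real_,
                 sd_p = if (length(p_inf) > 1) stats::sd(p_inf) else 0,
                 n_noninformative = sum(!informative),
                 seed = as.integer(seed)),
            class = "bin_comparison_result")
}

#' @export
print.bin_comparison_result <- function(x, ...) {
  cat(sprintf(
    "Adjacent-bin test, [0.05,0.10) vs [0.10,0.15): %d iterations\n",
    x$iterations))
  cat(sprintf("  median P = %.4g, SD = %.3g (%d non-informative iterations)\n",
              x$median_p, x$sd_p, x$n_noninformative))
  invisible(x)
}
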