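#' Binomial probability mass function
#'
#' Evaluates \eqn{P(X = k)} for \eqn{X \sim Binomial(n, p)} in log space,
#' so that it remains accurate for large \code{n} (tested to n = 1e4).
#' This is the primitive underlying the exact binomial census test.
#'
#' @param k Number of successes (vectorised); non-negative integer(s).
#' @param n Number of trials; positive integer.
#' @param p Success probability in [0, 1].
#' @return Numeric vector of probabilities, same length as \code{k}.
#' @examples
#' binomial_pmf(0, 10, 0.5)   # 0.5^10
#' binomial_pmf(4, 250, 0.05)
#' @export
binomial_pmf <- function(k, n, p) {
  if (length(n) != 1L || length(p) != 1L)
    stop("'n' and 'p' must be scalars")
  if (is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a positive integer")
  if (is.na(p) || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]")
  if (any(is.na(k)) || any(k < 0) || any(k != floor(k)))
    stop("'k' must be non-negative integers")
  if (any(k > n))
    stop("'k' must not exceed 'n'")
  # handle the boundary probabilities exactly (log(0) terms)
  out <- numeric(length(k))
  if (p == 0) { out[k == 0] <- 1; return(out) }
  if (p == 1) { out[k == n] <- 1; return(out) }
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}

#' One-sided exact binomial test (alternative: fewer successes than null)
#'
#' Lower-tail exact binomial test of \code{k} successes in \code{n} trials
#' against null proportion \code{p0}, with a one-sided Clopper-Pearson
#' interval of the form [0, upper]. This is the test used to compare the
#' number of "significant" articles in a literature against the 5%
#' expected under honest reporting of null confound-balance tests.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @param confidence Confidence level for the one-sided upper bound
#'   (default 0.95).
#' @return Object of class \code{"binom_test_result"}: a list with
#'   \code{successes}, \code{trials}, \code{null_prob}, \code{p_value},
#'   \code{ci_lower} (always 0), \code{ci_upper}, \code{confidence}.
#' @examples
#' binom_test_less(4, 250, 0.05)  # p ~ 0.005, upper bound ~ 0.036
#' @export
binom_test_less <- function(k, n, p0, confidence = 0.95) {
  if (length(k) != 1L || length(n) != 1L || length(p0) != 1L)
    stop("scalar arguments required")
  if (is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly inside (0, 1)")
  if (is.na(confidence) || confidence <= 0 || confidence >= 1)
    stop("'confidence' must lie strictly inside (0, 1)")
  p_value <- sum(binomial_pmf(0:k, n, p0))
  p_value <- min(p_value, 1)  # guard accumulated rounding at full support
  structure(
    list(successes = as.integer(k), trials = as.integer(n), null_prob = p0,
         p_value = p_value, ci_lower = 0,
         ci_upper = clopper_pearson_upper(k, n, confidence),
         confidence = confidence),
    class = "binom_test_result")
}

#' @export
print.binom_test_result <- function(x, ...) {
  cat(sprintf("One-sided exact binomial test (alternative: true p < %g)\n",
              x$null_prob))
  cat(sprintf("  %d successes in %d trials (%.4f)\n",
              x$successes, x$trials, x$successes / x$trials))
  cat(sprintf("  P = %.6g; one-sided %g%% CI = [0, %.4f]\n",
              x$p_value, 100 * x$confidence, x$ci_upper))
  invisible(x)
}

#' One-sided Clopper-Pearson upper confidence bound
#'
#' Exact upper bound for a binomial proportion: the value u at which the
#' binomial CDF at \code{k} equals \code{1 - confidence}, i.e. the
#' \code{confidence} quantile of Beta(k + 1, n - k). Returns 1 when k = n.
#'
#' @inheritParams binom_test_less
#' @return Upper bound in [0, 1].
#' @examples
#' clopper_pearson_upper(4, 250, 0.95)  # ~ 0.036
#' @export
clopper_pearson_upper <- function(k, n, confidence = 0.95) {
  if (any(is.na(c(k, n))) || k < 0 || k > n || n < 1)
    stop("need 0 <= k <= n with n >= 1")
  if (is.na(confidence) || confidence <= 0 || confidence >= 1)
    stop("'confidence' must lie strictly inside (0, 1)")
  if (k == n) return(1)
  stats::qbeta(confidence, k + 1, n - k)
}

#' Upper-tail probability of the central Student t distribution
#'
#' @param t Observed statistic.
#' @param df Degrees of freedom (> 0).
#' @return \eqn{P(T > t)}.
#' @examples
#' student_t_tail(0.408, 247)  # ~ 0.342
#' @export
student_t_tail <- function(t, df) {
  if (any(is.na(df)) || any(df <= 0)) stop("'df' must be positive")
  stats::pt(t, df = df, lower.tail = FALSE)
}

#' Pooled-variance two-sample Student t test
#'
#' Classical independent-sample t test with pooled variance,
#' df = n_a + n_b - 2. Welch's correction is available via
#' \code{var_equal = FALSE} but the pooled form is the default, matching
#' the usual textbook "independent sample t test".
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param tails \code{"two-sided"} (default) or \code{"one-sided"}
#'   (upper tail of the statistic as computed, a - b).
#' @param var_equal Pool the variances (default TRUE).
#' @return Object of class \code{"t_test_result"}: list with
#'   \code{statistic}, \code{df}, \code{p_value}, \code{tails}.
#' @examples
#' two_sample_t(rnorm(10), rnorm(10))
#' @export
two_sample_t <- function(group_a, group_b,
                         tails = c("two-sided", "one-sided"),
                         var_equal = TRUE) {
  tails <- match.arg(tails)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  if (anyNA(group_a) || anyNA(group_b)) stop("missing values not allowed")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (var_equal) {
    pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (pooled <= 0)
      stop("degenerate data: pooled variance is zero")
    se <- sqrt(pooled * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va <= 0 && vb <= 0)
      stop("degenerate data: both group variances are zero")
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  stat <- (mean(group_a) - mean(group_b)) / se
  p <- if (tails == "two-sided") 2 * student_t_tail(abs(stat), df)
       else student_t_tail(stat, df)
  structure(list(statistic = stat, df = df, p_value = p, tails = tails),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Two-sample t test (%s): t_%g = %.4f, P = %.4g\n",
              x$tails, x$df, x$statistic, x$p_value))
  invisible(x)
}

# minimal pooled-t p-value for hot loops (no validation, two-sided)
.pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (pooled <= 0) return(1)
  stat <- (mean(a) - mean(b)) / sqrt(pooled * (1 / na + 1 / nb))
  2 * stats::pt(abs(stat), na + nb - 2, lower.tail = FALSE)
}

#' Power of the pooled two-sample t test
#'
#' Exact power via the noncentral t distribution, for possibly unequal
#' group sizes: noncentrality \eqn{d \sqrt{n_a n_b / (n_a + n_b)}},
#' df = \eqn{n_a + n_b - 2}. Handles the badly unbalanced designs that
#' arise when comparing a handful of "significant" articles against
#' hundreds of nonsignificant ones.
#'
#' @param n_a,n_b Group sizes (>= 2).
#' @param effect_d Standardised mean difference (Cohen's d).
#' @param alpha Significance level.
#' @param tails \code{"two-sided"} or \code{"one-sided"}.
#' @return Power in [0, 1].
#' @examples
#' power_two_sample_t(4, 246, 0.5)  # ~ 0.17
#' @export
power_two_sample_t <- function(n_a, n_b, effect_d, alpha = 0.05,
                               tails = c("two-sided", "one-sided")) {
  tails <- match.arg(tails)
  if (any(is.na(c(n_a, n_b))) || n_a < 2 || n_b < 2 ||
      n_a != floor(n_a) || n_b != floor(n_b))
    stop("group sizes must be integers >= 2")
  if (is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  df <- n_a + n_b - 2
  ncp <- effect_d * sqrt(n_a * n_b / (n_a + n_b))
  if (tails == "two-sided") {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Round half away from zero
#'
#' Rounding convention used for exact P-values as they would be printed in
#' an article (base \code{round()} rounds half to even). Used both when
#' simulated reports are rounded and when computed statistics are compared
#' against printed values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
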