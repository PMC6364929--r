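#' Reporting policy for simulated articles
#'
#' Governs how a computed confound-balance P-value appears (or not) in a
#' simulated article. The unit interval is split into the three bins
#' [0, 0.05), [0.05, 0.10), [0.10, 1]; the probability of reporting an
#' exact P-value may differ by bin, which is how selective reporting of
#' (near-)significant values is expressed. A value not reported exactly is
#' converted to a bound statement ("P > bound_value") with probability
#' \code{prob_convert_to_bound}, to a qualitative "NS" with probability
#' \code{prob_convert_to_ns}, and is otherwise omitted from the article
#' altogether. So per bin the four outcome probabilities (exact, bound,
#' NS, omitted) sum to one.
#'
#' @param prob_report_exact Length-3 numeric, probability of an exact
#'   report for P in [0, 0.05), [0.05, 0.10), [0.10, 1].
#' @param prob_convert_to_bound Probability (given not exact) of a
#'   "P > bound_value" report.
#' @param prob_convert_to_ns Probability (given not exact) of a
#'   qualitative "NS" report. Must satisfy
#'   \code{prob_convert_to_bound + prob_convert_to_ns <= 1}; the remainder
#'   is omission.
#' @param bound_value Bound used for converted reports (default 0.05, the
#'   most common bound in published "P >" statements).
#' @param decimals_for_exact Decimal places for exact reports (default 2).
#' @return Object of class \code{"reporting_policy"}.
#' @export
reporting_policy <- function(prob_report_exact = c(1, 1, 1),
                             prob_convert_to_bound = 0,
                             prob_convert_to_ns = 0,
                             bound_value = 0.05,
                             decimals_for_exact = 2) {
  prob_report_exact <- rep_len(as.numeric(prob_report_exact), 3L)
  stopifnot(all(prob_report_exact >= 0 & prob_report_exact <= 1),
            prob_convert_to_bound >= 0, prob_convert_to_ns >= 0,
            prob_convert_to_bound + prob_convert_to_ns <= 1 + 1e-12,
            bound_value > 0, bound_value < 1,
            decimals_for_exact >= 1)
  structure(list(prob_report_exact = prob_report_exact,
                 prob_convert_to_bound = prob_convert_to_bound,
                 prob_convert_to_ns = prob_convert_to_ns,
                 bound_value = bound_value,
                 decimals_for_exact = as.integer(decimals_for_exact)),
            class = "reporting_policy")
}

#' Reverse P-hacking policy
#'
#' Describes whether and how a simulated researcher manipulates data until
#' an initially significant confound-balance test becomes nonsignificant.
#'
#' @param enabled Apply hacking to significant tests?
#' @param target_threshold Stop once P reaches this value (default 0.05).
#' @param max_removed_fraction Budget: maximum fraction of the original
#'   data points that may be removed (or added, for the
#'   \code{add_subjects} strategy), in [0, 1).
#' @param strategy \code{"greedy_remove"} (delete the point whose removal
#'   raises P the most, repeatedly), \code{"random_remove"}, or
#'   \code{"add_subjects"} (greedily add new random subjects).
#' @return Object of class \code{"hacking_policy"}.
#' @export
hacking_policy <- function(enabled = FALSE, target_threshold = 0.05,
                           max_removed_fraction = 0.2,
                           strategy = c("greedy_remove", "random_remove",
                                        "add_subjects")) {
  strategy <- match.arg(strategy)
  stopifnot(target_threshold > 0, target_threshold < 1,
            max_removed_fraction >= 0, max_removed_fraction < 1)
  structure(list(enabled = isTRUE(enabled),
                 target_threshold = target_threshold,
                 max_removed_fraction = max_removed_fraction,
                 strategy = strategy),
            class = "hacking_policy")
}

#' Full parameterisation of a synthetic literature
#'
#' Defaults emulate the structure of a behavioural-ecology corpus in which
#' articles test between 1 and 17 potential confounds (about two on
#' average), each test being a two-group comparison of a variable that is
#' truly balanced by randomisation (effect 0), honestly reported.
#'
#' @param n_articles Number of published articles to simulate.
#' @param tests_per_article Either a single integer (every article runs
#'   that many confound tests) or a probability vector over counts
#'   1..length(tests_per_article). Default: geometric with success
#'   probability 0.49 truncated to 1..17, mean about 2 tests/article.
#' @param n_per_group Subjects per experimental group (default 20).
#' @param confound_effect True standardised group difference in each
#'   confound (0 under randomisation).
#' @param reporting A \code{reporting_policy}.
#' @param hacking A \code{hacking_policy}.
#' @param seed Integer seed; mandatory, so simulated literatures are
#'   reproducible.
#' @param mode \code{"data"} simulates subject-level data and runs the
#'   pooled t test per confound (required when hacking is enabled, since
#'   hacking manipulates data points); \code{"uniform"} draws the null
#'   P-values directly from Uniform(0,1), which is faster and is intended
#'   for calibration runs that never touch the data.
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_articles = 250,
                              tests_per_article = trunc_geom_probs(0.49, 17),
                              n_per_group = 20,
                              confound_effect = 0,
                              reporting = reporting_policy(),
                              hacking = hacking_policy(),
                              seed,
                              mode = c("data", "uniform")) {
  mode <- match.arg(mode)
  if (missing(seed) || is.na(seed))
    stop("'seed' is required for a reproducible simulation")
  stopifnot(n_articles >= 1, n_per_group >= 3,
            inherits(reporting, "reporting_policy"),
            inherits(hacking, "hacking_policy"))
  if (mode == "uniform" && hacking$enabled)
    stop("hacking operates on data points; use mode = \"data\"")
  if (length(tests_per_article) == 1L) {
    stopifnot(tests_per_article >= 1)
    probs <- c(rep(0, tests_per_article - 1), 1)
  } else {
    stopifnot(all(tests_per_article >= 0), sum(tests_per_article) > 0)
    probs <- tests_per_article / sum(tests_per_article)
  }
  structure(list(n_articles = as.integer(n_articles),
                 tests_per_article = probs,
                 n_per_group = as.integer(n_per_group),
                 confound_effect = confound_effect,
                 reporting = reporting, hacking = hacking,
                 seed = as.integer(seed), mode = mode),
            class = "simulation_config")
}

#' Truncated geometric probabilities for tests per article
#'
#' P(k) proportional to (1 - q)^(k - 1) on k = 1..max_tests. With
#' q = 0.49 and max_tests = 17 the mean is about 2 tests per article,
#' matching a corpus of roughly two confound tests per article with a
#' heavy-ish tail up to 17.
#'
#' @param q Per-step stopping probability.
#' @param max_tests Upper truncation point.
#' @return Probability vector over 1..max_tests.
#' @export
trunc_geom_probs <- function(q = 0.49, max_tests = 17) {
  stopifnot(q > 0, q < 1, max_tests >= 1)
  p <- q * (1 - q)^(0:(max_tests - 1))
  p / sum(p)
}

#' Simulate one randomised experiment with confound measurements
#'
#' Draws \code{n_per_group} subjects per group for each of
#' \code{n_confounds} confounding variables from a unit-variance Gaussian;
#' the treatment-group mean is shifted by \code{effect} (0 under true
#' randomisation). Each confound is then tested with the pooled two-sample
#' t test, so under effect 0 the P-values are uniform. Uses the current R
#' random number stream.
#'
#' @param n_per_group Subjects per group (>= 3).
#' @param n_confounds Number of confounding variables (>= 1).
#' @param effect True standardised group difference.
#' @return Object of class \code{"confound_experiment"}: lists
#'   \code{control} and \code{treatment} of per-confound value vectors,
#'   a numeric vector \code{p_values}, and \code{effect}.
#' @export
simulate_confound_experiment <- function(n_per_group, n_confounds = 1,
                                         effect = 0) {
  stopifnot(n_per_group >= 3, n_confounds >= 1)
  control <- vector("list", n_confounds)
  treatment <- vector("list", n_confounds)
  p <- numeric(n_confounds)
  for (j in seq_len(n_confounds)) {
    control[[j]] <- stats::rnorm(n_per_group)
    treatment[[j]] <- stats::rnorm(n_per_group, mean = effect)
    p[j] <- .pooled_t_p(control[[j]], treatment[[j]])
  }
  structure(list(control = control, treatment = treatment,
                 p_values = p, effect = effect),
            class = "confound_experiment")
}

#' Reverse P-hack one confound test
#'
#' Mimics a researcher manipulating data until a significant
#' confound-balance test becomes nonsignificant: starting from an
#' experiment whose \code{confound_index}-th test has P below the policy
#' threshold, data points are removed (or added) one at a time until P
#' reaches the threshold, the change budget is exhausted, or a group would
#' shrink below 3 subjects. An already-nonsignificant test is returned
#' untouched with zero steps.
#'
#' @param exp A \code{confound_experiment}.
#' @param confound_index Which confound to manipulate.
#' @param policy A \code{hacking_policy}.
#' @return List with \code{experiment} (updated), \code{steps} (number of
#'   points changed), and \code{success} (did P reach the threshold?).
#' @export
reverse_p_hack <- function(exp, confound_index, policy) {
  stopifnot(inherits(exp, "confound_experiment"),
            inherits(policy, "hacking_policy"),
            confound_index >= 1, confound_index <= length(exp$p_values))
  j <- confound_index
  a <- exp$control[[j]]; b <- exp$treatment[[j]]
  p <- exp$p_values[j]
  thr <- policy$target_threshold
  if (p >= thr)
    return(list(experiment = exp, steps = 0L, success = TRUE))
  budget <- floor(policy$max_removed_fraction * (length(a) + length(b)))
  steps <- 0L
  while (p < thr && steps < budget) {
    if (policy$strategy == "add_subjects") {
      cand_a <- c(a, stats::rnorm(1))
      cand_b <- c(b, stats::rnorm(1, mean = exp$effect))
      p_a <- .pooled_t_p(cand_a, b)
      p_b <- .pooled_t_p(a, cand_b)
      if (p_a >= p_b) { a <- cand_a; p <- p_a } else { b <- cand_b; p <- p_b }
    } else {
      if (length(a) <= 3 && length(b) <= 3) break
      drop_one <- function(x, i) x[-i]
      cand <- list()
      if (length(a) > 3)
        cand <- c(cand, lapply(seq_along(a),
                               function(i) list(g = "a", i = i,
                                                p = .pooled_t_p(a[-i], b))))
      if (length(b) > 3)
        cand <- c(cand, lapply(seq_along(b),
                               function(i) list(g = "b", i = i,
                                                p = .pooled_t_p(a, b[-i]))))
      if (!length(cand)) break
      pick <- if (policy$strategy == "greedy_remove")
        which.max(vapply(cand, `[[`, numeric(1), "p"))
      else sample.int(length(cand), 1)
      ch <- cand[[pick]]
      if (ch$g == "a") a <- drop_one(a, ch$i) else b <- drop_one(b, ch$i)
      p <- ch$p
    }
    steps <- steps + 1L
  }
  exp$control[[j]] <- a
  exp$treatment[[j]] <- b
  exp$p_values[j] <- p
  list(experiment = exp, steps = steps, success = p >= thr)
}

#' Turn computed P-values into published reports
#'
#' Applies a \code{reporting_policy} independently to each P-value: it
#' becomes an exact report (rounded half-away-from-zero to the policy's
#' decimals), a "P > bound" statement, a qualitative "NS", or is omitted.
#' Bin membership (which exact-report probability applies) is decided on
#' the computed, unrounded P-value. Uses the current R random stream.
#'
#' @param p_values Numeric vector of P-values in [0, 1].
#' @param policy A \code{reporting_policy}.
#' @return data.frame with columns \code{report_kind} (including
#'   \code{"omitted"}), \code{value}, \code{decimals}.
#' @export
apply_reporting_policy <- function(p_values, policy) {
  stopifnot(inherits(policy, "reporting_policy"),
            all(p_values >= 0 & p_values <= 1))
  n <- length(p_values)
  bin <- ifelse(p_values < 0.05, 1L, ifelse(p_values < 0.10, 2L, 3L))
  p_exact <- policy$prob_report_exact[bin]
  u <- stats::runif(n)
  kind <- character(n)
  exact <- u < p_exact
  kind[exact] <- "exact"
  # conditional split of the non-exact mass: bound / NS / omitted
  u2 <- (u - p_exact) / pmax(1 - p_exact, .Machine$double.eps)
  kind[!exact & u2 < policy$prob_convert_to_bound] <- "bound_greater"
  kind[!exact & kind == "" &
         u2 < policy$prob_convert_to_bound + policy$prob_convert_to_ns] <-
    "qualitative_ns"
  kind[kind == ""] <- "omitted"
  value <- rep(NA_real_, n)
  decimals <- rep(NA_integer_, n)
  value[kind == "exact"] <- round_half_up(p_values[kind == "exact"],
                                          policy$decimals_for_exact)
  decimals[kind == "exact"] <- policy$decimals_for_exact
  value[kind == "bound_greater"] <- policy$bound_value
  data.frame(report_kind = kind, value = value, decimals = decimals,
             stringsAsFactors = FALSE)
}

#' Simulate a published literature
#'
#' Generates \code{n_articles} articles: each runs a randomised experiment
#' with a drawn number of confound tests; if hacking is enabled every test
#' significant at the policy threshold is reverse-P-hacked; the resulting
#' P-values then pass through the reporting policy. Tests that end up
#' omitted do not appear, and an article whose every test is omitted drops
#' out of the dataset entirely (it published no confound-balance test).
#' Fully reproducible from the config's seed.
#'
#' @param config A \code{simulation_config}.
#' @return A \code{literature_dataset}.
#' @export
simulate_literature <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  k_max <- length(config$tests_per_article)
  art_rows <- vector("list", config$n_articles)
  test_rows <- vector("list", config$n_articles)
  for (i in seq_len(config$n_articles)) {
    n_tests <- sample.int(k_max, 1, prob = config$tests_per_article)
    if (config$mode == "uniform") {
      p <- stats::runif(n_tests)
    } else {
      exp <- simulate_confound_experiment(config$n_per_group, n_tests,
                                          config$confound_effect)
      if (config$hacking$enabled) {
        for (j in which(exp$p_values < config$hacking$target_threshold)) {
          exp <- reverse_p_hack(exp, j, config$hacking)$experiment
        }
      }
      p <- exp$p_values
    }
    rep <- apply_reporting_policy(p, config$reporting)
    keep <- rep$report_kind != "omitted"
    if (!any(keep)) next
    id <- sprintf("A%04d", i)
    art_rows[[i]] <- data.frame(article_id = id, journal = "synthetic",
                                year = 2000L + (i %% 19L),
                                stringsAsFactors = FALSE)
    test_rows[[i]] <- data.frame(article_id = id,
                                 confound_label =
                                   sprintf("confound_%d", which(keep)),
                                 report_kind = rep$report_kind[keep],
                                 value = rep$value[keep],
                                 decimals = rep$decimals[keep],
                                 stringsAsFactors = FALSE)
  }
  articles <- do.call(rbind, art_rows[!vapply(art_rows, is.null, TRUE)])
  tests <- do.call(rbind, test_rows[!vapply(test_rows, is.null, TRUE)])
  if (is.null(articles))
    stop("every simulated article omitted all its tests")
  rownames(articles) <- rownames(tests) <- NULL
  literature_dataset(articles, tests)
}
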