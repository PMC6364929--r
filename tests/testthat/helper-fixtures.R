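# small literature fixtures built in code

# two articles, three tests (one bound report)
make_small_dataset <- function() {
  literature_dataset(
    articles = data.frame(
      article_id = c("A1", "A2"),
      journal = c("J Behav Ecol", "Ethology"),
      year = c(2001L, 2012L),
      stringsAsFactors = FALSE),
    tests = data.frame(
      article_id = c("A1", "A1", "A2"),
      confound_label = c("body size", "age", "mass"),
      report_kind = c("exact", "bound_greater", "exact"),
      value = c(0.30, 0.05, 0.07),
      decimals = c(2L, NA_integer_, 2L),
      stringsAsFactors = FALSE))
}

# a deterministic corpus-shaped dataset: n_articles articles of which
# n_sig report at least one significant exact P-value; two of the
# significant articles also carry extra nonsignificant tests (sizes 2 and
# 8), mirroring the structure where multi-test articles dilute their
# significant result under one-test-per-article resampling
make_census_dataset <- function(n_articles = 250, n_sig = 4) {
  stopifnot(n_sig >= 2, n_articles > n_sig)
  ids <- sprintf("A%04d", seq_len(n_articles))
  nonsig_cycle <- c(0.20, 0.35, 0.50, 0.65, 0.80, 0.95, 0.12, 0.27)
  rows <- list()
  add <- function(id, values) {
    data.frame(article_id = id, confound_label = "confound",
               report_kind = "exact", value = values, decimals = 2L,
               stringsAsFactors = FALSE)
  }
  rows[[1]] <- add(ids[1], c(0.03, 0.44))                 # 2 tests, 1 sig
  rows[[2]] <- add(ids[2], c(0.01, nonsig_cycle[1:7]))    # 8 tests, 1 sig
  for (i in 3:n_sig) rows[[i]] <- add(ids[i], 0.02)
  for (i in (n_sig + 1):n_articles)
    rows[[i]] <- add(ids[i], nonsig_cycle[1 + (i %% length(nonsig_cycle))])
  literature_dataset(
    articles = data.frame(article_id = ids, journal = "fixture",
                          year = 1990L + (seq_len(n_articles) %% 29L),
                          stringsAsFactors = FALSE),
    tests = do.call(rbind, rows))
}

# exact distribution of the significant-article count when one test is
# drawn per article: Poisson-binomial over per-article probabilities,
# computed by direct convolution (independent oracle for resample_census)
poisson_binomial_pmf <- function(probs) {
  dist <- 1
  for (q in probs) dist <- c(dist * (1 - q), 0) + c(0, dist * q)
  dist
}
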