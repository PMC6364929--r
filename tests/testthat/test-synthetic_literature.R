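test_that("null confound experiments give uniform P-values", {
  # fraction significant within 3 Monte-Carlo SEs of 5%, and a KS
  # uniformity check passed in the majority of seeded repeats
  n_draws <- 20000
  ks_pass <- logical(3)
  for (s in 1:3) {
    set.seed(100 + s)
    p <- unlist(lapply(1:200, function(i)
      simulate_confound_experiment(10, n_confounds = 100)$p_values))
    if (s == 1) {
      se <- sqrt(0.05 * 0.95 / n_draws)
      expect_lt(abs(mean(p < 0.05) - 0.05), 3 * se)
    }
    ks_pass[s] <- suppressWarnings(ks.test(p, "punif")$p.value) > 0.01
  }
  expect_gte(sum(ks_pass), 2)
})

test_that("experiments are reproducible from the random seed", {
  set.seed(7); e1 <- simulate_confound_experiment(8, 3, effect = 0.2)
  set.seed(7); e2 <- simulate_confound_experiment(8, 3, effect = 0.2)
  expect_identical(e1, e2)
  expect_true(all(e1$p_values >= 0 & e1$p_values <= 1))
})

test_that("reverse_p_hack honours its no-op, budget and group-size contracts", {
  pol <- hacking_policy(enabled = TRUE, max_removed_fraction = 0.3)
  # already nonsignificant: untouched, zero steps, success
  set.seed(1)
  repeat {
    exp <- simulate_confound_experiment(10, 1)
    if (exp$p_values[1] >= 0.05) break
  }
  out <- reverse_p_hack(exp, 1, pol)
  expect_identical(out$experiment, exp)
  expect_identical(out$steps, 0L)
  expect_true(out$success)
  # zero budget on a significant test: unchanged data, failure
  set.seed(2)
  repeat {
    exp <- simulate_confound_experiment(10, 1)
    if (exp$p_values[1] < 0.05) break
  }
  out <- reverse_p_hack(exp, 1, hacking_policy(TRUE, max_removed_fraction = 0))
  expect_identical(out$experiment$control, exp$control)
  expect_false(out$success)
  # groups at the floor of 3 cannot shrink further
  exp3 <- structure(list(control = list(c(0, 0.1, 0.2)),
                         treatment = list(c(2, 2.1, 2.2)),
                         p_values = NA, effect = 0),
                    class = "confound_experiment")
  exp3$p_values <- two_sample_t(exp3$control[[1]], exp3$treatment[[1]])$p_value
  out <- reverse_p_hack(exp3, 1, pol)
  expect_false(out$success)
  expect_length(out$experiment$control[[1]], 3)
})

test_that("the first greedy removal matches exhaustive single-deletion search", {
  set.seed(31)
  repeat {
    exp <- simulate_confound_experiment(10, 1)
    if (exp$p_values[1] < 0.05) break
  }
  a <- exp$control[[1]]; b <- exp$treatment[[1]]
  # oracle: recompute the test for every possible single deletion
  best_p <- -1; best <- NULL
  for (i in seq_along(a)) {
    p <- t.test(a[-i], b, var.equal = TRUE)$p.value
    if (p > best_p) { best_p <- p; best <- list(g = "a", i = i) }
  }
  for (i in seq_along(b)) {
    p <- t.test(a, b[-i], var.equal = TRUE)$p.value
    if (p > best_p) { best_p <- p; best <- list(g = "b", i = i) }
  }
  # one greedy step (budget of exactly one point out of 20)
  out <- reverse_p_hack(exp, 1, hacking_policy(TRUE, max_removed_fraction = 0.05))
  expect_identical(out$steps, 1L)
  got <- if (best$g == "a")
    list(out$experiment$control[[1]], a[-best$i])
  else list(out$experiment$treatment[[1]], b[-best$i])
  expect_equal(got[[1]], got[[2]])
  expect_equal(out$experiment$p_values[1], best_p, tolerance = 1e-12)
})

test_that("successfully hacked tests end at or above the threshold", {
  set.seed(41)
  n_success <- 0
  for (i in 1:60) {
    exp <- simulate_confound_experiment(15, 1)
    if (exp$p_values[1] >= 0.05) next
    out <- reverse_p_hack(exp, 1, hacking_policy(TRUE, max_removed_fraction = 0.6))
    if (out$success) {
      n_success <- n_success + 1
      expect_gte(out$experiment$p_values[1], 0.05)
    }
  }
  expect_gt(n_success, 0)
})

test_that("apply_reporting_policy follows its per-bin contracts", {
  set.seed(51)
  p <- runif(500)
  # identity policy: everything exact, rounded to 2 decimals
  out <- apply_reporting_policy(p, reporting_policy())
  expect_true(all(out$report_kind == "exact"))
  expect_equal(out$value, round_half_up(p, 2))
  expect_true(all(out$decimals == 2L))
  # censoring policy: no exact value below 0.10
  pol <- reporting_policy(prob_report_exact = c(0, 0, 1),
                          prob_convert_to_bound = 1)
  out <- apply_reporting_policy(p, pol)
  expect_false(any(out$value[out$report_kind == "exact"] < 0.10))
  expect_true(all(out$report_kind[p < 0.10] == "bound_greater"))
  expect_true(all(out$value[out$report_kind == "bound_greater"] == 0.05))
})

test_that("reporting category frequencies match the configured probabilities", {
  # all P-values in one bin, so the category law is a single multinomial
  pol <- reporting_policy(prob_report_exact = c(1, 1, 0.4),
                          prob_convert_to_bound = 0.3,
                          prob_convert_to_ns = 0.2)
  n <- 50000
  set.seed(61)
  out <- apply_reporting_policy(rep(0.5, n), pol)
  probs <- c(exact = 0.4, bound_greater = 0.6 * 0.3,
             qualitative_ns = 0.6 * 0.2, omitted = 0.6 * 0.5)
  for (kind in names(probs)) {
    freq <- mean(out$report_kind == kind)
    se <- sqrt(probs[[kind]] * (1 - probs[[kind]]) / n)
    expect_lt(abs(freq - probs[[kind]]), 3 * se)
  }
})

test_that("an honest simulated literature is null-calibrated at the article level", {
  cfg <- simulation_config(n_articles = 5000, tests_per_article = 1,
                           seed = 71, mode = "uniform")
  lit <- simulate_literature(cfg)
  frac <- mean(classify_articles(lit, 0.05))
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("honest exact P-value histograms are flat across 20 bins", {
  crit <- qchisq(0.99, df = 19)
  below <- 0
  for (s in 1:20) {
    cfg <- simulation_config(n_articles = 210, seed = 5000 + s,
                             mode = "uniform")
    lit <- simulate_literature(cfg)
    pc <- build_pcurve(filter_exact_pvalues(lit), 20)
    expected <- pc$n_values / 20
    stat <- sum((pc$counts - expected)^2 / expected)
    below <- below + (stat < crit)
  }
  expect_gt(below, 10)
})

test_that("hacked literatures shift reported P-values upward", {
  # a nonzero group difference makes most confound tests start significant,
  # so the manipulation acts on most of the mass and its direction is
  # visible in a rank comparison
  honest_cfg <- simulation_config(n_articles = 200, n_per_group = 12,
                                  confound_effect = 0.8,
                                  seed = 81, mode = "data")
  hacked_cfg <- simulation_config(n_articles = 200, n_per_group = 12,
                                  confound_effect = 0.8,
                                  seed = 81, mode = "data",
                                  hacking = hacking_policy(
                                    TRUE, max_removed_fraction = 0.45))
  p_honest <- filter_exact_pvalues(simulate_literature(honest_cfg))$tests$value
  p_hacked <- filter_exact_pvalues(simulate_literature(hacked_cfg))$tests$value
  # stochastic dominance direction: hacked values are larger
  w <- wilcox.test(p_hacked, p_honest, alternative = "greater")
  expect_lt(w$p.value, 0.05)
  # and the sub-threshold mass moves just above the threshold
  expect_lt(mean(p_hacked < 0.05), mean(p_honest < 0.05))
  pc <- build_pcurve(
    filter_exact_pvalues(simulate_literature(hacked_cfg)), 20)
  expect_gt(pc$counts[2], pc$n_values / 20)
})

test_that("the full simulation pipeline is byte-deterministic given a seed", {
  cfg <- simulation_config(n_articles = 60, seed = 91, mode = "data",
                           reporting = reporting_policy(
                             prob_report_exact = c(0.5, 0.7, 0.9),
                             prob_convert_to_bound = 0.5,
                             prob_convert_to_ns = 0.3))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(simulate_literature(cfg), f1)
  write_dataset(simulate_literature(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # uniform mode refuses hacking, which operates on data points
  expect_error(simulation_config(seed = 1, mode = "uniform",
                                 hacking = hacking_policy(TRUE)),
               "data")
})
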