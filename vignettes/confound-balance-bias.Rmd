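---
title: "Detecting a bias toward nonsignificant confound-balance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a bias toward nonsignificant confound-balance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullbias)
```

## The model

When subjects are randomly assigned to treatment and control groups, any
test of a between-group difference in an unmanipulated (confounding)
variable tests a true null hypothesis. Its P-value is therefore uniform
on [0, 1], and across a literature of such tests 5% should be significant
at $\alpha = 0.05$. `nullbias` asks whether a literature departs from
that expectation *downward* — the signature of selective reporting of
nonsignificant results or of reverse P-hacking — using two complementary
instruments.

**The census.** Each article is classified significant if it reports at
least one significant confound test, giving a count $K$ out of $N$
articles. Under honest reporting with one test per article,
$K \sim \mathrm{Binomial}(N, 0.05)$, and a deficit is assessed with the
one-sided lower-tail exact test $P(X \le K)$ together with the one-sided
Clopper–Pearson interval $[0, u]$, where $u$ is the 0.95 quantile of
$\mathrm{Beta}(K + 1, N - K)$. The direction is one-sided "fewer than
expected" throughout: the question is whether significant results are
missing, and the matching interval has the form $[0, u]$.

**The P-curve and adjacent-bin test.** Exactly reported P-values (at
least two decimal places) are binned into 20 bins of width 0.05. Honest
null reporting gives a flat curve at $n/20$ per bin. Reverse P-hacking
that stops as soon as a test crosses $P \ge 0.05$ should instead pile
values into $[0.05, 0.10)$; the adjacent-bin test compares the counts $a$
in $[0.05, 0.10)$ and $b$ in $[0.10, 0.15)$ with a one-sided exact
binomial test of $a$ successes in $a + b$ trials against $\tfrac12$
(alternative: the lower bin is richer). This is the standard two-bin
formulation; it returns large P-values when the lower bin is in fact
*poorer*, which is what a censoring mechanism produces.

**One-test-per-article resampling.** Articles report 1–17 confound tests,
and an article with many tests has more than a 5% chance of showing at
least one significant one. Both iterated procedures therefore draw one
test (or one exact P-value) per article, repeat the draw (10,000
iterations by default), and summarise the per-iteration statistics by
their median and SD, plus the full distribution of significant-article
counts. Iterations of the adjacent-bin test in which no draw lands in
either bin are non-informative; they are excluded from the median and
their frequency is reported, since including them would require inventing
a P-value for a test that could not be run.

## Reading published reports

Published articles report P-values as exact numbers ("P = 0.23"), as
bounds ("P > 0.05", "P < 0.01"), or qualitatively ("NS"). The dataset
schema keeps the report kind, the value, and — for exact reports — the
number of decimal places as stated, so "0.30" and "0.3" remain
distinguishable and the two-decimal filter used by the P-curve stages is
applied to what the article actually printed.

Classification reads reports the way a reader would: an exact value is
significant when strictly below $\alpha$ (a printed "P = 0.05" is *not*
significant), "P < x" counts as significant when $x \le \alpha$,
"P > x" and "NS" are nonsignificant. Binning likewise uses the printed
(rounded) value, so "0.05" falls in $[0.05, 0.10)$.

Rounding has a quantifiable side effect worth knowing about: if raw
P-values are uniform and printed to two decimals, the printed value is
below 0.05 only when the raw value is below 0.045. The per-article
significance rate of an honest two-decimal literature is therefore 4.5%,
not 5%, which nudges the lower-tail census toward rejection (empirically
a rejection rate near 0.07–0.08 at $N = 250$ instead of the discrete
binomial's 0.031). This is not an artifact of the implementation but of
reading rounded tables — the same convention under which a surveyed
corpus is extracted — and it is visible in the calibration results below.

## The literature simulator

`simulate_literature()` generates articles end to end:

1. **Experiment.** Each article runs one randomized experiment measuring
   1–17 confounds (truncated-geometric distributed, mean ≈ 2, matching a
   corpus averaging about two confound tests per article), with
   `n_per_group` subjects per group (default 20, a typical
   behavioural-ecology sample) drawn from a unit Gaussian; the treatment
   mean is shifted by `confound_effect` (0 under true randomization).
   Each confound is tested with the pooled two-sample t test, so null
   P-values are uniform by construction.
2. **Hacking (optional).** Every test significant at the threshold is
   manipulated until nonsignificant: `greedy_remove` deletes the single
   data point whose removal raises P the most and repeats;
   `random_remove` deletes random points; `add_subjects` greedily adds
   new random subjects. The budget `max_removed_fraction` caps the
   fraction of data points changed, groups never shrink below 3, and the
   outcome records whether the threshold was reached. P-values are
   simulated by actually manipulating data, not by shifting numbers,
   because the mechanism being emulated operates on data points; a
   `mode = "uniform"` shortcut draws null P-values directly for
   calibration runs that never touch the data (it refuses hacking).
3. **Reporting.** Each P-value independently becomes an exact report
   (rounded half-away-from-zero to 2 decimals by default), a "P > 0.05"
   bound, a qualitative "NS", or is omitted. The exact-report probability
   is a step function over the bins $[0, 0.05)$, $[0.05, 0.10)$,
   $[0.10, 1]$ — censoring "marginal" values is exactly a low
   exact-probability in the first bins. Conditional on not reporting
   exactly, the bound/NS/omit split is governed by two probabilities, so
   the four outcome probabilities sum to one within each bin. Articles
   whose every test is omitted disappear from the dataset: they published
   no confound-balance test.

Everything is reproducible from the config seed, to the byte, in the
serialized CSV.

What the simulator does *not* emulate: correlated confounds within an
experiment, heterogeneous group sizes across articles, non-Gaussian
measurements, reviewer/editor behaviour, or hacking of the focal
(non-confound) test. Passing calibration here shows the tests behave
correctly under the stated mechanisms, not that real literatures contain
no other distortions.

## Choices of hacking strategy and scenario design

Greedy removal takes the largest available step each time, so it tends to
overshoot: the first removal that crosses 0.05 often lands well past
0.10 — a behaviour worth simulating because the displaced mass then
*escapes* the adjacent-bin test's window, which is a genuine limitation
of that test. Random removal crosses the threshold in small steps and
lands just above 0.05, the scenario the adjacent-bin test is designed to
catch. The power demonstrations therefore use `random_remove`, and pair
it with a nonzero `confound_effect` so that an appreciable share of tests
starts significant: under a strict null only 5% of the mass is
displaceable, and a single 400-article literature gives the bin test
little to find. How far hacked values travel past 0.05 in real
literatures is unknowable from published values alone, so the simulator
exposes the budget and strategy rather than asserting a landing
distribution.

## Calibration

`run_calibration()` simulates literatures under a scenario grid and
tabulates rejection rates with Monte-Carlo standard errors
$\sqrt{r(1-r)/R}$:

```{r calibration, eval = FALSE}
run_calibration(replicates = 500, seed = 1)
```

Honest scenarios use one test per article — the setting where the
census's 5% null holds exactly. With several tests per article an honest
article is significant *more* than 5% of the time, so the lower-tail
census becomes strongly conservative (it essentially never rejects);
that dependence is precisely what the resampled census corrects. Full
censoring of exact P-values below 0.10 into "P > 0.05" bounds drives the
census rejection rate to 1 at $N = 250$: the detection problem is easy
when the mechanism is strong.

## Numerical choices

* Binomial tail probabilities are accumulated from a log-space PMF
  (`lchoose` plus log terms), stable to $n = 10^4$ and beyond; the
  Clopper–Pearson bound uses the Beta-quantile inversion.
* The two-sample test is the classical pooled-variance Student t
  (`var_equal = FALSE` switches to Welch); degenerate (zero-variance)
  input is an error, never a silent statistic.
* Power uses the noncentral t with noncentrality
  $d\sqrt{n_a n_b/(n_a+n_b)}$. For the badly unbalanced year comparison
  (groups of 4 and 246, $d = 0.5$, two-sided $\alpha = 0.05$) this gives
  16.7%; reports sometimes quote such power as "15%" from approximate
  tables, and the package reports its exact computed value rather than
  reproducing any particular rounding.
* The year t-test tail is one-sided: $P(T_{247} > 0.408) = 0.342$
  matches the conventional report of that comparison, where the
  two-sided value (≈ 0.68) does not.
* "Rounds to" comparisons and exact-report rounding use
  half-away-from-zero (`round_half_up`), the convention of printed
  tables; base R's `round()` rounds half to even.
* Bin assignment adds a $10^{-9}$ tolerance before flooring so printed
  edge values (0.05, 0.15, ...) land in their intended left-closed bin
  despite binary floating point.
* Modal resampled counts break ties toward the smaller count; this can
  matter only in pathological symmetric cases and is documented rather
  than randomized.

## Problem sizes used in the test suite

The suite verifies null calibration with $2\times10^4$ simulated tests,
checks the resampled census against the exact Poisson-binomial law on
15-article datasets at $10^5$ iterations (total-variation distance below
0.01), and calibrates both detection tests over 500 honest literatures of
250 single-test articles — sizes chosen so that three Monte-Carlo
standard errors give decisive bounds while the whole suite runs in a few
minutes on one CPU.

## Limitations

* The census's 5% null is exact only for one reported test per article;
  for real multi-test articles use the resampled census.
* The adjacent-bin test has power only against hacking that lands in
  $[0.05, 0.10)$; overshooting mechanisms evade it by design, and a true
  deficit below 0.10 (censoring of "marginally significant" values)
  yields large median P rather than small.
* With bounds and "NS" statements carrying no exact value, censored
  literatures lose P-curve sample size exactly where the signal is; the
  census, which uses all report kinds, is the more robust instrument.
* The import schema is the package's own; mapping a third-party
  extraction spreadsheet onto it is left to a small user-written adapter.
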