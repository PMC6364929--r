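Package: nullbias
Title: Detecting Publication Bias Toward Nonsignificant Results in
    Confound-Balance Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether a literature under-reports significant
    results from tests of confounding-variable balance between randomly
    assigned experimental groups. Under randomisation such tests have
    uniform P-values, so 5 percent should be significant at alpha = 0.05;
    the package compares the observed number of "significant" articles
    against that expectation with a one-sided exact binomial test and
    Clopper-Pearson bound, builds 20-bin P-curves of exactly reported
    P-values, runs an iterated one-test-per-article adjacent-bin test just
    above the significance threshold, and simulates whole literatures under
    honest reporting, selective reporting, and reverse P-hacking to
    calibrate both detection tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
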