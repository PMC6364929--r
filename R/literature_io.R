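#' @importFrom utils read.csv write.csv packageVersion
NULL

# recognised ways a P-value can be reported in an article
REPORT_KINDS <- c("exact", "bound_greater", "bound_less",
                  "qualitative_ns", "qualitative_sig")

DATASET_COLUMNS <- c("article_id", "journal", "year", "confound_label",
                     "report_kind", "value", "decimals")

#' Construct a literature-extraction dataset
#'
#' A literature dataset holds one row per reported confound-balance test
#' (a test that a potentially confounding variable does not differ between
#' randomised treatment and control groups), plus per-article metadata.
#' Each test carries a P-value report that is either an exact value with a
#' stated number of decimal places, an inequality bound ("P > 0.05",
#' "P < 0.01"), or a qualitative statement ("NS" / "significant").
#'
#' @param articles data.frame with columns \code{article_id},
#'   \code{journal}, \code{year} (year may be NA).
#' @param tests data.frame with columns \code{article_id},
#'   \code{confound_label}, \code{report_kind}, \code{value},
#'   \code{decimals}. \code{value} is NA for qualitative kinds;
#'   \code{decimals} is only meaningful for \code{report_kind = "exact"}.
#' @return Object of class \code{"literature_dataset"}.
#' @export
literature_dataset <- function(articles, tests) {
  articles <- as.data.frame(articles, stringsAsFactors = FALSE)
  tests <- as.data.frame(tests, stringsAsFactors = FALSE)
  ds <- structure(list(articles = articles, tests = tests),
                  class = "literature_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a literature dataset
#'
#' Checks the structural invariants: unique non-empty article ids, every
#' test resolving to an article, every article carrying at least one test,
#' report kinds drawn from the recognised set, values in [0, 1], and exact
#' values consistent with their stated decimal places.
#'
#' @param ds A \code{literature_dataset}.
#' @param rows Optional integer vector of source row numbers for the tests
#'   (used in error messages when called from \code{read_dataset}).
#' @return \code{ds}, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(ds, rows = NULL) {
  a <- ds$articles; t <- ds$tests
  if (is.null(rows)) rows <- seq_len(nrow(t))
  if (!all(c("article_id", "journal", "year") %in% names(a)))
    stop("articles table must have columns article_id, journal, year")
  need <- c("article_id", "confound_label", "report_kind", "value", "decimals")
  if (!all(need %in% names(t)))
    stop("tests table must have columns ", paste(need, collapse = ", "))
  if (any(is.na(a$article_id) | !nzchar(a$article_id)))
    stop("empty article_id in articles table")
  if (anyDuplicated(a$article_id))
    stop("duplicate article_id: ",
         paste(unique(a$article_id[duplicated(a$article_id)]), collapse = ", "))
  bad <- which(is.na(t$report_kind) | !(t$report_kind %in% REPORT_KINDS))
  if (length(bad))
    stop(sprintf("row %d: unknown report kind '%s'",
                 rows[bad[1]], t$report_kind[bad[1]]))
  dangling <- which(!(t$article_id %in% a$article_id))
  if (length(dangling))
    stop(sprintf("row %d: test references unknown article '%s'",
                 rows[dangling[1]], t$article_id[dangling[1]]))
  childless <- setdiff(a$article_id, t$article_id)
  if (length(childless))
    stop("article(s) without any test: ", paste(childless, collapse = ", "))
  qualit <- t$report_kind %in% c("qualitative_ns", "qualitative_sig")
  bad <- which(!qualit & (is.na(t$value) | t$value < 0 | t$value > 1))
  if (length(bad))
    stop(sprintf("row %d: report value %s outside [0, 1]",
                 rows[bad[1]], format(t$value[bad[1]])))
  ex <- which(t$report_kind == "exact")
  if (length(ex)) {
    if (any(is.na(t$decimals[ex]) | t$decimals[ex] < 0))
      stop(sprintf("row %d: exact report without valid 'decimals'",
                   rows[ex[which(is.na(t$decimals[ex]) | t$decimals[ex] < 0)[1]]]))
    scaled <- t$value[ex] * 10^t$decimals[ex]
    off <- which(abs(scaled - round(scaled)) > 1e-9)
    if (length(off))
      stop(sprintf(
        "row %d: exact value %s inconsistent with %d stated decimals",
        rows[ex[off[1]]], format(t$value[ex[off[1]]]), t$decimals[ex[off[1]]]))
  }
  invisible(ds)
}

#' @export
print.literature_dataset <- function(x, ...) {
  cat(sprintf("Literature dataset: %d articles, %d reported tests\n",
              nrow(x$articles), nrow(x$tests)))
  tab <- table(x$tests$report_kind)
  cat("  report kinds:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a literature dataset from CSV
#'
#' One row per test, with article metadata repeated on each row. Schema:
#' \code{article_id,journal,year,confound_label,report_kind,value,decimals}
#' (UTF-8, header required; empty fields for absent values). Validation
#' failures report the offending file row.
#'
#' @param path Path to (or connection for) the CSV file.
#' @return A \code{literature_dataset}.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(article_id = "character",
                                        journal = "character",
                                        confound_label = "character"),
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[DATASET_COLUMNS]
  raw$year <- suppressWarnings(as.integer(raw$year))
  raw$value <- suppressWarnings(as.numeric(raw$value))
  raw$decimals <- suppressWarnings(as.integer(raw$decimals))
  first <- !duplicated(raw$article_id)
  articles <- data.frame(article_id = raw$article_id[first],
                         journal = raw$journal[first],
                         year = raw$year[first],
                         stringsAsFactors = FALSE)
  tests <- raw[c("article_id", "confound_label", "report_kind",
                 "value", "decimals")]
  rownames(tests) <- NULL
  ds <- structure(list(articles = articles, tests = tests),
                  class = "literature_dataset")
  # +1 for the header row so messages name the physical file line
  validate_dataset(ds, rows = seq_len(nrow(tests)) + 1L)
  ds
}

#' Write a literature dataset to CSV
#'
#' Inverse of \code{read_dataset}: canonical column order, rows sorted by
#' \code{article_id} then original test order, exact values serialised at
#' their stated number of decimals so that "0.30" survives a round-trip.
#'
#' @param ds A \code{literature_dataset}.
#' @param path Output path or connection.
#' @return \code{ds}, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  t <- ds$tests
  ord <- order(match(t$article_id, sort(unique(t$article_id))),
               seq_len(nrow(t)))
  t <- t[ord, , drop = FALSE]
  a <- ds$articles[match(t$article_id, ds$articles$article_id), ]
  value_chr <- character(nrow(t))
  for (i in seq_len(nrow(t))) {
    if (is.na(t$value[i])) value_chr[i] <- ""
    else if (t$report_kind[i] == "exact")
      value_chr[i] <- formatC(t$value[i], format = "f",
                              digits = t$decimals[i])
    else value_chr[i] <- format(t$value[i], scientific = FALSE)
  }
  out <- data.frame(article_id = t$article_id,
                    journal = a$journal,
                    year = ifelse(is.na(a$year), "", as.character(a$year)),
                    confound_label = t$confound_label,
                    report_kind = t$report_kind,
                    value = value_chr,
                    decimals = ifelse(is.na(t$decimals), "",
                                      as.character(t$decimals)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(ds)
}

#' Keep only exact P-values reported to enough decimal places
#'
#' P-curve analysis uses only numerically reported P-values; values given
#' as bounds ("P > 0.05") or qualitative statements ("NS") are dropped, as
#' are exact values printed to fewer than \code{min_decimals} places.
#' Articles left with no usable test are removed from the dataset.
#'
#' @param ds A \code{literature_dataset}.
#' @param min_decimals Minimum decimal places for an exact value to be
#'   retained (default 2).
#' @return Filtered \code{literature_dataset}.
#' @export
filter_exact_pvalues <- function(ds, min_decimals = 2) {
  validate_dataset(ds)
  keep <- ds$tests$report_kind == "exact" &
    !is.na(ds$tests$decimals) & ds$tests$decimals >= min_decimals
  tests <- ds$tests[keep, , drop = FALSE]
  rownames(tests) <- NULL
  articles <- ds$articles[ds$articles$article_id %in% tests$article_id, ,
                          drop = FALSE]
  rownames(articles) <- NULL
  structure(list(articles = articles, tests = tests),
            class = "literature_dataset")
}
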