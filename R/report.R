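# Validation reports: a findings tibble plus an overall validity flag.

finding <- function(code, message, severity = "error", locus = NA_integer_,
                    row = NA_integer_, column = NA_character_) {
  n <- length(code)
  tibble::new_tibble(list(
    severity = rep_len(severity, n), code = code,
    message = rep_len(message, n), locus = rep_len(as.integer(locus), n),
    row = rep_len(as.integer(row), n), column = rep_len(column, n)
  ), nrow = n)
}

.empty_findings <- finding(character(0), character(0), character(0))

no_findings <- function() .empty_findings

#' Construct a validation report
#'
#' A `mave_report` bundles a findings table (one row per finding, with
#' `severity` in `error`/`warning`/`info`, a machine-readable `code`, a
#' human-readable `message`, and optional `locus`/`row`/`column` context)
#' with a `valid` flag that is `TRUE` iff no error-severity findings exist.
#' Findings are sorted by (severity, row, code) so reports diff cleanly.
#'
#' @param findings A tibble as produced by the validators.
#' @return A `mave_report` object.
#' @keywords internal
new_report <- function(findings) {
  if (nrow(findings) > 1L) {
    sev <- match(findings$severity, c("error", "warning", "info"))
    findings <- findings[order(sev, findings$row, findings$code), ]
  }
  structure(
    list(valid = !any(findings$severity == "error"), findings = findings),
    class = "mave_report"
  )
}

#' @export
print.mave_report <- function(x, ...) {
  status <- if (x$valid) "VALID" else "INVALID"
  cat(sprintf("<mave_report> %s (%d finding%s)\n", status, nrow(x$findings),
              if (nrow(x$findings) == 1) "" else "s"))
  if (nrow(x$findings)) print(x$findings, n = 20)
  invisible(x)
}

#' Tidy a validation report into its findings tibble
#'
#' @param x A `mave_report`.
#' @param ... Unused.
#' @return A tibble with one row per finding.
#' @export
tidy.mave_report <- function(x, ...) x$findings

#' One-row summary of a validation report
#'
#' @param x A `mave_report`.
#' @param ... Unused.
#' @return A tibble with columns `valid`, `n_error`, `n_warning`, `n_info`.
#' @export
glance.mave_report <- function(x, ...) {
  tibble::tibble(
    valid = x$valid,
    n_error = sum(x$findings$severity == "error"),
    n_warning = sum(x$findings$severity == "warning"),
    n_info = sum(x$findings$severity == "info")
  )
}

#' Error-severity findings of a report
#'
#' Convenience accessor used throughout the tests: the subset of findings
#' with severity `error`.
#'
#' @param report A `mave_report`.
#' @return A tibble of error findings.
#' @export
report_errors <- function(report) {
  dplyr::filter(report$findings, .data$severity == "error")
}

merge_reports <- function(...) {
  new_report(dplyr::bind_rows(lapply(list(...), function(r) {
    if (inherits(r, "mave_report")) r$findings else r
  })))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
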