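# URN accessions: the hierarchical "urn:mavedb:NNNNNNNN[-x[-k[#v]]]" scheme.
#
# Levels: experiment set (urn:mavedb:00000055), experiment
# (urn:mavedb:00000055-a), score set (urn:mavedb:00000055-a-1), and variant
# (urn:mavedb:00000055-a-1#7). Unpublished records use the same structure
# with the "urn:mavedb:" prefix replaced by "tmp:".

.urn_re <- "^(urn:mavedb:|tmp:)([0-9]{8})(?:-([a-z]+)(?:-([1-9][0-9]*)(?:#([1-9][0-9]*))?)?)?$"

#' Parse a MaveDB-style URN accession
#'
#' Accessions are hierarchical: an 8-digit zero-padded experiment-set number,
#' an optional lowercase-letter experiment suffix, an optional positive
#' score-set index, and an optional `#`-separated variant index. Each deeper
#' field requires the shallower ones.
#'
#' @param s A single URN string, e.g. `"urn:mavedb:00000055"` or
#'   `"urn:mavedb:00000055-a-1#7"`.
#' @return A `mave_urn` object with fields `experiment_set` (integer),
#'   `experiment_suffix`, `score_set_index`, `variant_index` (NA when
#'   absent), `temporary` (flag) and `level` (one of `"experiment_set"`,
#'   `"experiment"`, `"score_set"`, `"variant"`).
#' @examples
#' parse_urn("urn:mavedb:00000055")
#' parse_urn("urn:mavedb:00000055-a-1")
#' @export
parse_urn <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    mave_abort("mave_malformed_urn", "URN must be a single nonempty string")
  }
  m <- regmatches(s, regexec(.urn_re, s))[[1]]
  if (!length(m)) {
    hint <- if (grepl("^urn:mavedb:[0-9]{1,7}($|-)", s)) {
      " (experiment-set number must be zero-padded to 8 digits)"
    } else {
      ""
    }
    mave_abort("mave_malformed_urn", sprintf("malformed URN '%s'%s", s, hint))
  }
  suffix <- if (m[4] == "") NA_character_ else m[4]
  ss <- if (m[5] == "") NA_integer_ else as.integer(m[5])
  vi <- if (m[6] == "") NA_integer_ else as.integer(m[6])
  level <- if (!is.na(vi)) "variant" else if (!is.na(ss)) "score_set" else
    if (!is.na(suffix)) "experiment" else "experiment_set"
  structure(
    list(experiment_set = as.integer(m[3]), experiment_suffix = suffix,
         score_set_index = ss, variant_index = vi,
         temporary = m[2] == "tmp:", level = level),
    class = "mave_urn"
  )
}

#' Format a URN object as its canonical accession string
#'
#' Deterministic inverse of [parse_urn()].
#'
#' @param u A `mave_urn` or a list with the same fields.
#' @return A single character string.
#' @examples
#' format_urn(parse_urn("urn:mavedb:00000055-a-1#7"))
#' @export
format_urn <- function(u) {
  if (!is.list(u) || is.null(u$experiment_set)) {
    mave_abort("mave_invalid_urn", "not a mave_urn object")
  }
  if (!is.na(u$variant_index %||% NA) && is.na(u$score_set_index %||% NA) ||
      !is.na(u$score_set_index %||% NA) && is.na(u$experiment_suffix %||% NA)) {
    mave_abort("mave_invalid_urn",
               "deeper URN fields require the shallower ones to be present")
  }
  ns <- if (isTRUE(u$temporary)) "tmp:" else "urn:mavedb:"
  out <- sprintf("%s%08d", ns, u$experiment_set)
  if (!is.na(u$experiment_suffix %||% NA)) {
    out <- paste0(out, "-", u$experiment_suffix)
    if (!is.na(u$score_set_index %||% NA)) {
      out <- paste0(out, "-", u$score_set_index)
      if (!is.na(u$variant_index %||% NA)) {
        out <- paste0(out, "#", u$variant_index)
      }
    }
  }
  out
}

#' @export
print.mave_urn <- function(x, ...) {
  cat(sprintf("<mave_urn> %s (%s level)\n", format_urn(x), x$level))
  invisible(x)
}

#' Does one URN extend another?
#'
#' `TRUE` when `child` is a strictly deeper accession under `parent`
#' (e.g. a score set under its experiment).
#'
#' @param child,parent URN strings.
#' @return Logical scalar.
#' @export
urn_extends <- function(child, parent) {
  startsWith(child, paste0(parent, "-")) || startsWith(child, paste0(parent, "#"))
}

urn_level <- function(s) parse_urn(s)$level

# filesystem-safe name for archive table files
urn_slug <- function(s) gsub("[:#]", "-", s)
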