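# Score and count table schema validation.
#
# Tables are plain tibbles. Reserved columns: hgvs_nt, hgvs_splice, hgvs_pro
# (variant strings) and score; any number of additional numeric columns may
# be present. Missing-value tokens are the empty string and "NA", exactly.

variant_column_names <- c("hgvs_nt", "hgvs_splice", "hgvs_pro")

cell_chr <- function(x) {
  out <- as.character(x)
  out[is.na(out)] <- ""
  out
}

cell_is_missing <- function(x) cell_chr(x) %in% c("", "NA")

cell_as_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  chr <- cell_chr(x)
  out <- suppressWarnings(as.numeric(chr))
  out[cell_is_missing(x)] <- NA_real_
  out
}

#' Read a score or count table from CSV
#'
#' Reads an RFC 4180 CSV with a mandatory header row. All columns come back
#' as character so that validation can report non-numeric cells verbatim;
#' [validate_score_table()] and the summary functions coerce numeric columns
#' themselves.
#'
#' @param path Path to a CSV file.
#' @return A tibble of character columns.
#' @export
read_score_csv <- function(path) {
  if (!file.exists(path)) {
    mave_abort("mave_io_error", sprintf("table file not found: '%s'", path))
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE)
}

#' Write a score or count table to CSV
#'
#' Missing cells are written as empty fields; numbers use the shortest
#' round-trip decimal representation, so writing the same table twice is
#' bit-identical.
#'
#' @param t A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(t, path) {
  t <- tibble::as_tibble(t)
  for (cn in names(t)) {
    if (is.numeric(t[[cn]])) t[[cn]] <- shortest_decimal(t[[cn]])
  }
  readr::write_csv(t, path, na = "", progress = FALSE)
  invisible(path)
}

# shortest decimal string that parses back to exactly the same double
shortest_decimal <- function(x) {
  out <- rep(NA_character_, length(x))
  for (i in which(!is.na(x))) {
    if (x[i] == trunc(x[i]) && abs(x[i]) < 1e15) {
      out[i] <- sprintf("%.0f", x[i])
      next
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, x[i])
      if (as.numeric(s) == x[i]) break
    }
    out[i] <- s
  }
  out
}

variant_tuple_key <- function(t) {
  vcols <- intersect(variant_column_names, names(t))
  if (!length(vcols)) return(rep("", nrow(t)))
  keys <- lapply(vcols, function(cn) {
    x <- cell_chr(t[[cn]])
    x[cell_is_missing(t[[cn]])] <- ""
    x
  })
  do.call(paste, c(keys, sep = "\r"))
}

parse_cell_variant <- function(s, column) {
  tryCatch(
    list(variant = parse_variant(s, splice_context = column == "hgvs_splice"),
         finding = NULL),
    mave_error = function(e) {
      code <- if (inherits(e, "mave_unsupported_feature")) "UNSUPPORTED_FEATURE"
        else if (inherits(e, "mave_offset_not_allowed")) "OFFSET_NOT_ALLOWED"
        else "MALFORMED_VARIANT"
      list(variant = NULL, finding = list(code = code, message = conditionMessage(e)))
    }
  )
}

check_numeric_columns <- function(t, numeric_cols, sign_check = FALSE) {
  out <- list()
  for (cn in numeric_cols) {
    chr <- cell_chr(t[[cn]])
    missing <- cell_is_missing(t[[cn]])
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!missing & is.na(num))
    for (i in bad) {
      out[[length(out) + 1L]] <- finding(
        "NON_NUMERIC", sprintf("cell '%s' in column '%s' is not numeric", chr[i], cn),
        row = i, column = cn)
    }
    if (sign_check) {
      neg <- which(!missing & !is.na(num) & num < 0)
      for (i in neg) {
        out[[length(out) + 1L]] <- finding(
          "NEGATIVE_COUNT", sprintf("negative count %s in column '%s'", chr[i], cn),
          row = i, column = cn)
      }
    }
  }
  dplyr::bind_rows(c(list(no_findings()), out))
}

check_variant_columns <- function(t, target = NULL) {
  vcols <- intersect(variant_column_names, names(t))
  out <- list()
  ctx_nt <- ctx_pro <- NULL
  if (!is.null(target)) {
    if (target$kind == "nucleotide") {
      ctx_nt <- target_validation_context(target, protein_level = FALSE)
    }
    if (target$kind == "protein" ||
        (target$category == "coding" && nchar(target$sequence) %% 3L == 0L)) {
      ctx_pro <- target_validation_context(target, protein_level = TRUE)
    }
  }
  col_chr <- lapply(t[vcols], cell_chr)
  col_missing <- lapply(t[vcols], cell_is_missing)
  names(col_chr) <- names(col_missing) <- vcols
  for (i in seq_len(nrow(t))) {
    prefixes <- character(0)
    for (cn in vcols) {
      raw <- col_chr[[cn]][i]
      if (col_missing[[cn]][i]) next
      res <- parse_cell_variant(raw, cn)
      if (is.null(res$variant)) {
        out[[length(out) + 1L]] <- finding(res$finding$code, res$finding$message,
                                           row = i, column = cn)
        next
      }
      v <- res$variant
      expected <- if (cn == "hgvs_pro") "p" else c("g", "c", "n")
      if (!v$prefix %in% expected) {
        out[[length(out) + 1L]] <- finding(
          "INVALID_PREFIX",
          sprintf("prefix '%s.' not allowed in column '%s'", v$prefix, cn),
          row = i, column = cn)
        next
      }
      prefixes <- c(prefixes, v$prefix)
      ctx <- if (cn == "hgvs_pro") ctx_pro else ctx_nt
      if (!is.null(ctx)) {
        ff <- variant_findings(v, ctx)
        if (nrow(ff)) {
          ff$row <- rep(i, nrow(ff))
          ff$column <- rep(cn, nrow(ff))
          out[[length(out) + 1L]] <- ff
        }
      }
    }
    # nucleotide and protein strings may coexist; contradictory nucleotide
    # prefixes within one row cannot describe the same molecule
    nt_prefixes <- setdiff(unique(prefixes), "p")
    if (length(nt_prefixes) > 1L) {
      out[[length(out) + 1L]] <- finding(
        "PREFIX_CONFLICT",
        sprintf("row mixes nucleotide prefixes %s", paste(nt_prefixes, collapse = "/")),
        row = i)
    }
  }
  dplyr::bind_rows(c(list(no_findings()), out))
}

#' Validate a score table
#'
#' Schema validation for a per-variant score table: the mandatory `score`
#' column, at least one variant column (`hgvs_nt`, `hgvs_splice`,
#' `hgvs_pro`), numeric parseability of every non-variant column, variant
#' strings that parse under the MAVE-HGVS grammar (offset positions only in
#' `hgvs_splice`), consistency with the target sequence when one is given,
#' uniqueness of the full variant-column tuple per row, and a score column
#' that is not entirely missing.
#'
#' @param t A tibble (columns may be character or numeric).
#' @param target Optional `mave_target` for sequence-consistency checks.
#' @return A `mave_report`. Finding codes include `MISSING_SCORE_COLUMN`,
#'   `MISSING_VARIANT_COLUMN`, `NON_NUMERIC`, `MALFORMED_VARIANT`,
#'   `REF_MISMATCH`, `OUT_OF_BOUNDS`, `DUPLICATE_VARIANT`,
#'   `EMPTY_SCORE_COLUMN`.
#' @export
validate_score_table <- function(t, target = NULL) {
  if (!is.data.frame(t) || is.null(names(t)) || !length(names(t))) {
    mave_abort("mave_bad_table", "score table must be a data frame with a header")
  }
  t <- tibble::as_tibble(t)
  out <- list()
  vcols <- intersect(variant_column_names, names(t))
  if (!"score" %in% names(t)) {
    out[[length(out) + 1L]] <- finding("MISSING_SCORE_COLUMN",
                                       "required column 'score' is absent")
  }
  if (!length(vcols)) {
    out[[length(out) + 1L]] <- finding("MISSING_VARIANT_COLUMN",
      "at least one of hgvs_nt/hgvs_splice/hgvs_pro is required")
  }
  numeric_cols <- setdiff(names(t), variant_column_names)
  out[[length(out) + 1L]] <- check_numeric_columns(t, numeric_cols)
  if ("score" %in% names(t) && nrow(t) > 0 && all(cell_is_missing(t$score))) {
    out[[length(out) + 1L]] <- finding("EMPTY_SCORE_COLUMN",
                                       "score column is entirely missing")
  }
  if (length(vcols)) {
    out[[length(out) + 1L]] <- check_variant_columns(t, target)
    key <- variant_tuple_key(t)
    dup <- which(duplicated(key) & nzchar(gsub("\r", "", key)))
    for (i in dup) {
      out[[length(out) + 1L]] <- finding(
        "DUPLICATE_VARIANT",
        sprintf("variant tuple duplicates row %d", match(key[i], key)), row = i)
    }
  }
  new_report(dplyr::bind_rows(c(list(no_findings()), out)))
}

#' Validate a count table against its paired score table
#'
#' Counts are optional companions to scores: per-variant nonnegative numbers
#' (missing allowed). Checks that the variant tuples of the two tables
#' match set-wise in both directions, that no count is negative or
#' non-numeric, and that no variant lacks both a score and all counts.
#'
#' @param scores Score table (tibble).
#' @param counts Count table (tibble) sharing the variant columns.
#' @return A `mave_report` with codes `UNMATCHED_VARIANT`, `NEGATIVE_COUNT`,
#'   `NON_NUMERIC`, `MISSING_DATA`.
#' @export
validate_count_consistency <- function(scores, counts) {
  if (!is.data.frame(scores) || !is.data.frame(counts)) {
    mave_abort("mave_bad_table", "scores and counts must be data frames")
  }
  scores <- tibble::as_tibble(scores)
  counts <- tibble::as_tibble(counts)
  out <- list()
  count_cols <- setdiff(names(counts), variant_column_names)
  out[[length(out) + 1L]] <- check_numeric_columns(counts, count_cols,
                                                   sign_check = TRUE)
  skey <- variant_tuple_key(scores)
  ckey <- variant_tuple_key(counts)
  for (i in which(!ckey %in% skey)) {
    out[[length(out) + 1L]] <- finding(
      "UNMATCHED_VARIANT",
      sprintf("count row %d has no matching variant in the score table", i),
      row = i, column = "counts")
  }
  for (i in which(!skey %in% ckey)) {
    out[[length(out) + 1L]] <- finding(
      "UNMATCHED_VARIANT",
      sprintf("score row %d has no matching variant in the count table", i),
      row = i, column = "scores")
  }
  if ("score" %in% names(scores)) {
    idx <- match(skey, ckey)
    for (i in which(!is.na(idx) & cell_is_missing(scores$score))) {
      crow <- counts[idx[i], count_cols, drop = FALSE]
      if (all(vapply(crow, cell_is_missing, logical(1)))) {
        out[[length(out) + 1L]] <- finding(
          "MISSING_DATA",
          sprintf("row %d has neither a score nor any counts", i), row = i)
      }
    }
  }
  new_report(dplyr::bind_rows(c(list(no_findings()), out)))
}

#' Validate a score set's tables in one call
#'
#' Convenience wrapper combining [validate_score_table()] on the scores and,
#' when a count table is given, [validate_count_consistency()] on the pair.
#' This is the validator the command-line `validate` command runs.
#'
#' @param scores Score table.
#' @param counts Optional count table.
#' @param target Optional `mave_target`.
#' @return A single aggregated `mave_report`.
#' @export
validate_score_set <- function(scores, counts = NULL, target = NULL) {
  rep <- validate_score_table(scores, target)
  if (!is.null(counts)) {
    rep <- merge_reports(rep, validate_count_consistency(scores, counts))
  }
  rep
}
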