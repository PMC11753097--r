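# MAVE-HGVS grammar: parsing, canonical formatting, covered positions.
#
# The dialect implemented here is the strictly validatable subset of the HGVS
# nomenclature used for MAVE targets: substitution, deletion, duplication,
# insertion, deletion-insertion, and target-identical events under the g., c.,
# n. and p. prefixes, plus multi-event variants in square brackets. Uncertain
# positions, predictions in parentheses, frameshift shorthand, repeats and
# alleles are deliberately out of the subset and raise a dedicated condition.

#' Three-letter amino-acid codes
#'
#' The twenty standard residues in alphabetical order by three-letter code,
#' followed by `Ter` (the stop symbol). This is the row alphabet used for
#' protein-level variants and effect matrices.
#'
#' @format Character vector of length 21.
#' @keywords internal
aa3_codes <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "Ter"
)

aa1_to_aa3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

.aa3_alt <- paste(aa3_codes, collapse = "|")

mave_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "mave_error"), ...)
}

new_event <- function(kind, start, start_offset = 0L, end = start,
                      end_offset = start_offset, ref = NA_character_,
                      alt = NA_character_, start_ref = NA_character_,
                      end_ref = NA_character_) {
  tibble::new_tibble(list(
    kind = kind,
    start = as.integer(start), start_offset = as.integer(start_offset),
    end = as.integer(end), end_offset = as.integer(end_offset),
    ref = ref, alt = alt, start_ref = start_ref, end_ref = end_ref
  ), nrow = 1L)
}

new_variant <- function(prefix, events, raw) {
  structure(list(prefix = prefix, events = events, raw = raw),
            class = "mave_variant")
}

#' @export
print.mave_variant <- function(x, ...) {
  cat("<mave_variant> ", format_variant(x), "\n", sep = "")
  cat("  prefix: ", x$prefix, ", events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

# --- position helpers --------------------------------------------------------

.pos_re <- "([0-9]+)([+-][0-9]+)?"

parse_offset <- function(tok) {
  if (is.na(tok) || tok == "") return(0L)
  as.integer(tok)
}

check_offsets <- function(events, splice_context, s) {
  if (!splice_context &&
      any(events$start_offset != 0L | events$end_offset != 0L)) {
    mave_abort("mave_offset_not_allowed",
               sprintf("offset positions are only allowed in splice context: '%s'", s))
  }
  invisible(events)
}

# --- nucleotide event parsing ------------------------------------------------

parse_nt_event <- function(tok, s) {
  if (tok == "=") {
    return(new_event("identical", 1L, end = 1L))
  }
  # delins before del: both share the 'del' keyword
  m <- regmatches(tok, regexec(
    paste0("^", .pos_re, "(?:_", .pos_re, ")?delins([ACGT]+)$"), tok))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); so <- parse_offset(m[3])
    end <- if (m[4] == "") start else as.integer(m[4])
    eo <- if (m[4] == "") so else parse_offset(m[5])
    ev <- new_event("delins", start, so, end, eo, alt = m[6])
    return(check_span(ev, tok, s))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .pos_re, "(?:_", .pos_re, ")?(del|dup)$"), tok))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); so <- parse_offset(m[3])
    end <- if (m[4] == "") start else as.integer(m[4])
    eo <- if (m[4] == "") so else parse_offset(m[5])
    kind <- if (m[6] == "del") "deletion" else "duplication"
    ev <- new_event(kind, start, so, end, eo)
    return(check_span(ev, tok, s))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .pos_re, "_", .pos_re, "ins([ACGT]+)$"), tok))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); so <- parse_offset(m[3])
    end <- as.integer(m[4]); eo <- parse_offset(m[5])
    adjacent <- (eo == so && end == start + 1L) ||
      (end == start && eo == so + 1L)
    if (!adjacent) {
      mave_abort("mave_malformed_variant",
                 sprintf("insertion flanks must be adjacent in '%s' (event '%s')", s, tok))
    }
    return(new_event("insertion", start, so, end, eo, alt = m[6]))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .pos_re, "([ACGT])>([ACGT])$"), tok))[[1]]
  if (length(m)) {
    if (m[4] == m[5]) {
      mave_abort("mave_malformed_variant",
                 sprintf("substitution reference equals alternate in '%s'; write the target-identical variant as '%s.='",
                         s, "<prefix>"))
    }
    return(new_event("substitution", as.integer(m[2]), parse_offset(m[3]),
                     ref = m[4], alt = m[5]))
  }
  mave_abort("mave_malformed_variant",
             sprintf("unrecognized event '%s' in variant '%s'", tok, s))
}

# --- protein event parsing ---------------------------------------------------

.p_pos_re <- paste0("(", .aa3_alt, ")([0-9]+)")

split_aa3 <- function(x) {
  # split a concatenated run of three-letter codes; already regex-validated
  substring(x, seq(1L, nchar(x) - 2L, by = 3L), seq(3L, nchar(x), by = 3L))
}

parse_pro_event <- function(tok, s) {
  if (tok == "=") {
    return(new_event("identical", 1L, end = 1L))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .p_pos_re, "(?:_", .p_pos_re, ")?delins((?:", .aa3_alt, ")+)$"),
    tok))[[1]]
  if (length(m)) {
    start <- as.integer(m[3])
    end <- if (m[4] == "") start else as.integer(m[5])
    end_ref <- if (m[4] == "") m[2] else m[4]
    ev <- new_event("delins", start, end = end, alt = m[6],
                    start_ref = m[2], end_ref = end_ref)
    return(check_span(ev, tok, s))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .p_pos_re, "(?:_", .p_pos_re, ")?(del|dup)$"), tok))[[1]]
  if (length(m)) {
    start <- as.integer(m[3])
    end <- if (m[4] == "") start else as.integer(m[5])
    end_ref <- if (m[4] == "") m[2] else m[4]
    kind <- if (m[6] == "del") "deletion" else "duplication"
    ev <- new_event(kind, start, end = end, start_ref = m[2], end_ref = end_ref)
    return(check_span(ev, tok, s))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .p_pos_re, "_", .p_pos_re, "ins((?:", .aa3_alt, ")+)$"),
    tok))[[1]]
  if (length(m)) {
    start <- as.integer(m[3]); end <- as.integer(m[5])
    if (end != start + 1L) {
      mave_abort("mave_malformed_variant",
                 sprintf("insertion flanks must be adjacent in '%s' (event '%s')", s, tok))
    }
    return(new_event("insertion", start, end = end, alt = m[6],
                     start_ref = m[2], end_ref = m[4]))
  }
  m <- regmatches(tok, regexec(
    paste0("^", .p_pos_re, "(", .aa3_alt, ")$"), tok))[[1]]
  if (length(m)) {
    if (m[2] == m[4]) {
      mave_abort("mave_malformed_variant",
                 sprintf("substitution reference equals alternate in '%s'; write the target-identical variant as 'p.='", s))
    }
    return(new_event("substitution", as.integer(m[3]), ref = m[2], alt = m[4],
                     start_ref = m[2]))
  }
  if (grepl(paste0("^([A-Z*])([0-9]+)"), tok) &&
      !grepl(paste0("^(", .aa3_alt, ")"), tok)) {
    mave_abort("mave_malformed_variant",
               sprintf("one-letter amino-acid codes are not accepted ('%s' in '%s'); use three-letter codes", tok, s))
  }
  mave_abort("mave_malformed_variant",
             sprintf("unrecognized event '%s' in variant '%s'", tok, s))
}

check_span <- function(ev, tok, s) {
  if (ev$end < ev$start ||
      (ev$end == ev$start && ev$end_offset < ev$start_offset)) {
    mave_abort("mave_malformed_variant",
               sprintf("range end precedes start in '%s' (event '%s')", s, tok))
  }
  if (!is.na(ev$start_ref) && ev$end == ev$start &&
      ev$end_offset == ev$start_offset && ev$end_ref != ev$start_ref) {
    mave_abort("mave_malformed_variant",
               sprintf("inconsistent residues at a single position in '%s'", s))
  }
  ev
}

# --- screening for features outside the subset -------------------------------

screen_unsupported <- function(s) {
  if (grepl("_wt$|_sy$|^_wt|^_sy", s) || grepl("(^|[.;\\[])_(wt|sy)", s)) {
    mave_abort("mave_malformed_variant",
               sprintf("legacy Enrich2 token in '%s': '_wt'/'_sy' are not valid MAVE-HGVS; use '<prefix>.=' for target-identical variants", s))
  }
  if (grepl("[?()]", s)) {
    mave_abort("mave_unsupported_feature",
               sprintf("uncertainty or prediction notation in '%s' is valid HGVS but outside the MAVE-HGVS subset", s))
  }
  if (grepl("fs", s, fixed = TRUE)) {
    mave_abort("mave_unsupported_feature",
               sprintf("frameshift shorthand in '%s' is outside the MAVE-HGVS subset", s))
  }
  if (grepl("\\[[0-9]+\\]", s)) {
    mave_abort("mave_unsupported_feature",
               sprintf("repeat notation in '%s' is outside the MAVE-HGVS subset", s))
  }
  invisible(s)
}

# --- public API --------------------------------------------------------------

#' Parse a MAVE-HGVS variant string
#'
#' Parses one variant string in the MAVE-HGVS dialect into a structured
#' `mave_variant` object: a sequence prefix (`g.`, `c.`, `n.` or `p.`) and one
#' or more events. Multi-event variants are written in square brackets with
#' events separated by semicolons and must be listed in ascending position
#' order with no overlapping reference positions.
#'
#' @param s A single variant string, e.g. `"c.1A>G"`, `"p.Trp24Cys"`,
#'   `"c.[1A>G;5del]"`.
#' @param splice_context Allow intronic offset positions such as `"122-6"`.
#'   These occur only in the `hgvs_splice` table column; outside that context
#'   an offset raises an error because it cannot be checked against a
#'   contiguous target.
#' @return A `mave_variant`: a list with elements `prefix` (character),
#'   `events` (a tibble with one row per event) and `raw` (the input string).
#' @section Errors: `mave_malformed_variant` for syntax violations,
#'   `mave_unsupported_feature` for full-HGVS constructs outside the subset
#'   (uncertainty `?`, parentheses, frameshifts, repeats),
#'   `mave_offset_not_allowed` for offsets outside splice context.
#' @examples
#' parse_variant("c.1A>G")
#' parse_variant("p.Trp24Cys")
#' parse_variant("c.[1A>G;5del]")
#' parse_variant("c.122-6T>A", splice_context = TRUE)
#' @export
parse_variant <- function(s, splice_context = FALSE) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    mave_abort("mave_malformed_variant", "variant must be a single nonempty string")
  }
  screen_unsupported(s)
  m <- regmatches(s, regexec("^([gcnp])\\.(.+)$", s))[[1]]
  if (!length(m)) {
    if (grepl("^[GCNP]\\.", s)) {
      mave_abort("mave_malformed_variant",
                 sprintf("prefix must be lowercase in '%s' (character 1)", s))
    }
    mave_abort("mave_malformed_variant",
               sprintf("missing or invalid prefix in '%s' (expected g., c., n. or p. at character 1)", s))
  }
  prefix <- m[2]
  body <- m[3]
  multi <- grepl("^\\[.*\\]$", body)
  if (grepl("[][]", body) && !multi) {
    mave_abort("mave_malformed_variant",
               sprintf("unbalanced brackets in '%s'", s))
  }
  toks <- if (multi) {
    inner <- substr(body, 2L, nchar(body) - 1L)
    strsplit(inner, ";", fixed = TRUE)[[1]]
  } else {
    body
  }
  if (length(toks) < 1L || any(!nzchar(toks))) {
    mave_abort("mave_malformed_variant", sprintf("empty event in '%s'", s))
  }
  if (multi && length(toks) < 2L) {
    mave_abort("mave_malformed_variant",
               sprintf("bracketed variant must contain at least two events: '%s'", s))
  }
  parse_one <- if (prefix == "p") parse_pro_event else parse_nt_event
  events <- if (length(toks) == 1L) {
    parse_one(toks, s = s)
  } else {
    dplyr::bind_rows(lapply(toks, parse_one, s = s))
  }
  if (multi && any(events$kind == "identical")) {
    mave_abort("mave_malformed_variant",
               sprintf("target-identical '=' cannot appear in a multi-event variant: '%s'", s))
  }
  if (any(events$start < 1L)) {
    mave_abort("mave_malformed_variant",
               sprintf("positions are 1-based; index 0 is invalid in '%s'", s))
  }
  if (prefix == "p" && any(events$start_offset != 0L | events$end_offset != 0L)) {
    mave_abort("mave_malformed_variant",
               sprintf("offset positions are not defined for protein variants: '%s'", s))
  }
  check_offsets(events, splice_context, s)
  if (nrow(events) > 1L) {
    if (anyDuplicated(events$start)) {
      # equal starts cannot co-occur without overlap under the supported kinds
      mave_abort("mave_malformed_variant",
                 sprintf("events share a start position in '%s'", s))
    }
    if (is.unsorted(events$start)) {
      mave_abort("mave_malformed_variant",
                 sprintf("events must be in ascending position order in '%s'", s))
    }
    covered <- lapply(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      if (ev$kind %in% c("insertion", "identical")) integer(0) else ev$start:ev$end
    })
    all_pos <- unlist(covered)
    if (anyDuplicated(all_pos)) {
      mave_abort("mave_malformed_variant",
                 sprintf("events cover overlapping positions in '%s'", s))
    }
  }
  new_variant(prefix, events, s)
}

format_event <- function(ev, prefix) {
  pos <- function(idx, off, ref) {
    o <- if (off == 0L) "" else sprintf("%+d", off)
    if (prefix == "p") paste0(ref, idx) else paste0(idx, o)
  }
  p1 <- pos(ev$start, ev$start_offset, ev$start_ref)
  p2 <- pos(ev$end, ev$end_offset, ev$end_ref)
  range <- if (ev$end == ev$start && ev$end_offset == ev$start_offset) {
    p1
  } else {
    paste0(p1, "_", p2)
  }
  switch(ev$kind,
    substitution = if (prefix == "p") paste0(ev$start_ref, ev$start, ev$alt)
                   else paste0(p1, ev$ref, ">", ev$alt),
    deletion = paste0(range, "del"),
    duplication = paste0(range, "dup"),
    insertion = paste0(p1, "_", p2, "ins", ev$alt),
    delins = paste0(range, "delins", ev$alt),
    identical = "=",
    mave_abort("mave_invalid_variant", sprintf("unknown event kind '%s'", ev$kind))
  )
}

#' Format a variant object as its canonical MAVE-HGVS string
#'
#' Deterministic inverse of [parse_variant()]: the canonical serialization of
#' a `mave_variant`. `parse_variant(format_variant(v))` reproduces `v`
#' event for event.
#'
#' @param v A `mave_variant`.
#' @return A single character string.
#' @examples
#' format_variant(parse_variant("c.[1A>G;5del]"))
#' @export
format_variant <- function(v) {
  if (!inherits(v, "mave_variant")) {
    mave_abort("mave_invalid_variant", "not a mave_variant object")
  }
  validate_variant_invariants(v)
  parts <- vapply(seq_len(nrow(v$events)),
                  function(i) format_event(v$events[i, ], v$prefix), character(1))
  body <- if (length(parts) > 1L) paste0("[", paste(parts, collapse = ";"), "]") else parts
  paste0(v$prefix, ".", body)
}

validate_variant_invariants <- function(v) {
  ev <- v$events
  if (nrow(ev) < 1L) mave_abort("mave_invalid_variant", "variant has no events")
  if (!v$prefix %in% c("g", "c", "n", "p")) {
    mave_abort("mave_invalid_variant", sprintf("invalid prefix '%s'", v$prefix))
  }
  if (any(ev$start < 1L) || any(ev$end < ev$start)) {
    mave_abort("mave_invalid_variant", "positions must satisfy 1 <= start <= end")
  }
  sub <- ev$kind == "substitution"
  if (v$prefix == "p") {
    if (any(sub & (is.na(ev$start_ref) | is.na(ev$alt) | ev$start_ref == ev$alt))) {
      mave_abort("mave_invalid_variant", "protein substitution needs distinct ref and alt residues")
    }
    tok_ok <- function(x) {
      vapply(x, function(t) {
        if (is.na(t)) return(TRUE)
        nchar(t) %% 3 == 0 && all(split_aa3(t) %in% aa3_codes)
      }, logical(1))
    }
    if (!all(tok_ok(ev$start_ref)) || !all(tok_ok(ev$end_ref)) || !all(tok_ok(ev$alt))) {
      mave_abort("mave_invalid_variant", "protein tokens must be three-letter amino-acid codes")
    }
  } else {
    nt_ok <- function(x) all(is.na(x) | grepl("^[ACGT]+$", x))
    if (!nt_ok(ev$ref) || !nt_ok(ev$alt)) {
      mave_abort("mave_invalid_variant", "nucleotide tokens must be uppercase A/C/G/T")
    }
    if (any(sub & (is.na(ev$ref) | is.na(ev$alt) | ev$ref == ev$alt))) {
      mave_abort("mave_invalid_variant", "substitution needs distinct single ref and alt bases")
    }
  }
  ins <- ev$kind == "insertion"
  if (any(ins & is.na(ev$alt))) {
    mave_abort("mave_invalid_variant", "insertion needs inserted residues")
  }
  invisible(v)
}

#' Reference positions covered by a variant
#'
#' The union of closed position ranges `[start, end]` over all events.
#' Insertions (which sit between two reference positions) and the
#' target-identical event contribute no positions.
#'
#' @param v A `mave_variant` with all offsets zero.
#' @return An integer vector of 1-based target positions (possibly empty).
#' @examples
#' covered_positions(parse_variant("c.5_7del"))  # 5 6 7
#' covered_positions(parse_variant("c.5_6insTTT"))  # integer(0)
#' @export
covered_positions <- function(v) {
  stopifnot(inherits(v, "mave_variant"))
  if (any(v$events$start_offset != 0L | v$events$end_offset != 0L)) {
    mave_abort("mave_offset_not_allowed",
               "covered positions are undefined for offset (intronic) positions")
  }
  keep <- !v$events$kind %in% c("insertion", "identical")
  if (!any(keep)) return(integer(0))
  sort(unique(unlist(lapply(which(keep), function(i) {
    v$events$start[i]:v$events$end[i]
  }))))
}
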