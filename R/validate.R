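# Target-consistency validation of parsed variants.
#
# A variant is consistent with its target when every event sits inside the
# target, every stated reference residue matches the target residue at that
# position, and insertion flanks fall within bounds. All problems come back
# as findings in a report; nothing raises mid-check, so a single report can
# aggregate every event of a multi-event variant.

residues_at <- function(residues, idx) residues[idx]

validate_event_against <- function(ev, residues, is_protein, L) {
  f <- no_findings()
  if (ev$kind == "identical") return(f)
  if (ev$start_offset != 0L || ev$end_offset != 0L) {
    # intronic bases cannot be checked without a genome; format-only pass
    return(finding("FORMAT_ONLY",
                   "offset (intronic) position validated for format only",
                   severity = "info", locus = ev$start))
  }
  if (ev$kind == "insertion") {
    if (ev$start < 1L || ev$end > L) {
      return(finding("OUT_OF_BOUNDS",
                     sprintf("insertion flanks %d_%d outside target of length %d",
                             ev$start, ev$end, L), locus = ev$start))
    }
  } else if (ev$end > L) {
    return(finding("OUT_OF_BOUNDS",
                   sprintf("position %d outside target of length %d", ev$end, L),
                   locus = ev$end))
  }
  check_ref <- function(pos, stated) {
    actual <- residues[pos]
    if (!is.na(stated) && stated != actual) {
      finding("REF_MISMATCH",
              sprintf("stated reference '%s' at position %d but target has '%s'",
                      stated, pos, actual), locus = pos)
    } else {
      no_findings()
    }
  }
  if (is_protein) {
    f <- dplyr::bind_rows(
      check_ref(ev$start, ev$start_ref),
      if (ev$end != ev$start || ev$kind == "insertion") {
        check_ref(ev$end, ev$end_ref)
      } else {
        no_findings()
      }
    )
  } else if (ev$kind == "substitution") {
    f <- check_ref(ev$start, ev$ref)
  }
  f
}

#' Validate a variant against a target sequence
#'
#' Checks that a parsed variant is consistent with the target it claims to
#' describe: prefix/target-kind compatibility (`p.` needs a protein sequence,
#' supplied directly or by translating a coding nucleotide target; `g.`, `c.`
#' and `n.` need a nucleotide sequence), every covered position within bounds,
#' every stated reference residue equal to the target residue, and insertion
#' flanks inside the target. Multi-event variants are validated event by
#' event into one aggregated report.
#'
#' @param v A `mave_variant` (offset positions get a format-only info
#'   finding, since intronic bases cannot be checked against a contiguous
#'   target).
#' @param t A `mave_target`.
#' @return A [`mave_report`][new_report] whose findings carry codes such as
#'   `REF_MISMATCH`, `OUT_OF_BOUNDS`, `PREFIX_KIND_MISMATCH`.
#' @examples
#' t <- target_sequence("ATGTGGTGC", "nucleotide", category = "coding")
#' validate_against_target(parse_variant("c.1A>G"), t)$valid
#' validate_against_target(parse_variant("p.Trp2Cys"), t)$valid
#' @export
validate_against_target <- function(v, t) {
  stopifnot(inherits(v, "mave_variant"), inherits(t, "mave_target"))
  ctx <- target_validation_context(t, protein_level = v$prefix == "p")
  validate_variant_core(v, ctx)
}

# Precomputed residue context so table-level validation translates a coding
# target once, not once per row.
target_validation_context <- function(t, protein_level) {
  if (protein_level) {
    ok <- t$kind == "protein" ||
      (t$kind == "nucleotide" && t$category == "coding" &&
         nchar(t$sequence) %% 3L == 0L)
    if (!ok) {
      return(list(mismatch = finding("PREFIX_KIND_MISMATCH",
        "p. variants require a protein target or a coding nucleotide target of length divisible by three")))
    }
    residues <- target_protein_residues(t)
    warn <- if (any(residues[-length(residues)] == "Ter")) {
      finding("INTERNAL_STOP", "translated target contains an internal stop codon",
              severity = "warning")
    } else {
      no_findings()
    }
    list(residues = residues, is_protein = TRUE, warn = warn,
         L = length(residues))
  } else {
    if (t$kind != "nucleotide") {
      return(list(mismatch = finding("PREFIX_KIND_MISMATCH",
        "g./c./n. variants require a nucleotide target")))
    }
    residues <- strsplit(t$sequence, "")[[1]]
    list(residues = residues, is_protein = FALSE, warn = no_findings(),
         L = length(residues))
  }
}

validate_variant_core <- function(v, ctx) {
  new_report(variant_findings(v, ctx))
}

# findings tibble without the report wrapper; the table validator's hot path
variant_findings <- function(v, ctx) {
  if (!is.null(ctx$mismatch)) return(ctx$mismatch)
  n_ev <- nrow(v$events)
  if (n_ev == 1L) {
    f <- validate_event_against(v$events, ctx$residues, ctx$is_protein, ctx$L)
    if (nrow(ctx$warn)) f <- dplyr::bind_rows(ctx$warn, f)
    return(f)
  }
  per_event <- lapply(seq_len(n_ev), function(i) {
    validate_event_against(v$events[i, ], ctx$residues, ctx$is_protein, ctx$L)
  })
  dplyr::bind_rows(c(list(ctx$warn), per_event))
}

# --- accession-anchored validation -------------------------------------------

#' Sequence lookups for accession-anchored variants
#'
#' Saturation genome editing and similar assays anchor variants to a
#' transcript or genome accession rather than a local target sequence.
#' Validation then needs a sequence lookup: a function
#' `f(accession, start, end)` returning the reference residue string for the
#' 1-based closed interval, or `NULL` when the accession is unknown. Two
#' fixture-friendly constructors are provided: an in-memory named list and a
#' local FASTA file. Both are deterministic and need no network access.
#'
#' @param sequences Named character vector or list mapping accession to
#'   full reference sequence.
#' @return A lookup function usable with [validate_against_accession()].
#' @examples
#' lk <- memory_lookup(c(FIX01 = "CCCCAGGG"))
#' lk("FIX01", 5, 5)  # "A"
#' @export
memory_lookup <- function(sequences) {
  sequences <- as.list(sequences)
  function(accession, start, end) {
    seq <- sequences[[accession]]
    if (is.null(seq)) return(NULL)
    if (start < 1L || end > nchar(seq)) return(NA_character_)
    substr(seq, start, end)
  }
}

#' @rdname memory_lookup
#' @param path Path to a FASTA file whose record ids are the accessions.
#' @export
fasta_lookup <- function(path) {
  targets <- read_targets_fasta(path)
  memory_lookup(lapply(targets, function(t) t$sequence))
}

#' Validate a variant against an accession via a sequence lookup
#'
#' Runs the same bounds and reference checks as
#' [validate_against_target()], fetching reference slices through a
#' pluggable lookup instead of a local sequence. An accession the lookup
#' cannot resolve yields an `UNRESOLVED_ACCESSION` error finding rather than
#' an exception.
#'
#' @param v A `mave_variant` (nucleotide prefixes only; protein accessions
#'   are looked up as protein one-letter sequences).
#' @param accession Accession string passed to the lookup.
#' @param lookup A function as returned by [memory_lookup()] or
#'   [fasta_lookup()].
#' @return A `mave_report`.
#' @examples
#' lk <- memory_lookup(c(FIX01 = "CCCCAGGG"))
#' validate_against_accession(parse_variant("g.5A>T"), "FIX01", lk)$valid
#' @export
validate_against_accession <- function(v, accession, lookup) {
  stopifnot(inherits(v, "mave_variant"), is.function(lookup))
  probe <- lookup(accession, 1L, 1L)
  if (is.null(probe)) {
    return(new_report(finding("UNRESOLVED_ACCESSION",
      sprintf("accession '%s' could not be resolved", accession))))
  }
  is_protein <- v$prefix == "p"
  per_event <- lapply(seq_len(nrow(v$events)), function(i) {
    ev <- v$events[i, ]
    if (ev$kind == "identical") return(no_findings())
    if (ev$start_offset != 0L || ev$end_offset != 0L) {
      return(finding("FORMAT_ONLY",
                     "offset (intronic) position validated for format only",
                     severity = "info", locus = ev$start))
    }
    span <- lookup(accession, ev$start, ev$end)
    if (is.null(span) || is.na(span)) {
      return(finding("OUT_OF_BOUNDS",
                     sprintf("interval %d_%d not available for accession '%s'",
                             ev$start, ev$end, accession), locus = ev$end))
    }
    residues <- if (is_protein) {
      unname(aa1_to_aa3[strsplit(span, "")[[1]]])
    } else {
      strsplit(span, "")[[1]]
    }
    # re-index the fetched slice so positions are local to the event span
    ev_local <- ev
    ev_local$end <- ev$end - ev$start + 1L
    ev_local$start <- 1L
    f <- validate_event_against(ev_local, residues, is_protein,
                                length(residues))
    if (nrow(f)) f$locus <- f$locus + ev$start - 1L
    f
  })
  new_report(dplyr::bind_rows(per_event))
}
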