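# Target sequences: constructors, FASTA input, and translation.

#' Construct a target sequence
#'
#' A target sequence is the nucleotide or protein sequence a score set's
#' variants are expressed and validated against. Nucleotide targets use the
#' uppercase A/C/G/T alphabet; protein targets use the twenty one-letter
#' amino-acid codes plus an optional terminal `*` stop.
#'
#' @param sequence Residue string.
#' @param kind `"nucleotide"` or `"protein"`.
#' @param label Free-text label (FASTA record id when read from file).
#' @param category One of `"coding"`, `"non_coding"`, `"regulatory"`,
#'   `"other"`. Protein-level validation of a nucleotide target requires
#'   `category = "coding"` and a length divisible by three.
#' @return A `mave_target` object.
#' @examples
#' target_sequence("ATGTGGTGC", kind = "nucleotide", category = "coding")
#' @export
target_sequence <- function(sequence, kind = c("nucleotide", "protein"),
                            label = "target",
                            category = c("coding", "non_coding",
                                         "regulatory", "other")) {
  kind <- match.arg(kind)
  category <- match.arg(category)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    mave_abort("mave_bad_target", "target sequence must be a single nonempty string")
  }
  if (kind == "nucleotide") {
    if (!grepl("^[ACGT]+$", sequence)) {
      mave_abort("mave_bad_target",
                 "nucleotide target must contain only uppercase A/C/G/T")
    }
  } else {
    if (!grepl("^[ARNDCQEGHILKMFPSTWYV]+\\*?$", sequence)) {
      mave_abort("mave_bad_target",
                 "protein target must use one-letter amino-acid codes with at most a terminal '*'")
    }
  }
  structure(
    list(label = label, kind = kind, sequence = sequence, category = category),
    class = "mave_target"
  )
}

#' @export
print.mave_target <- function(x, ...) {
  cat(sprintf("<mave_target> %s: %s %s, %d residues\n",
              x$label, x$category, x$kind, nchar(x$sequence)))
  invisible(x)
}

target_length <- function(t) nchar(t$sequence)

#' Read target sequences from a FASTA file
#'
#' Reads single- or multi-record FASTA; each record id becomes the target
#' label. Alphabet decides the kind: records containing only A/C/G/T are
#' nucleotide, anything else protein.
#'
#' @param path Path to a FASTA file.
#' @param category Target category applied to every record (see
#'   [target_sequence()]).
#' @return A list of `mave_target` objects, named by label.
#' @export
read_targets_fasta <- function(path, category = "coding") {
  if (!file.exists(path)) {
    mave_abort("mave_io_error", sprintf("FASTA file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1] != 1L) {
    mave_abort("mave_io_error", sprintf("'%s' is not FASTA (no leading '>')", path))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- lapply(seq_along(starts), function(i) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    seq <- if (starts[i] < ends[i]) {
      toupper(paste(lines[(starts[i] + 1L):ends[i]], collapse = ""))
    } else {
      ""
    }
    if (!nzchar(seq)) {
      mave_abort("mave_io_error", sprintf("empty FASTA record '%s' in '%s'", id, path))
    }
    kind <- if (grepl("^[ACGT]+$", seq)) "nucleotide" else "protein"
    target_sequence(seq, kind = kind, label = id, category = category)
  })
  names(out) <- vapply(out, function(t) t$label, character(1))
  out
}

#' Write a target sequence to FASTA
#'
#' @param t A `mave_target`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(t, path, width = 60L) {
  stopifnot(inherits(t, "mave_target"))
  n <- nchar(t$sequence)
  chunks <- substring(t$sequence, seq(1L, n, by = width),
                      pmin(seq(1L, n, by = width) + width - 1L, n))
  writeLines(c(paste0(">", t$label), chunks), path)
  invisible(path)
}

#' Translate a coding DNA sequence
#'
#' Standard genetic code (NCBI table 1) translation of a coding nucleotide
#' sequence into a one-letter protein string; stop codons translate to `*`.
#' Internal stops are permitted here and flagged downstream by the target
#' validators.
#'
#' @param seq Nucleotide string, length divisible by three, alphabet ACGT.
#' @return One-letter protein string (possibly containing `*`).
#' @examples
#' translate_dna("ATGTGGTGC")  # "MWC"
#' @export
translate_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !grepl("^[ACGT]+$", seq)) {
    mave_abort("mave_bad_alphabet", "sequence must contain only uppercase A/C/G/T")
  }
  if (nchar(seq) %% 3L != 0L) {
    mave_abort("mave_length_not_multiple_of_three",
               sprintf("length %d is not divisible by three", nchar(seq)))
  }
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "error"))
}

#' Protein residues of a target, as three-letter codes
#'
#' For a protein target, converts its one-letter sequence; for a coding
#' nucleotide target, translates first. Returns a character vector with one
#' three-letter code per residue (`Ter` for `*`).
#'
#' @param t A `mave_target`.
#' @return Character vector of three-letter codes.
#' @keywords internal
target_protein_residues <- function(t) {
  pro <- if (t$kind == "protein") {
    t$sequence
  } else {
    if (t$category != "coding") {
      mave_abort("mave_bad_target",
                 "protein-level validation requires a coding nucleotide target")
    }
    if (nchar(t$sequence) %% 3L != 0L) {
      mave_abort("mave_length_not_multiple_of_three",
                 "coding target length must be divisible by three for protein-level validation")
    }
    translate_dna(t$sequence)
  }
  unname(aa1_to_aa3[strsplit(pro, "")[[1]]])
}
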