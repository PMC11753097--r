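# Automatic score-set summaries: the score histogram and the variant effect
# heatmap matrix, plus landing-page summary statistics.

score_values <- function(t) {
  if (!"score" %in% names(t)) {
    mave_abort("mave_bad_table", "table has no score column")
  }
  cell_as_numeric(t$score)
}

#' Score histogram
#'
#' Bins the non-missing scores of a score table. The default binning is the
#' Freedman-Diaconis rule (bin width `2 * IQR / n^(1/3)`), which is robust
#' for the bimodal score distributions typical of multiplexed assays of
#' variant effect; when the interquartile range is zero it falls back to 30
#' equal-width bins. Counts are conserved:
#' `sum(counts) + n_missing == nrow(t)`.
#'
#' @param t A validated score table.
#' @param rule `"fd"` (Freedman-Diaconis, the default), a single integer
#'   number of equal-width bins, or a numeric vector of explicit bin edges.
#' @return A `mave_histogram`: list with `bin_edges` (length B+1, strictly
#'   increasing), `counts` (length B), `n_missing` and `n` (source rows).
#' @examples
#' t <- tibble::tibble(hgvs_pro = c("p.Met1Ala", "p.Trp2Cys"), score = c(0, 1))
#' score_histogram(t, rule = 2)$counts
#' @export
score_histogram <- function(t, rule = "fd") {
  s <- score_values(t)
  x <- s[!is.na(s)]
  n_missing <- sum(is.na(s))
  if (!length(x)) {
    mave_abort("mave_empty_scores", "all scores are missing; nothing to bin")
  }
  edges <- if (is.numeric(rule) && length(rule) > 1L) {
    if (is.unsorted(rule, strictly = TRUE)) {
      mave_abort("mave_bad_spec", "explicit bin edges must be strictly increasing")
    }
    rule
  } else {
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      lo <- lo - 0.5; hi <- hi + 0.5
    }
    nbins <- if (is.numeric(rule)) {
      as.integer(rule)
    } else if (identical(rule, "fd")) {
      iqr <- stats::IQR(x)
      if (iqr == 0) {
        30L
      } else {
        max(1L, as.integer(ceiling((hi - lo) / (2 * iqr / length(x)^(1 / 3)))))
      }
    } else {
      mave_abort("mave_bad_spec", sprintf("unknown binning rule '%s'", rule))
    }
    seq(lo, hi, length.out = nbins + 1L)
  }
  bins <- cut(x, edges, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(tabulate(bins, nbins = length(edges) - 1L))
  n_out <- sum(is.na(bins))  # only possible with explicit edges
  structure(
    list(bin_edges = as.numeric(edges), counts = counts,
         n_missing = n_missing + n_out, n = length(s)),
    class = "mave_histogram"
  )
}

#' @export
print.mave_histogram <- function(x, ...) {
  cat(sprintf("<mave_histogram> %d bins over [%g, %g], %d scored, %d missing\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts), x$n_missing))
  invisible(x)
}

#' Tidy a score histogram
#'
#' @param x A `mave_histogram`.
#' @param ... Unused.
#' @return A tibble with one row per bin: `bin_left`, `bin_right`, `count`.
#' @export
tidy.mave_histogram <- function(x, ...) {
  tibble::tibble(
    bin_left = utils::head(x$bin_edges, -1L),
    bin_right = x$bin_edges[-1L],
    count = x$counts
  )
}

effect_rows <- function(level) {
  if (level == "protein") c(aa3_codes, "del") else c("A", "C", "G", "T", "del")
}

#' Variant effect matrix (heatmap data)
#'
#' Builds the per-position, per-substitution matrix behind a variant effect
#' heatmap. Coding targets are summarized at the protein level from the
#' `hgvs_pro` column (22 rows: the twenty amino acids, `Ter`, and a `del`
#' row); non-coding targets at the nucleotide level from `hgvs_nt` (5 rows:
#' A, C, G, T, `del`). One cell is filled per single-event substitution or
#' single-position deletion with a non-missing score. Everything without a
#' natural single cell — multi-event variants, insertions, multi-position
#' deletions, duplications, target-identical rows, and rows lacking a
#' variant at the requested level — is tallied in `n_excluded_multi`;
#' placeable variants with a missing score are tallied in `n_missing_score`.
#'
#' @param t A score table validated against `target`.
#' @param target A `mave_target`.
#' @param level `"protein"`, `"nucleotide"`, or `NULL` to choose from the
#'   target (protein level for protein targets and coding nucleotide
#'   targets, nucleotide level otherwise).
#' @return A `mave_effect_matrix`: list with `matrix` (rows x positions,
#'   `NA` where unfilled), `row_labels`, `positions`, `wt_mask` (row index
#'   of the target residue per position), `n_excluded_multi`,
#'   `n_missing_score`, `level`.
#' @export
effect_matrix <- function(t, target, level = NULL) {
  stopifnot(inherits(target, "mave_target"))
  if (is.null(level)) {
    level <- if (target$kind == "protein" ||
                 (target$kind == "nucleotide" && target$category == "coding" &&
                    nchar(target$sequence) %% 3L == 0L)) "protein" else "nucleotide"
  }
  column <- if (level == "protein") "hgvs_pro" else "hgvs_nt"
  if (level == "protein") {
    if (target$kind == "nucleotide" && target$category != "coding") {
      mave_abort("mave_alphabet_mismatch",
                 "protein-level matrix requested for a non-coding target")
    }
    wt_residues <- target_protein_residues(target)
  } else {
    if (target$kind != "nucleotide") {
      mave_abort("mave_alphabet_mismatch",
                 "nucleotide-level matrix requires a nucleotide target")
    }
    wt_residues <- strsplit(target$sequence, "")[[1]]
  }
  if (nrow(t) > 0 && !column %in% names(t)) {
    mave_abort("mave_alphabet_mismatch",
               sprintf("%s-level matrix needs column '%s'", level, column))
  }
  rows <- effect_rows(level)
  L <- length(wt_residues)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = L,
                dimnames = list(rows, as.character(seq_len(L))))
  scores <- if (nrow(t)) score_values(t) else numeric(0)
  n_excluded <- 0L
  n_missing_score <- 0L
  for (i in seq_len(nrow(t))) {
    raw <- if (column %in% names(t)) cell_chr(t[[column]][i]) else ""
    if (raw %in% c("", "NA")) {
      n_excluded <- n_excluded + 1L
      next
    }
    v <- tryCatch(parse_variant(raw, splice_context = FALSE),
                  mave_error = function(e) NULL)
    placeable <- !is.null(v) && nrow(v$events) == 1L &&
      (v$events$kind == "substitution" ||
         (v$events$kind == "deletion" && v$events$end == v$events$start)) &&
      v$events$end <= L
    if (!placeable) {
      n_excluded <- n_excluded + 1L
      next
    }
    if (is.na(scores[i])) {
      n_missing_score <- n_missing_score + 1L
      next
    }
    row_lab <- if (v$events$kind == "deletion") "del" else v$events$alt
    mat[row_lab, v$events$start] <- scores[i]
  }
  structure(
    list(matrix = mat, row_labels = rows, positions = seq_len(L),
         wt_mask = match(wt_residues, rows),
         n_excluded_multi = n_excluded, n_missing_score = n_missing_score,
         level = level),
    class = "mave_effect_matrix"
  )
}

#' @export
print.mave_effect_matrix <- function(x, ...) {
  cat(sprintf("<mave_effect_matrix> %s level, %d x %d, %d filled, %d excluded, %d missing-score\n",
              x$level, nrow(x$matrix), ncol(x$matrix),
              sum(!is.na(x$matrix)), x$n_excluded_multi, x$n_missing_score))
  invisible(x)
}

#' Tidy a variant effect matrix
#'
#' @param x A `mave_effect_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `residue`, `score`, `is_wt`.
#' @export
tidy.mave_effect_matrix <- function(x, ...) {
  tidyr::expand_grid(position = x$positions, residue = x$row_labels) |>
    dplyr::mutate(
      score = as.vector(x$matrix[cbind(match(.data$residue, x$row_labels),
                                       .data$position)]),
      is_wt = x$wt_mask[.data$position] == match(.data$residue, x$row_labels)
    )
}

#' Summary statistics for a score table
#'
#' Landing-page style metadata: row and scored-variant counts and the
#' range, mean, and median of the non-missing scores.
#'
#' @param t A validated score table.
#' @return A one-row tibble with columns `n_variants`, `n_scored`, `min`,
#'   `max`, `mean`, `median`.
#' @export
summary_stats <- function(t) {
  s <- score_values(t)
  x <- s[!is.na(s)]
  tibble::tibble(
    n_variants = length(s), n_scored = length(x),
    min = if (length(x)) min(x) else NA_real_,
    max = if (length(x)) max(x) else NA_real_,
    mean = if (length(x)) mean(x) else NA_real_,
    median = if (length(x)) stats::median(x) else NA_real_
  )
}

# --- plotting ----------------------------------------------------------------

#' Plot a score histogram
#'
#' @param object A `mave_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mave_histogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$bin_left, xmax = .data$bin_right,
                                  ymin = 0, ymax = .data$count)) +
    ggplot2::geom_rect(fill = "grey35", colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = "score", y = "variants") +
    ggplot2::theme_minimal()
}

#' Plot a variant effect heatmap
#'
#' @param object A `mave_effect_matrix`.
#' @param ... Unused.
#' @return A ggplot object; wild-type cells are marked with a dot.
#' @export
autoplot.mave_effect_matrix <- function(object, ...) {
  d <- tidy(object)
  d$residue <- factor(d$residue, levels = rev(object$row_labels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$residue)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score), colour = "grey85",
                       linewidth = 0.1) +
    ggplot2::geom_point(data = dplyr::filter(d, .data$is_wt), size = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac",
                                  midpoint = stats::median(d$score, na.rm = TRUE),
                                  na.value = "white") +
    ggplot2::labs(x = "target position", y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

histogram_to_list <- function(h) {
  list(bin_edges = h$bin_edges, counts = h$counts, n_missing = h$n_missing,
       n = h$n)
}

effect_matrix_to_list <- function(m) {
  cells <- m$matrix
  cells_list <- lapply(seq_len(ncol(cells)), function(j) {
    col <- cells[, j]
    col[is.na(col)] <- NA
    as.list(col)
  })
  list(level = m$level, row_labels = m$row_labels,
       positions = m$positions, wt_mask = m$wt_mask,
       n_excluded_multi = m$n_excluded_multi,
       n_missing_score = m$n_missing_score, cells = cells_list)
}
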