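# Bulk-release archive: one JSON file with all structured metadata for every
# experiment set, experiment and score set, plus a directory of CSV score and
# count tables, one per score set. Layout:
#
#   dest/
#     metadata.json
#     csv/<urn-slug>.scores.csv
#     csv/<urn-slug>.counts.csv   (only for score sets with counts)
#
# Records are sorted by URN and JSON keys are emitted in a fixed order, so
# writing the same collection twice is bit-identical.

target_to_json <- function(target) {
  if (inherits(target, "mave_target")) {
    list(type = "sequence", label = target$label, kind = target$kind,
         category = target$category, sequence = target$sequence)
  } else {
    list(type = "accession", accession = as.character(target))
  }
}

target_from_json <- function(x) {
  if (identical(x$type, "accession")) return(x$accession)
  target_sequence(x$sequence, kind = x$kind, label = x$label,
                  category = x$category)
}

references_to_json <- function(refs) {
  lapply(seq_len(nrow(refs)), function(i) {
    list(identifier = refs$identifier[i], source = refs$source[i],
         is_primary = refs$is_primary[i],
         journal_or_server = refs$journal_or_server[i],
         authors = as.list(refs$authors[[i]]), year = refs$year[i])
  })
}

references_from_json <- function(x) {
  if (!length(x)) return(empty_references())
  dplyr::bind_rows(lapply(x, function(r) {
    reference(r$identifier, r$source, isTRUE(r$is_primary),
              r$journal_or_server %||% NA_character_,
              unlist(r$authors) %||% character(0),
              r$year %||% NA_integer_)
  }))
}

#' Write a record collection as a bulk-release archive
#'
#' Serializes the collection to a single `metadata.json` (all experiment
#' set, experiment and score set metadata) plus a `csv/` directory holding
#' one scores CSV per score set and one counts CSV per score set that has
#' counts. Filenames are derived from URNs with `:` and `#` replaced by `-`.
#' The collection must pass [validate_hierarchy()] without errors.
#'
#' @param collection A `mave_collection`.
#' @param dest Destination directory (created if needed).
#' @return An archive manifest: a list with `metadata_path`, `table_paths`
#'   (named by score-set URN, each with `scores` and optional `counts`) and
#'   `version_tag`.
#' @export
write_archive <- function(collection, dest) {
  stopifnot(inherits(collection, "mave_collection"))
  hier <- validate_hierarchy(collection)
  if (!hier$valid) {
    mave_abort("mave_invalid_collection",
               "collection fails hierarchy validation; refusing to write archive")
  }
  dir.create(file.path(dest, "csv"), recursive = TRUE, showWarnings = FALSE)

  es <- dplyr::arrange(collection$experiment_sets, .data$urn)
  ex <- dplyr::arrange(collection$experiments, .data$urn)
  ss_order <- sort(names(collection$score_sets))
  score_sets_json <- lapply(ss_order, function(u) {
    ss <- collection$score_sets[[u]]
    list(urn = ss$urn, experiment_urn = ss$experiment_urn, title = ss$title,
         short_description = ss$short_description, abstract = ss$abstract,
         methods = ss$methods, target = target_to_json(ss$target),
         references = references_to_json(ss$references),
         meta_analysis_sources = as.list(ss$meta_analysis_sources),
         has_counts = !is.null(ss$counts))
  })
  doc <- list(
    format = "mavekit-archive",
    schema_version = 1L,
    version_tag = collection$version_tag,
    experiment_sets = lapply(seq_len(nrow(es)), function(i) {
      list(urn = es$urn[i], title = es$title[i])
    }),
    experiments = lapply(seq_len(nrow(ex)), function(i) {
      list(urn = ex$urn[i], experiment_set_urn = ex$experiment_set_urn[i],
           title = ex$title[i])
    }),
    score_sets = score_sets_json
  )
  meta_path <- file.path(dest, "metadata.json")
  json <- jsonlite::toJSON(doc, pretty = TRUE, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  writeLines(json, meta_path, useBytes = TRUE)

  table_paths <- list()
  for (u in ss_order) {
    ss <- collection$score_sets[[u]]
    slug <- urn_slug(u)
    spath <- file.path(dest, "csv", paste0(slug, ".scores.csv"))
    write_score_csv(ss$scores, spath)
    entry <- list(scores = spath)
    if (!is.null(ss$counts)) {
      cpath <- file.path(dest, "csv", paste0(slug, ".counts.csv"))
      write_score_csv(ss$counts, cpath)
      entry$counts <- cpath
    }
    table_paths[[u]] <- entry
  }
  structure(list(metadata_path = meta_path, table_paths = table_paths,
                 version_tag = collection$version_tag),
            class = "mave_manifest")
}

#' Read a bulk-release archive back into a record collection
#'
#' Inverse of [write_archive()]: `read_archive(write_archive(c))` reproduces
#' `c` up to canonical formatting (see [canonicalize_collection()]). Missing
#' table files become `MISSING_TABLE` findings in the attached report, not
#' crashes; an unreadable or absent `metadata.json` raises a
#' `mave_corrupt_archive` condition.
#'
#' @param src Archive directory.
#' @return A `mave_collection` with a `mave_report` in its `report`
#'   attribute describing per-score-set table problems.
#' @export
read_archive <- function(src) {
  meta_path <- file.path(src, "metadata.json")
  if (!file.exists(meta_path)) {
    mave_abort("mave_corrupt_archive",
               sprintf("no metadata.json in '%s'", src))
  }
  doc <- tryCatch(jsonlite::fromJSON(meta_path, simplifyVector = FALSE),
                  error = function(e) {
    mave_abort("mave_corrupt_archive",
               sprintf("unreadable metadata.json: %s", conditionMessage(e)))
  })
  if (!identical(doc$format, "mavekit-archive")) {
    mave_abort("mave_corrupt_archive", "metadata.json is not a mavekit archive")
  }
  out_findings <- list()
  es <- if (length(doc$experiment_sets)) {
    dplyr::bind_rows(lapply(doc$experiment_sets, function(x) {
      tibble::tibble(urn = x$urn, title = x$title)
    }))
  } else {
    tibble::tibble(urn = character(0), title = character(0))
  }
  ex <- if (length(doc$experiments)) {
    dplyr::bind_rows(lapply(doc$experiments, function(x) {
      tibble::tibble(urn = x$urn, experiment_set_urn = x$experiment_set_urn,
                     title = x$title)
    }))
  } else {
    tibble::tibble(urn = character(0), experiment_set_urn = character(0),
                   title = character(0))
  }
  score_sets <- list()
  for (x in doc$score_sets) {
    slug <- urn_slug(x$urn)
    spath <- file.path(src, "csv", paste0(slug, ".scores.csv"))
    scores <- if (file.exists(spath)) {
      read_score_csv(spath)
    } else {
      out_findings[[length(out_findings) + 1L]] <- finding(
        "MISSING_TABLE", sprintf("scores CSV for %s is missing", x$urn))
      tibble::tibble()
    }
    counts <- NULL
    if (isTRUE(x$has_counts)) {
      cpath <- file.path(src, "csv", paste0(slug, ".counts.csv"))
      if (file.exists(cpath)) {
        counts <- read_score_csv(cpath)
      } else {
        out_findings[[length(out_findings) + 1L]] <- finding(
          "MISSING_TABLE", sprintf("counts CSV for %s is missing", x$urn))
      }
    }
    score_sets[[x$urn]] <- score_set_record(
      urn = x$urn, experiment_urn = x$experiment_urn, scores = scores,
      target = target_from_json(x$target), counts = counts,
      title = x$title, short_description = x$short_description,
      abstract = x$abstract, methods = x$methods,
      references = references_from_json(x$references),
      meta_analysis_sources = as.character(unlist(x$meta_analysis_sources))
    )
  }
  collection <- record_collection(es, ex, score_sets,
                                  version_tag = doc$version_tag)
  attr(collection, "report") <-
    new_report(dplyr::bind_rows(c(list(no_findings()), out_findings)))
  collection
}

#' Canonicalize a collection for comparison
#'
#' Normalizes a collection so that archive round-trips compare equal:
#' score sets sorted by URN, non-variant table columns coerced to numeric,
#' variant columns to character, and side-channel attributes dropped.
#'
#' @param collection A `mave_collection`.
#' @return A `mave_collection` in canonical form.
#' @export
canonicalize_collection <- function(collection) {
  canon_table <- function(t) {
    if (is.null(t)) return(NULL)
    t <- tibble::as_tibble(t)
    for (cn in names(t)) {
      if (cn %in% variant_column_names) {
        x <- cell_chr(t[[cn]])
        x[cell_is_missing(t[[cn]])] <- NA_character_
        t[[cn]] <- x
      } else {
        t[[cn]] <- cell_as_numeric(t[[cn]])
      }
    }
    t
  }
  score_sets <- collection$score_sets[sort(names(collection$score_sets))]
  score_sets <- lapply(score_sets, function(ss) {
    ss$scores <- canon_table(ss$scores)
    ss$counts <- canon_table(ss$counts)
    ss$meta_analysis_sources <- as.character(ss$meta_analysis_sources)
    ss
  })
  out <- record_collection(
    dplyr::arrange(collection$experiment_sets, .data$urn),
    dplyr::arrange(collection$experiments, .data$urn),
    score_sets, version_tag = collection$version_tag)
  attributes(out) <- attributes(out)[c("names", "class")]
  out
}

#' @export
print.mave_manifest <- function(x, ...) {
  n_counts <- sum(vapply(x$table_paths, function(p) !is.null(p$counts),
                         logical(1)))
  cat(sprintf("<mave_manifest> %s: %d score table(s), %d count table(s)\n",
              x$version_tag, length(x$table_paths), n_counts))
  invisible(x)
}
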