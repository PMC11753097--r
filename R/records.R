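# The hierarchical record model: experiment sets group experiments, which
# group score sets; meta-analysis score sets link to source score sets
# without modifying them.

#' Construct a bibliographic reference
#'
#' Records can cite published papers and preprints: PubMed entries, bioRxiv
#' and medRxiv preprints, and Crossref DOIs. One reference per record may be
#' primary (the publication describing the data); the rest are secondary.
#'
#' @param identifier Source-specific identifier (PMID, DOI, ...).
#' @param source One of `"pubmed"`, `"biorxiv"`, `"medrxiv"`,
#'   `"crossref_doi"`.
#' @param is_primary Is this the primary reference?
#' @param journal_or_server,authors,year Optional display metadata.
#' @return A one-row tibble.
#' @export
reference <- function(identifier, source = c("pubmed", "biorxiv", "medrxiv",
                                             "crossref_doi"),
                      is_primary = FALSE, journal_or_server = NA_character_,
                      authors = character(0), year = NA_integer_) {
  source <- match.arg(source)
  tibble::tibble(
    identifier = identifier, source = source, is_primary = is_primary,
    journal_or_server = journal_or_server,
    authors = list(authors), year = as.integer(year)
  )
}

empty_references <- function() reference(character(0))[0, ]

#' Construct a score set record
#'
#' A score set holds per-variant effect scores (and optionally counts)
#' against one target, plus free-text metadata and references. A
#' meta-analysis score set is a score set whose `meta_analysis_sources` is
#' nonempty: it represents scores derived by transforming or combining
#' existing score sets (imputation, cross-assay combination) while the
#' source tables stay untouched.
#'
#' @param urn Score-set-level URN string.
#' @param experiment_urn Parent experiment URN string.
#' @param scores Score table (tibble).
#' @param target A `mave_target`, or an accession string for
#'   accession-anchored score sets.
#' @param counts Optional count table.
#' @param title,short_description,abstract,methods Free-text metadata.
#' @param references Tibble of [reference()] rows.
#' @param meta_analysis_sources Character vector of source score-set URNs.
#' @return A `mave_score_set` object.
#' @export
score_set_record <- function(urn, experiment_urn, scores, target,
                             counts = NULL, title = "", short_description = "",
                             abstract = "", methods = "",
                             references = empty_references(),
                             meta_analysis_sources = character(0)) {
  structure(
    list(urn = urn, experiment_urn = experiment_urn,
         title = title, short_description = short_description,
         abstract = abstract, methods = methods, target = target,
         scores = tibble::as_tibble(scores),
         counts = if (is.null(counts)) NULL else tibble::as_tibble(counts),
         references = references,
         meta_analysis_sources = meta_analysis_sources),
    class = "mave_score_set"
  )
}

is_meta_analysis <- function(ss) length(ss$meta_analysis_sources) > 0L

#' Construct a record collection
#'
#' The full hierarchy of one dataset release: experiment sets, experiments
#' (each pointing at its experiment set), and score sets (each pointing at
#' its experiment, possibly carrying meta-analysis source edges).
#'
#' @param experiment_sets Tibble with columns `urn`, `title`.
#' @param experiments Tibble with columns `urn`, `experiment_set_urn`,
#'   `title`.
#' @param score_sets List of `mave_score_set` objects.
#' @param version_tag Free-text release tag (e.g. a date).
#' @return A `mave_collection`.
#' @export
record_collection <- function(experiment_sets = tibble::tibble(
                                urn = character(0), title = character(0)),
                              experiments = tibble::tibble(
                                urn = character(0),
                                experiment_set_urn = character(0),
                                title = character(0)),
                              score_sets = list(),
                              version_tag = "unreleased") {
  names(score_sets) <- vapply(score_sets, function(s) s$urn, character(1))
  structure(
    list(experiment_sets = tibble::as_tibble(experiment_sets),
         experiments = tibble::as_tibble(experiments),
         score_sets = score_sets, version_tag = version_tag),
    class = "mave_collection"
  )
}

#' @export
print.mave_collection <- function(x, ...) {
  n_meta <- sum(vapply(x$score_sets, is_meta_analysis, logical(1)))
  cat(sprintf(
    "<mave_collection> %d experiment set(s), %d experiment(s), %d score set(s) (%d meta-analysis)\n",
    nrow(x$experiment_sets), nrow(x$experiments), length(x$score_sets), n_meta))
  invisible(x)
}

# depth-first cycle detection over the meta-analysis edge list
meta_cycle_members <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  cyclic <- character(0)
  visit <- function(u) {
    color[u] <<- 1L
    for (w in adj[[u]]) {
      if (!w %in% nodes) next
      if (color[w] == 1L) cyclic <<- union(cyclic, c(u, w))
      else if (color[w] == 0L) visit(w)
    }
    color[u] <<- 2L
  }
  for (u in nodes) if (color[u] == 0L) visit(u)
  cyclic
}

#' Validate a record collection's hierarchy
#'
#' Checks the structural integrity of the record hierarchy: every experiment
#' belongs to a known experiment set and every score set to a known
#' experiment (no orphans); every child URN textually extends its parent URN;
#' meta-analysis source URNs resolve to score sets in the collection and the
#' meta-analysis edge graph is acyclic; no record carries more than one
#' primary reference. Advisory structure (an experiment carrying several
#' score sets, which may indicate several assays folded into one experiment;
#' meta-analyses spanning experiment sets) is reported at info severity only.
#'
#' @param collection A `mave_collection`.
#' @return A `mave_report` with codes `ORPHAN_RECORD`, `URN_MISMATCH`,
#'   `UNRESOLVED_SOURCE`, `CYCLE`, `MULTIPLE_PRIMARY_REFERENCES`, and
#'   info-level `MULTI_SCORE_SET_EXPERIMENT`, `CROSS_SET_META_ANALYSIS`.
#' @export
validate_hierarchy <- function(collection) {
  stopifnot(inherits(collection, "mave_collection"))
  out <- list()
  es_urns <- collection$experiment_sets$urn
  ex <- collection$experiments
  for (i in seq_len(nrow(ex))) {
    if (!ex$experiment_set_urn[i] %in% es_urns) {
      out[[length(out) + 1L]] <- finding("ORPHAN_RECORD",
        sprintf("experiment %s references unknown experiment set %s",
                ex$urn[i], ex$experiment_set_urn[i]))
    } else if (!urn_extends(ex$urn[i], ex$experiment_set_urn[i])) {
      out[[length(out) + 1L]] <- finding("URN_MISMATCH",
        sprintf("experiment URN %s does not extend %s",
                ex$urn[i], ex$experiment_set_urn[i]))
    }
  }
  ss_urns <- names(collection$score_sets)
  ordinary <- collection$score_sets[!vapply(collection$score_sets,
                                            is_meta_analysis, logical(1))]
  per_experiment <- table(vapply(ordinary, function(s) s$experiment_urn,
                                 character(1)))
  for (ss in collection$score_sets) {
    if (!ss$experiment_urn %in% ex$urn) {
      out[[length(out) + 1L]] <- finding("ORPHAN_RECORD",
        sprintf("score set %s references unknown experiment %s",
                ss$urn, ss$experiment_urn))
    } else if (!urn_extends(ss$urn, ss$experiment_urn)) {
      out[[length(out) + 1L]] <- finding("URN_MISMATCH",
        sprintf("score set URN %s does not extend %s", ss$urn, ss$experiment_urn))
    }
    if (nrow(ss$references) && sum(ss$references$is_primary) > 1L) {
      out[[length(out) + 1L]] <- finding("MULTIPLE_PRIMARY_REFERENCES",
        sprintf("score set %s has %d primary references",
                ss$urn, sum(ss$references$is_primary)))
    }
    for (src in ss$meta_analysis_sources) {
      if (!src %in% ss_urns) {
        out[[length(out) + 1L]] <- finding("UNRESOLVED_SOURCE",
          sprintf("meta-analysis %s sources unknown score set %s", ss$urn, src))
      } else {
        src_set <- parse_urn(src)$experiment_set
        own_set <- parse_urn(ss$urn)$experiment_set
        if (src_set != own_set) {
          out[[length(out) + 1L]] <- finding("CROSS_SET_META_ANALYSIS",
            sprintf("meta-analysis %s sources a score set in another experiment set (%s)",
                    ss$urn, src), severity = "info")
        }
      }
    }
  }
  edges <- dplyr::bind_rows(lapply(collection$score_sets, function(ss) {
    if (!is_meta_analysis(ss)) return(NULL)
    tibble::tibble(from = ss$urn, to = ss$meta_analysis_sources)
  }))
  if (!is.null(edges) && nrow(edges)) {
    cyc <- meta_cycle_members(edges)
    for (u in sort(cyc)) {
      out[[length(out) + 1L]] <- finding("CYCLE",
        sprintf("meta-analysis edge graph contains a cycle through %s", u))
    }
  }
  for (exp_urn in names(per_experiment)[per_experiment > 1]) {
    out[[length(out) + 1L]] <- finding("MULTI_SCORE_SET_EXPERIMENT",
      sprintf("experiment %s carries %d score sets; convention is one experiment per assay",
              exp_urn, per_experiment[[exp_urn]]), severity = "info")
  }
  new_report(dplyr::bind_rows(c(list(no_findings()), out)))
}
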