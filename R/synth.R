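# Deterministic synthetic fixtures: targets, score sets, count tables and
# record collections, with controlled defect seeding so validators can be
# tested for exactness (k seeded defects => k error findings).
#
# All draws go through R's Mersenne-Twister stream with inversion normals,
# seeded from the spec, and the pre-call RNG state is restored afterwards:
# the same spec yields byte-identical outputs on every platform.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Specification for the synthetic fixture generator
#'
#' Collects every knob of the generator in one validated object. The
#' defaults emulate a typical deep mutational scanning score set: a coding
#' nucleotide target of 99 bases (33 codons), 200 variants of which 10% are
#' two-event multi-variants, scores drawn from a two-component Gaussian
#' mixture (a loss-of-function class near 0 and a wild-type-like class near
#' 1, the bimodal shape characteristic of MAVE scores), and 5% missing
#' scores.
#'
#' @param seed Integer seed; identical specs produce identical outputs.
#' @param target_kind `"nucleotide"` or `"protein"`.
#' @param target_length Residues in the target (for coding nucleotide
#'   targets, must be divisible by three).
#' @param target_category Target category; `"coding"` targets are generated
#'   without internal stop codons and summarized at the protein level.
#' @param n_variants Rows in the generated score table.
#' @param multi_variant_fraction Fraction of rows that are two-event
#'   multi-variants.
#' @param score_model List with `component_means`, `component_sds`,
#'   `weights` (summing to 1) describing the Gaussian mixture scores are
#'   drawn from.
#' @param missing_rate Fraction of scores replaced by missing values.
#' @param defects Named integer vector of defects to seed, e.g.
#'   `c(REF_MISMATCH = 2, DUPLICATE_VARIANT = 1)`. Supported codes:
#'   `REF_MISMATCH`, `OUT_OF_BOUNDS`, `DUPLICATE_VARIANT`,
#'   `MALFORMED_VARIANT`, `NON_NUMERIC`, `NEGATIVE_COUNT`,
#'   `UNMATCHED_VARIANT`. Each seeded defect produces exactly one
#'   error finding with the matching code under [validate_score_set()].
#' @return A `mave_generator_spec`.
#' @export
generator_spec <- function(seed = 42L,
                           target_kind = c("nucleotide", "protein"),
                           target_length = 99L,
                           target_category = "coding",
                           n_variants = 200L,
                           multi_variant_fraction = 0.1,
                           score_model = list(component_means = c(0, 1),
                                              component_sds = c(0.2, 0.2),
                                              weights = c(0.35, 0.65)),
                           missing_rate = 0.05,
                           defects = integer(0)) {
  target_kind <- match.arg(target_kind)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    mave_abort("mave_bad_spec", "seed must be a single integer")
  }
  if (target_length < 1L) mave_abort("mave_bad_spec", "target_length must be >= 1")
  if (target_kind == "nucleotide" && target_category == "coding" &&
      target_length %% 3L != 0L) {
    mave_abort("mave_bad_spec",
               "coding nucleotide targets need a length divisible by three")
  }
  w <- score_model$weights
  if (abs(sum(w) - 1) > 1e-9 ||
      length(w) != length(score_model$component_means) ||
      length(w) != length(score_model$component_sds)) {
    mave_abort("mave_bad_spec",
               "score_model weights must sum to 1 and match means/sds in length")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    mave_abort("mave_bad_spec", "missing_rate must be in [0, 1]")
  }
  if (multi_variant_fraction < 0 || multi_variant_fraction > 1) {
    mave_abort("mave_bad_spec", "multi_variant_fraction must be in [0, 1]")
  }
  defects <- unlist(defects)
  if (length(defects)) {
    known <- c("REF_MISMATCH", "OUT_OF_BOUNDS", "DUPLICATE_VARIANT",
               "MALFORMED_VARIANT", "NON_NUMERIC", "NEGATIVE_COUNT",
               "UNMATCHED_VARIANT")
    if (is.null(names(defects)) || !all(names(defects) %in% known) ||
        any(defects < 0)) {
      mave_abort("mave_bad_spec",
                 sprintf("defects must be a named nonnegative vector over {%s}",
                         paste(known, collapse = ", ")))
    }
  }
  structure(
    list(seed = as.integer(seed), target_kind = target_kind,
         target_length = as.integer(target_length),
         target_category = target_category,
         n_variants = as.integer(n_variants),
         multi_variant_fraction = multi_variant_fraction,
         score_model = score_model, missing_rate = missing_rate,
         defects = defects),
    class = "mave_generator_spec"
  )
}

#' Generate a deterministic synthetic target sequence
#'
#' Coding nucleotide targets are built codon-by-codon from the 61 non-stop
#' codons, so translation never hits an internal stop; non-coding targets
#' are uniform over A/C/G/T and protein targets uniform over the twenty
#' amino acids.
#'
#' @param spec A [generator_spec()].
#' @return A `mave_target`.
#' @export
make_target <- function(spec) {
  stopifnot(inherits(spec, "mave_generator_spec"))
  with_seed(spec$seed, {
    if (spec$target_kind == "protein") {
      seq <- paste(sample(names(aa1_to_aa3)[1:20], spec$target_length,
                          replace = TRUE), collapse = "")
      target_sequence(seq, "protein", label = sprintf("synthetic-%d", spec$seed),
                      category = spec$target_category)
    } else if (spec$target_category == "coding") {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      codons <- setdiff(codons, .stop_codons)
      seq <- paste(sample(codons, spec$target_length %/% 3L, replace = TRUE),
                   collapse = "")
      target_sequence(seq, "nucleotide", label = sprintf("synthetic-%d", spec$seed),
                      category = "coding")
    } else {
      seq <- paste(sample(c("A", "C", "G", "T"), spec$target_length,
                          replace = TRUE), collapse = "")
      target_sequence(seq, "nucleotide", label = sprintf("synthetic-%d", spec$seed),
                      category = spec$target_category)
    }
  })
}

# residues and formatting helpers for the generator's variant level
generator_level <- function(spec) {
  if (spec$target_kind == "protein" ||
      spec$target_category == "coding") "protein" else "nucleotide"
}

gen_residues <- function(target, level) {
  if (level == "protein") target_protein_residues(target)
  else strsplit(target$sequence, "")[[1]]
}

gen_sub_string <- function(level, pos, ref, alt) {
  if (level == "protein") sprintf("p.%s%d%s", ref, pos, alt)
  else sprintf("c.%d%s>%s", pos, ref, alt)
}

gen_del_string <- function(level, pos, ref) {
  if (level == "protein") sprintf("p.%s%ddel", ref, pos)
  else sprintf("c.%ddel", pos)
}

gen_alphabet <- function(level) {
  if (level == "protein") aa3_codes else c("A", "C", "G", "T")
}

draw_single_variant <- function(level, residues) {
  L <- length(residues)
  pos <- sample.int(L, 1L)
  ref <- residues[pos]
  if (stats::runif(1) < 0.85) {
    alt <- sample(setdiff(gen_alphabet(level), ref), 1L)
    gen_sub_string(level, pos, ref, alt)
  } else {
    gen_del_string(level, pos, ref)
  }
}

draw_multi_variant <- function(level, residues) {
  L <- length(residues)
  if (L < 2L) return(NULL)
  pos <- sort(sample.int(L, 2L))
  parts <- vapply(pos, function(p) {
    ref <- residues[p]
    alt <- sample(setdiff(gen_alphabet(level), ref), 1L)
    sub("^[cp]\\.", "", gen_sub_string(level, p, ref, alt))
  }, character(1))
  prefix <- if (level == "protein") "p" else "c"
  sprintf("%s.[%s]", prefix, paste(parts, collapse = ";"))
}

draw_mixture_scores <- function(n, model) {
  comp <- sample.int(length(model$weights), n, replace = TRUE,
                     prob = model$weights)
  stats::rnorm(n, mean = model$component_means[comp],
               sd = model$component_sds[comp])
}

#' Generate a synthetic score set (scores plus counts)
#'
#' Draws `n_variants` distinct variant strings from the target (single-event
#' substitutions and deletions, plus two-event multi-variants per
#' `multi_variant_fraction`), scores from the spec's Gaussian mixture with
#' `missing_rate` missing cells, and a paired count table (`count_pre` from
#' the unselected library, `count_post` scaled by the exponentiated score).
#' With an empty `defects` vector the output passes [validate_score_set()]
#' cleanly; each entry in `defects` corrupts the tables so that exactly one
#' error finding with that code appears downstream.
#'
#' @param spec A [generator_spec()].
#' @param target The `mave_target` the variants are drawn from (usually
#'   [make_target()] of the same spec).
#' @return A list with elements `scores` and `counts` (tibbles) and
#'   `variant_column` (the populated column name).
#' @export
make_score_set <- function(spec, target) {
  stopifnot(inherits(spec, "mave_generator_spec"), inherits(target, "mave_target"))
  level <- generator_level(spec)
  residues <- gen_residues(target, level)
  vcol <- if (level == "protein") "hgvs_pro" else "hgvs_nt"
  n <- spec$n_variants
  n_multi <- as.integer(round(n * spec$multi_variant_fraction))
  with_seed(spec$seed + 1L, {
    variants <- character(n)
    seen <- new.env(hash = TRUE, size = 2L * n)
    n_drawn <- 0L
    attempts <- 0L
    while (n_drawn < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n) {
        mave_abort("mave_exhausted",
                   "cannot draw enough distinct variants from this target")
      }
      s <- if (n_drawn < n - n_multi) {
        draw_single_variant(level, residues)
      } else {
        draw_multi_variant(level, residues)
      }
      if (!is.null(s) && is.null(seen[[s]])) {
        seen[[s]] <- TRUE
        n_drawn <- n_drawn + 1L
        variants[n_drawn] <- s
      }
    }
    scores <- draw_mixture_scores(n, spec$score_model)
    missing <- stats::runif(n) < spec$missing_rate
    scores[missing] <- NA_real_
    count_pre <- stats::rpois(n, lambda = 200) + 1L
    rate <- ifelse(is.na(scores), 1, pmax(exp(scores), 1e-3))
    count_post <- stats::rpois(n, lambda = 50 * rate)
    score_tbl <- tibble::tibble(!!vcol := variants, score = scores)
    count_tbl <- tibble::tibble(!!vcol := variants,
                                count_pre = as.numeric(count_pre),
                                count_post = as.numeric(count_post))
    seed_defects(spec, level, residues, score_tbl, count_tbl, vcol)
  })
}

seed_defects <- function(spec, level, residues, scores, counts, vcol) {
  defects <- spec$defects
  out <- list(scores = scores, counts = counts, variant_column = vcol)
  if (!length(defects) || sum(defects) == 0L) return(out)
  codes <- rep(names(defects), defects)
  # victims: distinct single-substitution rows, one per defect, so defects
  # never interact and each maps to exactly one downstream finding
  is_sub <- grepl(if (level == "protein") "^p\\.[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}$"
                  else "^c\\.[0-9]+[ACGT]>[ACGT]$",
                  scores[[vcol]])
  victims <- sample(which(is_sub), length(codes) + 1L)
  donor <- victims[length(victims)]  # row whose variant gets duplicated
  victims <- victims[-length(victims)]
  L <- length(residues)
  alphabet <- gen_alphabet(level)
  set_variant <- function(row, s) {
    out$scores[[vcol]][row] <<- s
    out$counts[[vcol]][row] <<- s
  }
  for (k in seq_along(codes)) {
    r <- victims[k]
    cur <- out$scores[[vcol]][r]
    v <- parse_variant(cur)
    switch(codes[k],
      REF_MISMATCH = {
        true_ref <- residues[v$events$start]
        wrong <- sample(setdiff(alphabet, c(true_ref, v$events$alt)), 1L)
        set_variant(r, gen_sub_string(level, v$events$start, wrong, v$events$alt))
      },
      OUT_OF_BOUNDS = {
        pos <- L + 5L + k
        set_variant(r, gen_sub_string(level, pos, alphabet[1], alphabet[2]))
      },
      DUPLICATE_VARIANT = {
        set_variant(r, out$scores[[vcol]][donor])
      },
      MALFORMED_VARIANT = {
        prefix <- if (level == "protein") "p" else "c"
        set_variant(r, sprintf("%s.bogus%d", prefix, k))
      },
      NON_NUMERIC = {
        out$scores$score <- as.character(out$scores$score)
        out$scores$score[r] <- "n/a"
      },
      NEGATIVE_COUNT = {
        out$counts$count_pre[r] <- -3
      },
      UNMATCHED_VARIANT = {
        extra <- NULL
        repeat {
          extra <- draw_single_variant(level, residues)
          if (!extra %in% out$scores[[vcol]] &&
              !extra %in% out$counts[[vcol]]) break
        }
        out$counts <- dplyr::bind_rows(
          out$counts,
          tibble::tibble(!!vcol := extra, count_pre = 100, count_post = 50))
      }
    )
  }
  out
}

#' Generate a synthetic record collection
#'
#' Builds a full hierarchy: one experiment set, `n_experiments` experiments
#' (suffixes `a`, `b`, ...), one score set per experiment over a shared
#' target, and optionally a meta-analysis score set that sources every
#' generated score set and carries the per-variant mean of the source
#' scores — the canonical two-assays-combined-into-one-function-score
#' shape. The hierarchy validates cleanly by construction.
#'
#' @param spec A [generator_spec()] (its `defects` are ignored here; seed
#'   collection-level defects by editing the returned object in tests).
#' @param n_experiments Number of experiments (>= 1).
#' @param with_meta_analysis Add the meta-analysis score set?
#' @param experiment_set_number Integer used for the 8-digit accession.
#' @return A `mave_collection`.
#' @export
make_collection <- function(spec, n_experiments = 2L,
                            with_meta_analysis = FALSE,
                            experiment_set_number = 1L) {
  stopifnot(inherits(spec, "mave_generator_spec"))
  if (n_experiments < 1L) mave_abort("mave_bad_spec", "n_experiments must be >= 1")
  if (n_experiments > 26L) mave_abort("mave_bad_spec", "at most 26 experiments supported")
  target <- make_target(spec)
  es_urn <- sprintf("urn:mavedb:%08d", experiment_set_number)
  clean <- spec
  clean$defects <- integer(0)
  experiments <- tibble::tibble(
    urn = paste0(es_urn, "-", letters[seq_len(n_experiments)]),
    experiment_set_urn = es_urn,
    title = sprintf("Assay %s", letters[seq_len(n_experiments)])
  )
  score_sets <- list()
  for (i in seq_len(n_experiments)) {
    sub <- clean
    sub$seed <- clean$seed + 97L * i
    tables <- make_score_set(sub, target)
    urn <- paste0(experiments$urn[i], "-1")
    score_sets[[urn]] <- score_set_record(
      urn = urn, experiment_urn = experiments$urn[i],
      scores = tables$scores, target = target, counts = tables$counts,
      title = sprintf("Score set %s-1", letters[i]),
      short_description = "Synthetic per-variant functional scores",
      references = reference(sprintf("10.0000/synthetic.%d", i),
                             source = "crossref_doi", is_primary = TRUE)
    )
  }
  if (with_meta_analysis) {
    sources <- names(score_sets)
    vcol <- if (generator_level(clean) == "protein") "hgvs_pro" else "hgvs_nt"
    merged <- dplyr::bind_rows(lapply(score_sets, function(ss) {
      tibble::tibble(variant = cell_chr(ss$scores[[vcol]]),
                     score = cell_as_numeric(ss$scores$score))
    }))
    meta_scores <- merged |>
      dplyr::group_by(.data$variant) |>
      dplyr::summarise(score = if (all(is.na(.data$score))) NA_real_
                       else mean(.data$score, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::arrange(.data$variant)
    names(meta_scores)[1] <- vcol
    meta_urn <- paste0(experiments$urn[1], "-", 2L)
    score_sets[[meta_urn]] <- score_set_record(
      urn = meta_urn, experiment_urn = experiments$urn[1],
      scores = meta_scores, target = target,
      title = "Combined function score (meta-analysis)",
      short_description = "Per-variant mean of the source score sets",
      meta_analysis_sources = sources
    )
  }
  record_collection(
    experiment_sets = tibble::tibble(urn = es_urn, title = "Synthetic study"),
    experiments = experiments,
    score_sets = score_sets,
    version_tag = sprintf("synthetic-%d", spec$seed)
  )
}
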