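test_that("the printed experiment-set accession parses and round-trips", {
  u <- parse_urn("urn:mavedb:00000055")
  expect_equal(u$experiment_set, 55L)
  expect_equal(u$level, "experiment_set")
  expect_false(u$temporary)
  expect_identical(format_urn(u), "urn:mavedb:00000055")
})

test_that("URN levels derive from the populated fields", {
  expect_equal(parse_urn("urn:mavedb:00000055-a")$level, "experiment")
  u <- parse_urn("urn:mavedb:00000055-a-1")
  expect_equal(u$level, "score_set")
  expect_equal(u$experiment_suffix, "a")
  expect_equal(u$score_set_index, 1L)
  v <- parse_urn("urn:mavedb:00000055-a-1#7")
  expect_equal(v$level, "variant")
  expect_equal(v$variant_index, 7L)
  expect_true(parse_urn("tmp:00000001-a-1")$temporary)
})

test_that("malformed URNs are rejected, including unpadded numbers", {
  expect_error(parse_urn("urn:mavedb:55"), class = "mave_malformed_urn")
  expect_error(parse_urn("urn:mavedb:00000055-A"), class = "mave_malformed_urn")
  expect_error(parse_urn("urn:mavedb:00000055-a-0"), class = "mave_malformed_urn")
  expect_error(parse_urn("urn:mavedb:00000055#7"), class = "mave_malformed_urn")
  expect_error(parse_urn("urn:other:00000055"), class = "mave_malformed_urn")
  expect_error(format_urn(list(experiment_set = 1L, experiment_suffix = NA,
                               score_set_index = 2L)),
               class = "mave_invalid_urn")
})

test_that("URNs round-trip over seeded random accessions", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_urn_string()
    expect_identical(format_urn(parse_urn(s)), s, label = s)
  }
})

test_that("the two-assay meta-analysis shape validates cleanly", {
  spec <- generator_spec(seed = 51L, n_variants = 40L)
  col <- make_collection(spec, n_experiments = 2L, with_meta_analysis = TRUE)
  expect_equal(nrow(col$experiment_sets), 1L)
  expect_equal(nrow(col$experiments), 2L)
  expect_equal(length(col$score_sets), 3L)
  meta <- Filter(function(s) length(s$meta_analysis_sources) > 0, col$score_sets)
  expect_equal(length(meta), 1L)
  expect_equal(length(meta[[1]]$meta_analysis_sources), 2L)
  rep <- validate_hierarchy(col)
  expect_true(rep$valid)
  expect_equal(nrow(report_errors(rep)), 0L)
})

test_that("meta-analysis attachment leaves source tables byte-identical", {
  spec <- generator_spec(seed = 52L, n_variants = 40L)
  before <- make_collection(spec, n_experiments = 2L, with_meta_analysis = FALSE)
  snapshot <- lapply(before$score_sets, function(ss) serialize(ss$scores, NULL))
  after <- make_collection(spec, n_experiments = 2L, with_meta_analysis = TRUE)
  expect_true(validate_hierarchy(after)$valid)
  for (u in names(before$score_sets)) {
    expect_identical(serialize(after$score_sets[[u]]$scores, NULL),
                     snapshot[[u]])
  }
})

test_that("meta scores are per-variant means and collapse to the source when alone", {
  spec <- generator_spec(seed = 53L, n_variants = 30L)
  col <- make_collection(spec, n_experiments = 1L, with_meta_analysis = TRUE)
  src <- col$score_sets[["urn:mavedb:00000001-a-1"]]$scores
  meta <- col$score_sets[["urn:mavedb:00000001-a-2"]]$scores
  merged <- dplyr::left_join(meta, src, by = "hgvs_pro",
                             suffix = c("_meta", "_src"))
  expect_equal(merged$score_meta, merged$score_src)

  col2 <- make_collection(spec, n_experiments = 2L, with_meta_analysis = TRUE)
  meta2 <- col2$score_sets[["urn:mavedb:00000001-a-2"]]
  s1 <- col2$score_sets[["urn:mavedb:00000001-a-1"]]$scores
  s2 <- col2$score_sets[["urn:mavedb:00000001-b-1"]]$scores
  for (i in seq_len(nrow(meta2$scores))) {
    v <- meta2$scores$hgvs_pro[i]
    vals <- c(s1$score[s1$hgvs_pro == v], s2$score[s2$hgvs_pro == v])
    expected <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    expect_equal(meta2$scores$score[i], expected, label = v)
  }
})

test_that("hierarchy defects are detected: cycles, orphans, URN mismatches, references", {
  spec <- generator_spec(seed = 54L, n_variants = 30L)
  col <- make_collection(spec, n_experiments = 2L, with_meta_analysis = TRUE)

  cyc <- col
  # meta sources a-1 and b-1; make a-1 source the meta back
  cyc$score_sets[["urn:mavedb:00000001-a-1"]]$meta_analysis_sources <-
    "urn:mavedb:00000001-a-2"
  rep <- validate_hierarchy(cyc)
  expect_true("CYCLE" %in% report_errors(rep)$code)

  orp <- col
  orp$experiments$experiment_set_urn[1] <- "urn:mavedb:00000099"
  expect_true("ORPHAN_RECORD" %in% report_errors(validate_hierarchy(orp))$code)

  mis <- col
  mis$score_sets[["urn:mavedb:00000001-b-1"]]$experiment_urn <-
    "urn:mavedb:00000001-a"
  expect_true("URN_MISMATCH" %in% report_errors(validate_hierarchy(mis))$code)

  unres <- col
  unres$score_sets[["urn:mavedb:00000001-a-2"]]$meta_analysis_sources <-
    c("urn:mavedb:00000001-a-1", "urn:mavedb:00000077-z-9")
  expect_true("UNRESOLVED_SOURCE" %in%
                report_errors(validate_hierarchy(unres))$code)

  refs <- col
  refs$score_sets[["urn:mavedb:00000001-a-1"]]$references <- dplyr::bind_rows(
    reference("1", "pubmed", is_primary = TRUE),
    reference("2", "pubmed", is_primary = TRUE))
  expect_true("MULTIPLE_PRIMARY_REFERENCES" %in%
                report_errors(validate_hierarchy(refs))$code)
})

test_that("cross-experiment-set meta-analysis is advisory only", {
  spec <- generator_spec(seed = 55L, n_variants = 20L)
  c1 <- make_collection(spec, n_experiments = 1L, experiment_set_number = 1L)
  c2 <- make_collection(spec, n_experiments = 1L, experiment_set_number = 2L)
  merged <- record_collection(
    dplyr::bind_rows(c1$experiment_sets, c2$experiment_sets),
    dplyr::bind_rows(c1$experiments, c2$experiments),
    c(c1$score_sets, c2$score_sets))
  src <- names(merged$score_sets)
  meta <- score_set_record(
    urn = "urn:mavedb:00000001-a-2", experiment_urn = "urn:mavedb:00000001-a",
    scores = merged$score_sets[[1]]$scores, target = merged$score_sets[[1]]$target,
    meta_analysis_sources = src)
  merged$score_sets[[meta$urn]] <- meta
  rep <- validate_hierarchy(merged)
  expect_true(rep$valid)
  expect_true("CROSS_SET_META_ANALYSIS" %in% rep$findings$code)
  expect_equal(rep$findings$severity[rep$findings$code == "CROSS_SET_META_ANALYSIS"],
               "info")
})
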