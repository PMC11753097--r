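test_that("substitutions, deletions and multi-variants parse into structured events", {
  v <- parse_variant("c.1A>G")
  expect_s3_class(v, "mave_variant")
  expect_equal(v$prefix, "c")
  expect_equal(nrow(v$events), 1L)
  expect_equal(v$events$kind, "substitution")
  expect_equal(v$events$start, 1L)
  expect_equal(v$events$ref, "A")
  expect_equal(v$events$alt, "G")

  p <- parse_variant("p.Trp24Cys")
  expect_equal(p$prefix, "p")
  expect_equal(p$events$kind, "substitution")
  expect_equal(p$events$start, 24L)
  expect_equal(p$events$start_ref, "Trp")
  expect_equal(p$events$alt, "Cys")

  m <- parse_variant("c.[1A>G;5del]")
  expect_equal(nrow(m$events), 2L)
  expect_setequal(m$events$kind, c("substitution", "deletion"))
})

test_that("identity must be written as '=' and offsets need splice context", {
  expect_error(parse_variant("c.1A>A"), class = "mave_malformed_variant")
  expect_equal(format_variant(parse_variant("c.=")), "c.=")
  expect_equal(format_variant(parse_variant("p.=")), "p.=")

  v <- parse_variant("c.122-6T>A", splice_context = TRUE)
  expect_equal(v$events$start, 122L)
  expect_equal(v$events$start_offset, -6L)
  expect_error(parse_variant("c.122-6T>A"), class = "mave_offset_not_allowed")
  expect_error(parse_variant("p.Trp24Cys", splice_context = TRUE), NA)
})

test_that("full-HGVS constructs outside the subset raise dedicated conditions", {
  expect_error(parse_variant("c.(1A>G)"), class = "mave_unsupported_feature")
  expect_error(parse_variant("c.1A>?"), class = "mave_unsupported_feature")
  expect_error(parse_variant("p.Trp24fs"), class = "mave_unsupported_feature")
  # legacy Enrich2 tokens get a message naming the legacy format
  err <- tryCatch(parse_variant("_wt"), error = function(e) e)
  expect_s3_class(err, "mave_malformed_variant")
  expect_match(conditionMessage(err), "Enrich2")
  expect_error(parse_variant("_sy"), class = "mave_malformed_variant")
})

test_that("strictness: case, one-letter codes, ordering and overlap are rejected", {
  expect_error(parse_variant("C.1A>G"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.1a>g"), class = "mave_malformed_variant")
  err <- tryCatch(parse_variant("p.W24C"), error = function(e) e)
  expect_s3_class(err, "mave_malformed_variant")
  expect_match(conditionMessage(err), "one-letter")
  expect_error(parse_variant("c.[5del;1A>G]"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.[1A>G;1A>T]"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.[1A>G;1_3del]"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.[2_4del;3A>G]"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.7_9insAAA"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.9_5del"), class = "mave_malformed_variant")
  expect_error(parse_variant("c.0A>G"), class = "mave_malformed_variant")
})

test_that("canonical strings round-trip through parse and format", {
  for (s in canonical_variant_corpus()) {
    expect_equal(format_variant(parse_variant(s)), s, label = s)
  }
  expect_equal(format_variant(parse_variant("c.122-6T>A", splice_context = TRUE)),
               "c.122-6T>A")
  expect_equal(format_variant(parse_variant("c.88+12del", splice_context = TRUE)),
               "c.88+12del")
})

test_that("generator-produced variants round-trip (seeded property)", {
  spec <- generator_spec(seed = 101L, n_variants = 300L,
                         multi_variant_fraction = 0.2)
  tables <- make_score_set(spec, make_target(spec))
  for (s in tables$scores$hgvs_pro) {
    expect_identical(format_variant(parse_variant(s)), s)
  }
})

test_that("single-character fuzzing yields a declared error or a valid parse", {
  declared <- c("mave_malformed_variant", "mave_unsupported_feature",
                "mave_offset_not_allowed")
  set.seed(99)
  alphabet <- c(LETTERS, letters, 0:9, ".", "[", "]", ";", ">", "_", "=", "+",
                "-", "*", "?", "(", ")")
  for (s in canonical_variant_corpus()) {
    for (pos in seq_len(nchar(s))) {
      mutated <- s
      substr(mutated, pos, pos) <- sample(alphabet, 1L)
      res <- tryCatch(parse_variant(mutated), condition = function(e) e)
      if (inherits(res, "condition")) {
        expect_true(any(class(res) %in% declared),
                    label = sprintf("'%s' raised %s", mutated, class(res)[1]))
      } else {
        expect_s3_class(res, "mave_variant")
      }
    }
  }
})

test_that("covered positions are the union of closed event ranges", {
  expect_equal(covered_positions(parse_variant("c.5_7del")), c(5L, 6L, 7L))
  expect_equal(covered_positions(parse_variant("c.5_6insTTT")), integer(0))
  expect_equal(covered_positions(parse_variant("c.=")), integer(0))
  expect_equal(covered_positions(parse_variant("c.[1A>G;5del]")), c(1L, 5L))
  expect_error(covered_positions(parse_variant("c.5+1del", splice_context = TRUE)),
               class = "mave_offset_not_allowed")
})
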