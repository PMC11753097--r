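test_that("direct target validation checks bounds and reference residues", {
  t <- target_sequence("ATG", "nucleotide", category = "coding")
  expect_true(validate_against_target(parse_variant("c.1A>G"), t)$valid)

  r <- validate_against_target(parse_variant("c.1C>G"), t)
  expect_false(r$valid)
  errs <- report_errors(r)
  expect_equal(errs$code, "REF_MISMATCH")
  expect_equal(errs$locus, 1L)

  r <- validate_against_target(parse_variant("c.4A>G"), t)
  expect_equal(report_errors(r)$code, "OUT_OF_BOUNDS")

  # insertion flanks must both be inside the target
  expect_true(validate_against_target(parse_variant("c.1_2insTT"), t)$valid)
  expect_false(validate_against_target(parse_variant("c.3_4insTT"), t)$valid)
})

test_that("protein variants validate against coding DNA via translation", {
  t <- mwc_coding()
  expect_true(validate_against_target(parse_variant("p.Trp2Cys"), t)$valid)
  expect_true(validate_against_target(parse_variant("p.Met1_Cys3del"), t)$valid)
  r <- validate_against_target(parse_variant("p.Cys2Ala"), t)
  expect_equal(report_errors(r)$code, "REF_MISMATCH")
  expect_equal(report_errors(r)$locus, 2L)
  # same checks against the translated protein directly
  expect_true(validate_against_target(parse_variant("p.Trp2Cys"), mwc_protein())$valid)
  # prefix/kind mismatches are findings, not crashes
  expect_false(validate_against_target(parse_variant("c.1A>G"), mwc_protein())$valid)
  noncoding <- target_sequence("ATGT", "nucleotide", category = "regulatory")
  r <- validate_against_target(parse_variant("p.Met1Ala"), noncoding)
  expect_equal(report_errors(r)$code, "PREFIX_KIND_MISMATCH")
})

test_that("translation uses the standard codon table and rejects bad input", {
  expect_equal(translate_dna("ATG"), "M")
  expect_equal(translate_dna("ATGTGGTGC"), "MWC")
  expect_equal(translate_dna("TAA"), "*")
  expect_error(translate_dna("ATGTA"),
               class = "mave_length_not_multiple_of_three")
  expect_error(translate_dna("ATGNNN"), class = "mave_bad_alphabet")
})

test_that("splice-column offsets get format-only validation", {
  t <- target_sequence("ATGTGGTGC", "nucleotide", category = "coding")
  v <- parse_variant("c.3-2A>G", splice_context = TRUE)
  r <- validate_against_target(v, t)
  expect_true(r$valid)
  expect_equal(r$findings$code, "FORMAT_ONLY")
  expect_equal(r$findings$severity, "info")
})

test_that("variants synthesized from a target always validate (soundness)", {
  spec <- generator_spec(seed = 11L, n_variants = 150L)
  target <- make_target(spec)
  tables <- make_score_set(spec, target)
  rep <- validate_score_table(tables$scores, target)
  expect_true(rep$valid)
  expect_equal(nrow(report_errors(rep)), 0L)
})

test_that("a single corrupted reference produces exactly one REF_MISMATCH at that locus", {
  spec <- generator_spec(seed = 12L, n_variants = 50L)
  target <- make_target(spec)
  residues <- strsplit(translate_dna(target$sequence), "")[[1]]
  aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
           "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
           "Tyr", "Val")
  aa3_of <- stats::setNames(aa3, c("A", "R", "N", "D", "C", "Q", "E", "G",
                                   "H", "I", "L", "K", "M", "F", "P", "S",
                                   "T", "W", "Y", "V"))
  set.seed(13)
  for (i in 1:50) {
    pos <- sample.int(length(residues), 1L)
    true_ref <- aa3_of[[residues[pos]]]
    wrong <- sample(setdiff(aa3, true_ref), 1L)
    alt <- sample(setdiff(aa3, c(true_ref, wrong)), 1L)
    r <- validate_against_target(parse_variant(sprintf("p.%s%d%s", wrong, pos, alt)),
                                 target)
    errs <- report_errors(r)
    expect_equal(nrow(errs), 1L)
    expect_equal(errs$code, "REF_MISMATCH")
    expect_equal(errs$locus, pos)
  }
})

test_that("accession-anchored validation matches the fixture lookup", {
  lk <- memory_lookup(c(FIX01 = "CCCCAGGG"))
  expect_true(validate_against_accession(parse_variant("g.5A>T"), "FIX01", lk)$valid)
  r <- validate_against_accession(parse_variant("g.5G>T"), "FIX01", lk)
  expect_equal(report_errors(r)$code, "REF_MISMATCH")
  expect_equal(report_errors(r)$locus, 5L)
  r <- validate_against_accession(parse_variant("g.2C>T"), "MISSING", lk)
  expect_equal(report_errors(r)$code, "UNRESOLVED_ACCESSION")
  r <- validate_against_accession(parse_variant("g.99A>T"), "FIX01", lk)
  expect_equal(report_errors(r)$code, "OUT_OF_BOUNDS")
})

test_that("accession mode agrees with direct mode when the lookup serves the target", {
  spec <- generator_spec(seed = 21L, n_variants = 60L,
                         target_category = "non_coding", target_length = 80L)
  target <- make_target(spec)
  tables <- make_score_set(spec, target)
  lk <- memory_lookup(stats::setNames(list(target$sequence), "ACC1"))
  for (s in tables$scores$hgvs_nt[1:25]) {
    v <- parse_variant(s)
    direct <- validate_against_target(v, target)
    via_acc <- validate_against_accession(v, "ACC1", lk)
    expect_equal(via_acc$valid, direct$valid, label = s)
    expect_equal(report_errors(via_acc)$code, report_errors(direct)$code)
  }
})

test_that("FASTA targets read back with record ids as labels", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">geneA some description", "ATGTGG", "TGC",
               ">geneB", "MWC"), path)
  targets <- read_targets_fasta(path)
  expect_named(targets, c("geneA", "geneB"))
  expect_equal(targets$geneA$sequence, "ATGTGGTGC")
  expect_equal(targets$geneA$kind, "nucleotide")
  expect_equal(targets$geneB$kind, "protein")

  lk <- fasta_lookup(path)
  expect_equal(lk("geneA", 4L, 6L), "TGG")
  expect_null(lk("nope", 1L, 1L))
})
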