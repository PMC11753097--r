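test_that("histogram bins conserve row totals", {
  t <- tibble::tibble(hgvs_pro = paste0("p.Met", 1:4, "Ala"),
                      score = c(0, 0, 1, 1))
  h <- score_histogram(t, rule = 2)
  expect_equal(h$counts, c(2L, 2L))
  expect_equal(h$n_missing, 0L)

  t2 <- tibble::tibble(hgvs_pro = paste0("p.Met", 1:4, "Ala"),
                       score = c(1, 1, 1, NA))
  h2 <- score_histogram(t2, rule = 3)
  expect_equal(h2$n_missing, 1L)
  expect_equal(sum(h2$counts), 3L)
  expect_equal(sum(h2$counts) + h2$n_missing, nrow(t2))

  all_na <- tibble::tibble(hgvs_pro = "p.Met1Ala", score = NA_real_)
  expect_error(score_histogram(all_na), class = "mave_empty_scores")
})

test_that("Freedman-Diaconis binning matches a brute-force oracle", {
  spec <- generator_spec(seed = 11L, n_variants = 1000L, target_length = 300L,
                         multi_variant_fraction = 0)
  tables <- make_score_set(spec, make_target(spec))
  h <- score_histogram(tables$scores, rule = "fd")
  x <- mavekit:::cell_as_numeric(tables$scores$score)
  expect_equal(h$counts, brute_force_bin(x, h$bin_edges))
  expect_equal(sum(h$counts) + h$n_missing, nrow(tables$scores))
  expect_true(all(diff(h$bin_edges) > 0))
})

test_that("histograms are invariant under row permutation", {
  spec <- generator_spec(seed = 12L, n_variants = 100L)
  tables <- make_score_set(spec, make_target(spec))
  h1 <- score_histogram(tables$scores)
  set.seed(1)
  h2 <- score_histogram(tables$scores[sample.int(nrow(tables$scores)), ])
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$bin_edges, h2$bin_edges)
})

test_that("effect matrix places single-event variants and excludes the rest", {
  t <- tibble::tibble(
    hgvs_pro = c("p.Met1Ala", "p.Trp2Cys", "p.Cys3del"),
    score = c(0.1, 0.2, 0.9)
  )
  m <- effect_matrix(t, mwc_protein())
  expect_equal(dim(m$matrix), c(22L, 3L))
  expect_equal(sum(!is.na(m$matrix)), 3L)
  expect_equal(m$matrix["Ala", 1], 0.1)
  expect_equal(m$matrix["Cys", 2], 0.2)
  expect_equal(m$matrix["del", 3], 0.9)
  expect_equal(m$n_excluded_multi, 0L)
  # wild-type mask points at the target residues, never filled cells
  expect_equal(m$row_labels[m$wt_mask], c("Met", "Trp", "Cys"))
  expect_true(all(is.na(m$matrix[cbind(m$wt_mask, seq_along(m$wt_mask))])))

  multi <- tibble::tibble(hgvs_pro = "p.[Met1Ala;Trp2Cys]", score = 0.5)
  m2 <- effect_matrix(multi, mwc_protein())
  expect_equal(sum(!is.na(m2$matrix)), 0L)
  expect_equal(m2$n_excluded_multi, 1L)

  empty <- tibble::tibble(hgvs_pro = character(0), score = numeric(0))
  m3 <- effect_matrix(empty, mwc_protein())
  expect_equal(sum(!is.na(m3$matrix)), 0L)
  expect_equal(m3$n_excluded_multi, 0L)
})

test_that("nucleotide-level matrices have exactly five rows; protein twenty-two", {
  nc <- generator_spec(seed = 13L, n_variants = 50L, target_length = 60L,
                       target_category = "regulatory")
  target <- make_target(nc)
  tables <- make_score_set(nc, target)
  m <- effect_matrix(tables$scores, target)
  expect_equal(m$level, "nucleotide")
  expect_equal(rownames(m$matrix), c("A", "C", "G", "T", "del"))
  expect_equal(nrow(m$matrix), 5L)

  pro <- generator_spec(seed = 13L, n_variants = 50L)
  target2 <- make_target(pro)
  m2 <- effect_matrix(make_score_set(pro, target2)$scores, target2)
  expect_equal(m2$level, "protein")
  expect_equal(nrow(m2$matrix), 22L)

  expect_error(effect_matrix(tables$scores, target, level = "protein"),
               class = "mave_alphabet_mismatch")
})

test_that("matrix cells, exclusions and missing scores partition the rows", {
  for (seed in c(21L, 22L, 23L)) {
    spec <- generator_spec(seed = seed, n_variants = 120L,
                           multi_variant_fraction = 0.25, missing_rate = 0.1)
    target <- make_target(spec)
    tables <- make_score_set(spec, target)
    m <- effect_matrix(tables$scores, target)
    expect_equal(sum(!is.na(m$matrix)) + m$n_excluded_multi + m$n_missing_score,
                 nrow(tables$scores))
  }
})

test_that("summary statistics agree with direct recomputation", {
  t <- tibble::tibble(hgvs_pro = paste0("p.Met", 1:3, "Ala"),
                      score = c(1, 2, 3))
  s <- summary_stats(t)
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)

  t2 <- tibble::tibble(hgvs_pro = c("p.Met1Ala", "p.Met2Ala"),
                       score = c(5, NA))
  s2 <- summary_stats(t2)
  expect_equal(s2$n_variants, 2L)
  expect_equal(s2$n_scored, 1L)
  expect_equal(s2$mean, 5)

  spec <- generator_spec(seed = 14L, n_variants = 400L, target_length = 150L)
  tables <- make_score_set(spec, make_target(spec))
  s3 <- summary_stats(tables$scores)
  x <- tables$scores$score
  x <- x[!is.na(x)]
  expect_equal(s3$mean, sum(x) / length(x), tolerance = 1e-12)
  xs <- sort(x)
  n <- length(xs)
  med <- if (n %% 2L == 1L) xs[(n + 1L) / 2L] else (xs[n / 2L] + xs[n / 2L + 1L]) / 2
  expect_equal(s3$median, med, tolerance = 1e-12)
})

test_that("tidy and autoplot work on both summary types", {
  spec <- generator_spec(seed = 15L, n_variants = 60L)
  target <- make_target(spec)
  tables <- make_score_set(spec, target)
  h <- score_histogram(tables$scores)
  td <- tidy(h)
  expect_equal(nrow(td), length(h$counts))
  expect_s3_class(autoplot(h), "ggplot")

  m <- effect_matrix(tables$scores, target)
  tm <- tidy(m)
  expect_equal(nrow(tm), nrow(m$matrix) * ncol(m$matrix))
  expect_equal(sum(!is.na(tm$score)), sum(!is.na(m$matrix)))
  expect_equal(sum(tm$is_wt), ncol(m$matrix))
  expect_s3_class(autoplot(m), "ggplot")
})
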