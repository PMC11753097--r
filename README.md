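# mavekit

Offline tooling for multiplexed assay of variant effect (MAVE) datasets.

Multiplexed assays — deep mutational scans, saturation genome editing
screens, massively parallel reporter assays — measure a functional score for
thousands of variants of one target sequence at once. Public repositories
for these data organize them as a hierarchy of records (experiment sets
grouping experiments, experiments grouping score sets, and meta-analysis
score sets derived from existing ones), identify records with hierarchical
URN accessions, and require every uploaded variant string to be valid
MAVE-HGVS that is consistent with the score set's target sequence.

`mavekit` implements that data model as an R package, so the same checks a
repository runs at submission time can be run locally, with no network:

- **Grammar** — a strict parser/formatter for the MAVE-HGVS subset of the
  HGVS nomenclature: substitution (`c.1A>G`, `p.Trp24Cys`), deletion,
  duplication, insertion, deletion-insertion and target-identical (`c.=`)
  events under `g.`/`c.`/`n.`/`p.`, plus multi-event variants
  (`c.[1A>G;5del]`). Positions are 1-based with closed ranges; intronic
  offsets (`c.122-6T>A`) are accepted only in splice context.
- **Target consistency** — every stated reference residue is checked
  against the target sequence (protein variants against a protein target or
  a translated coding DNA target), or against an accession through a
  pluggable sequence lookup.
- **Tables** — schema validation for score and count CSVs with the
  reserved columns `hgvs_nt`, `hgvs_splice`, `hgvs_pro`, `score`.
- **Records** — URN parsing/formatting, the record hierarchy, and
  meta-analysis links, with structural validation (orphans, URN mismatches,
  cycles, unresolved sources).
- **Archive** — a bulk-release layout (one `metadata.json` plus one CSV
  per table) with deterministic, bit-stable output and exact round-trips.
- **Summaries** — the score histogram and variant effect heatmap matrix
  (protein level for coding targets, nucleotide level otherwise), with
  `tidy()`/`glance()`/`autoplot()` support.
- **Synthetic fixtures** — a seeded generator for targets, score sets and
  collections, including controlled defect seeding: `k` seeded defects
  produce exactly `k` error findings downstream.

## Worked example

```r
library(mavekit)

target <- target_sequence("ATGTGGTGC", "nucleotide", category = "coding")
scores <- tibble::tibble(
  hgvs_pro = c("p.Met1Ala", "p.Trp2Cys", "p.Cys3del"),
  score    = c(0.12, -1.4, 0.95)
)

report <- validate_score_table(scores, target)
glance(report)
#> # A tibble: 1 × 4
#>   valid n_error n_warning n_info
#>   <lgl>   <int>     <int>  <int>
#> 1 TRUE        0         0      0

summary_stats(scores)
#> # A tibble: 1 × 6
#>   n_variants n_scored   min   max   mean median
#>        <int>    <int> <dbl> <dbl>  <dbl>  <dbl>
#> 1          3        3  -1.4  0.95 -0.11   0.12

m <- effect_matrix(scores, target)
m
#> <mave_effect_matrix> protein level, 22 x 3, 3 filled, 0 excluded, 0 missing-score
m$matrix["Cys", 2]
#> [1] -1.4
```

`valid = TRUE` means no error-severity findings: all three variant strings
parse, their stated reference residues (`Met1`, `Trp2`, `Cys3`) match the
translation `MWC` of the coding target, and no tuple is duplicated. The
effect matrix has one filled cell per single-event substitution or
single-position deletion; the deletion lands in the dedicated `del` row at
position 3.

A corrupted table is pinpointed rather than rejected wholesale:

```r
bad <- scores
bad$hgvs_pro[2] <- "p.Cys2Ala"   # target has Trp at residue 2
tidy(validate_score_table(bad, target))
#> # A tibble: 1 × 6
#>   severity code         message                                 locus   row column
#>   <chr>    <chr>        <chr>                                   <int> <int> <chr>
#> 1 error    REF_MISMATCH stated reference 'Cys' at position 2 b…     2     2 hgvs_pro
```

The same validators are available from a shell via `inst/cli/mavekit`
(`validate`, `summarize`, `export-archive`, `load-archive`,
`gen-fixture`), exiting 0 when clean, 1 on validation errors, 2 on usage
errors.

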