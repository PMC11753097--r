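---
title: "Validating and summarizing MAVE datasets with mavekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and summarizing MAVE datasets with mavekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavekit)
```

## The problem

A multiplexed assay of variant effect (MAVE) measures a functional score for
each of thousands of variants of one target — a deep mutational scan over a
protein, a saturation genome editing screen over a genomic locus, a reporter
assay over a regulatory element. Sharing these data reliably requires three
things that `mavekit` implements: an unambiguous, machine-checkable variant
nomenclature; schema validation tying every score to a variant that actually
exists on the target; and a record model that preserves provenance when
scores are reanalyzed or combined.

## The MAVE-HGVS grammar

MAVE targets frequently lack database reference sequences, so the general
HGVS nomenclature — which leans on transcript accessions and permits
uncertainty — is both too heavy and too permissive. `parse_variant()`
accepts the strictly validatable subset: substitution, deletion,
duplication, insertion, deletion–insertion and target-identical (`=`)
events under the `g.`/`c.`/`n.`/`p.` prefixes, with multi-event variants in
square brackets. Everything else (uncertainty `?`, parenthesized
predictions, frameshift shorthand, repeats) raises a dedicated
"unsupported feature" condition so callers can distinguish "not HGVS" from
"HGVS we refuse".

Deliberate strictness choices, each favoring unambiguous round-trips over
convenience:

- Coordinates are 1-based with fully closed ranges. Position 0 is invalid.
- Protein residues must be three-letter codes (`Trp`, not `W`); one-letter
  input is rejected with a pointed message rather than auto-converted,
  because silent conversion would make `format(parse(s))` differ from `s`.
- Nucleotides are uppercase only, prefixes lowercase only.
- Multi-event variants must be listed in ascending position order with no
  overlapping covered positions; equal start positions are rejected
  outright, since no two supported event kinds can share a start without
  overlapping. The parser never re-sorts silently.
- Identity is written `c.=`; a substitution whose reference equals its
  alternate is an error, not an identity.
- Intronic offsets (`c.122-6T>A`) are only meaningful in the `hgvs_splice`
  table column; outside splice context they raise `mave_offset_not_allowed`
  because no contiguous target can verify them.
- Legacy Enrich2-style tokens (`_wt`, `_sy`) are rejected with an error
  message that names the legacy format, since they are the most common
  historical contamination in uploaded tables.

`format_variant()` is the deterministic inverse; the test suite asserts
format∘parse identity over 10,000 generated strings and over a hand-written
corpus covering every event kind, and fuzzes single-character mutations to
check that the parser is total: every mutation either parses or raises one
of the three declared condition classes.

## Target consistency

`validate_against_target()` checks a parsed variant against the sequence it
claims to describe: prefix/kind compatibility, bounds, stated reference
residues, insertion flanks. Protein variants validate against a protein
target directly or against a coding nucleotide target via standard-code
translation (`translate_dna()`, genetic code table 1 through Biostrings; no
alternative codon tables are offered). All problems are findings in a
report — validation never throws on bad data, only on violated
preconditions — so one report aggregates every event of a multi-event
variant. Design points:

- Splice-column variants with offsets get a `FORMAT_ONLY` info finding:
  without a genome there is nothing to check an intronic base against, and
  pretending otherwise would be worse than saying so.
- Targets are validated on the given strand only; score sets define their
  own target, so reverse-complement handling is out of scope.
- Accession-anchored variants (saturation genome editing) use a pluggable
  lookup function; the shipped implementations are an in-memory map and a
  local FASTA file, which keeps tests hermetic. An unresolvable accession
  is an `UNRESOLVED_ACCESSION` finding, not an exception, because whether a
  score set must also carry a local subsequence is a policy question left
  to the caller.

## Table schema

Score tables are tibbles with reserved columns `hgvs_nt`, `hgvs_splice`,
`hgvs_pro` and `score`; any number of additional columns is allowed but
they must be numeric. Missing-value tokens are the empty string and `NA`,
exactly. A row may populate nucleotide and protein strings simultaneously;
cross-projection between them is deliberately not checked (that would
require transcript modeling outside this package's scope), but two
different nucleotide prefixes in one row are flagged as contradictory.
Duplicate variant-column tuples are errors. An entirely missing score
column is an error, while row-wise missing scores are fine when the paired
count row carries data — after filtering, a variant may legitimately retain
counts but no score.

Count tables must match the score table's variant tuples set-wise in both
directions, contain no negative counts, and leave no variant with neither a
score nor any count.

## Records, URNs and meta-analysis

Accessions follow the hierarchical scheme
`urn:mavedb:NNNNNNNN[-x[-k[#v]]]`: an 8-digit zero-padded experiment-set
number, a lowercase experiment suffix, a positive score-set index, and a
`#`-separated variant index; each deeper field requires the shallower ones,
and the record level is derivable from which fields are populated.
Unpublished records use the same structure with the namespace replaced by
`tmp:` — the published literature prints only the published form, so the
temporary scheme is this package's own convention, chosen to keep
`parse_urn()`/`format_urn()` exact inverses.

`validate_hierarchy()` checks orphans, textual URN extension from parent to
child, meta-analysis source resolution, cycle freedom of the meta-analysis
edge graph (a depth-first search; the graphs are tiny), and the
one-primary-reference rule. Two conventions are advisory and therefore
reported at info severity, never as errors: one experiment per assay
(surfaced when an experiment carries several ordinary score sets) and
meta-analyses that span experiment sets (permitted, flagged).

Meta-analysis score sets are append-only by construction: they reference
their sources by URN and carry their own table. The tests assert that
attaching a meta-analysis leaves every source table byte-identical
(serialized bytes compared), which is the property that makes reanalysis
trustworthy.

## Archive format

The bulk release is one `metadata.json` holding all record metadata plus a
`csv/` directory with one scores CSV per score set and one counts CSV per
score set that has counts, filenames derived from URNs with `:` and `#`
mapped to `-`. No published schema exists for the metadata file, so this
package defines its own (`format: "mavekit-archive"`, `schema_version`,
and a free-text `version_tag` for snapshot dating) and treats it as the
format definition. Determinism is a hard requirement: records are sorted
by URN, JSON keys are emitted in fixed order, and numbers are written as
the shortest decimal string that parses back to the identical double —
writing the same collection twice is bit-identical, and
`read_archive(write_archive(c))` equals `c` under
`canonicalize_collection()`. Missing table files degrade to
`MISSING_TABLE` findings; only an absent or unreadable `metadata.json` is a
hard error.

## Summaries

`score_histogram()` defaults to Freedman–Diaconis binning (width
`2·IQR·n^{-1/3}`), which is robust for the bimodal distributions MAVE
scores typically show (a loss-of-function mode and a wild-type-like mode);
when the IQR is zero it falls back to 30 equal-width bins, and a degenerate
single-valued score vector gets a unit-width window around the value. Bins
are right-closed with the first bin closed on both sides; counts plus the
missing tally always equal the row count.

`effect_matrix()` builds the heatmap matrix: 22 rows for protein-level
summaries (twenty amino acids in alphabetical three-letter order, then
`Ter`, then `del`) and 5 rows for nucleotide-level ones (A, C, G, T,
`del`), columns 1..L. Coding targets are summarized at the protein level
from `hgvs_pro`, everything else at the nucleotide level from `hgvs_nt`.
One cell is filled per single-event substitution or single-position
deletion; multi-event variants, insertions, duplications, multi-position
deletions and target-identical rows have no natural single cell and are
tallied in `n_excluded_multi` (they still contribute to the histogram),
and placeable variants with missing scores are tallied separately, so the
three buckets partition the table exactly. The `wt_mask` records the
target residue row per column; validated substitutions can never land
there (their stated reference must equal the target residue and differ
from the alternate). Whether wild-type cells should be colored is a
rendering question; the mask is provided, uncolored.

## The synthetic generator

`generator_spec()` fixes the simulated study conditions: a coding
nucleotide target of 99 bases (33 codons, drawn from the 61 non-stop
codons so translation is stop-free), 200 variants with 10% two-event
multi-variants, scores from a two-component Gaussian mixture (means 0 and
1, SDs 0.2, weights 0.35/0.65 — a loss-of-function class and a
wild-type-like class on a typical min–max normalized score scale), and 5%
missing scores. Counts emulate a selection experiment: a pre-selection
Poisson count (λ = 200) and a post-selection count whose rate scales with
the exponentiated score. Draws use R's Mersenne-Twister with inversion
normals, the generator restores the caller's RNG state, and identical
specs are bit-reproducible across platforms.

Defect seeding is the generator's central testing feature: each entry of
`defects` corrupts the tables so that exactly one downstream error finding
with that code appears. Victim rows are distinct single-substitution rows,
and variant-string edits are mirrored into the count table, so defects
never interact — which is what makes "k seeded defects ⇒ exactly k error
findings" a meaningful exactness property rather than a lower bound.

What the generator does not emulate: position-dependent mutational
tolerance, codon-level biases, sequencing noise beyond Poisson counts,
replicate structure, and real bottleneck effects. Passing tests therefore
demonstrate the correctness of parsing, validation, bookkeeping and
serialization on realistic shapes of data — not that any scoring method is
biologically calibrated.

## Problem sizes and numerical choices

The test suite runs the full-scale properties: 10,000 round-trip strings
(on a 1,000-residue target, whose distinct single-variant capacity is more
than double the number of single-event draws),
200 defect-seeded score sets at the default 200 rows, 1,000 soundness
draws, 200 ref corruptions, 50 archive round-trips, and 20 conservation
checks, all under fixed seeds. Unit tests use smaller sizes of the same
generators. Floating-point equality in round-trips is exact by design
(shortest-round-trip serialization), not tolerance-based; summary
statistics are checked against brute-force recomputation at `1e-12`.

## Limitations

- No projection from nucleotide variants to protein consequences, no
  3'-shifting or indel normalization, no transcript liftover.
- No real genome or transcript database; accession mode is only as good as
  the lookup supplied.
- The archive schema is this package's own; it is not interoperable with
  any official dump format byte-for-byte, though the layout mirrors the
  JSON-plus-CSV convention.
- Score normalization, clinical calibration and classification thresholds
  are out of scope.
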