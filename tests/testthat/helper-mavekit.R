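# Shared fixtures and independent oracles, all built in code at test time.

# small protein target Met-Trp-Cys and its coding DNA
mwc_protein <- function() target_sequence("MWC", "protein", label = "mwc")
mwc_coding <- function() {
  target_sequence("ATGTGGTGC", "nucleotide", label = "mwc-dna",
                  category = "coding")
}

# independent brute-force histogram binning: first bin closed on the left,
# all bins closed on the right
brute_force_bin <- function(x, edges) {
  x <- x[!is.na(x)]
  counts <- integer(length(edges) - 1L)
  for (v in x) {
    for (b in seq_along(counts)) {
      lo <- edges[b]; hi <- edges[b + 1L]
      inside <- if (b == 1L) v >= lo && v <= hi else v > lo && v <= hi
      if (inside) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# random URN component draw for round-trip properties
random_urn_string <- function() {
  ns <- if (stats::runif(1) < 0.2) "tmp:" else "urn:mavedb:"
  out <- sprintf("%s%08d", ns, sample.int(99999999L, 1L))
  depth <- sample(0:3, 1L)
  if (depth >= 1L) {
    out <- paste0(out, "-", paste(sample(letters, sample(1:2, 1L)), collapse = ""))
  }
  if (depth >= 2L) out <- paste0(out, "-", sample.int(30L, 1L))
  if (depth >= 3L) out <- paste0(out, "#", sample.int(5000L, 1L))
  out
}

# assorted hand-written canonical strings covering every event kind
canonical_variant_corpus <- function() {
  c("c.1A>G", "g.100A>T", "n.12C>G", "c.5del", "c.5_7del", "c.5dup",
    "c.5_9dup", "c.5_6insTTT", "c.5delinsTT", "c.5_7delinsAAG", "c.=",
    "p.Trp24Cys", "p.Met1Ala", "p.Cys3del", "p.Met1_Cys3del", "p.Trp24dup",
    "p.Trp24_Cys25insAlaGly", "p.Trp24delinsAlaGly", "p.=", "g.7_8insA",
    "c.[1A>G;5del]", "c.[1A>G;5_7del]", "p.[Met1Ala;Trp2Cys]",
    "c.[2del;9dup]")
}

expect_error_codes <- function(report, codes) {
  expect_setequal(report_errors(report)$code, codes)
}
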