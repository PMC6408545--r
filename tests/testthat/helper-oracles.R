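# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit loops, exhaustive enumeration) and share
# no code with the package implementation.

# step-by-step running-sum enrichment score: walk the ranked list one
# feature at a time, track the running sum, return its value at the
# point of largest absolute excursion
oracle_enrichment_score <- function(ranked, set) {
  g <- length(ranked)
  s <- length(set)
  running <- 0
  best <- 0
  for (f in ranked) {
    if (f %in% set) {
      running <- running + 1 / s
    } else {
      running <- running - 1 / (g - s)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# exact upper-tail hypergeometric by enumerating every n-subset of the
# universe (feasible for N <= 12)
oracle_hypergeom_upper <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(universe, n)
  overlaps <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(overlaps >= k)
}

# exact null probability P(RP <= observed) for one fixed gene under
# independent random rankings: enumerate every combination of rank
# assignments across comparisons ((G!)^c equivalent reduces to G^c for
# a single gene's rank, which is uniform per comparison)
oracle_rank_product_null <- function(n_genes, n_comparisons, observed_rp) {
  grids <- rep(list(seq_len(n_genes)), n_comparisons)
  combos <- as.matrix(expand.grid(grids))
  rp <- exp(rowMeans(log(combos)))
  mean(rp <= observed_rp + 1e-12)
}

# small helpers to build in-memory fixtures ---------------------------

make_signature <- function(ranked, n1, n2, sample = "s") {
  structure(list(sample = sample,
                 up = ranked[seq_len(n1)],
                 down = ranked[seq.int(length(ranked) - n2 + 1, length(ranked))],
                 ranked = ranked),
            class = "subject_signature")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

make_records <- function(a, b, type = "physical", org_a = 9606L, org_b = 9606L) {
  n <- length(a)
  data.frame(symbol_a = a, symbol_b = b,
             organism_a = rep_len(org_a, n), organism_b = rep_len(org_b, n),
             system_type = rep_len(type, n), stringsAsFactors = FALSE)
}
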