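# Synthetic-data generators with planted ground truth. Every generator
# is a pure function of its parameters and seed (bit-reproducible);
# noise is Normal on the log2 scale for expression and on the Ct scale
# for qPCR, matching the multiplicative error model implicit in
# fold-change and 2^-ddCt analyses.

default_group_sizes <- function() {
  c(T2DM_CTRL = 20L, NONT2DM_CTRL = 12L, T2DM_AD = 6L, NONT2DM_AD = 19L)
}

#' Generate a grouped expression dataset with planted signatures
#'
#' Background features are Normal(baseline, noise_sd) on the log2 scale
#' in every sample; each group receives a disjoint set of planted up-
#' and down-regulated features, shifted by `+-effect_size * noise_sd` in
#' that group's samples only. The `linear` scale exponentiates the log2
#' values, guaranteeing positivity. Defaults mirror a four-group
#' case/control design with cohort sizes 20/12/6/19 on an array-scale
#' feature space.
#'
#' @param n_features Number of probes (default 20000).
#' @param group_sizes Named integer vector, group label -> sample count.
#' @param planted_per_group Planted up features per group; the same
#'   number is planted down (default 10).
#' @param effect_size Shift in units of `noise_sd` (default 2).
#' @param noise_sd Log2-scale noise SD (default 1).
#' @param baseline Log2-scale background mean (default 8).
#' @param scale `"linear"` (exponentiated) or `"log2"`.
#' @param seed Integer seed.
#' @return List with `expression` (matrix), `groups` (named character
#'   vector) and `truth` (class `synthetic_truth`: planted up/down probe
#'   ids per group, seed, parameters).
#' @export
generate_expression_dataset <- function(n_features = 20000,
                                        group_sizes = default_group_sizes(),
                                        planted_per_group = 10,
                                        effect_size = 2,
                                        noise_sd = 1,
                                        baseline = 8,
                                        scale = c("linear", "log2"),
                                        seed = 1) {
  scale <- match.arg(scale)
  stopifnot(length(group_sizes) >= 2, all(group_sizes >= 1),
            !is.null(names(group_sizes)))
  n_groups <- length(group_sizes)
  if (2 * planted_per_group * n_groups > n_features) {
    stop("cannot plant ", 2 * planted_per_group * n_groups,
         " disjoint features among ", n_features, call. = FALSE)
  }
  probes <- sprintf("P%05d", seq_len(n_features))
  samples <- unlist(lapply(names(group_sizes), function(g) {
    sprintf("%s_S%02d", g, seq_len(group_sizes[[g]]))
  }))
  groups <- stats::setNames(rep(names(group_sizes), group_sizes), samples)

  withr::with_seed(seed, {
    planted_pool <- sample(probes, 2 * planted_per_group * n_groups)
    vals <- matrix(stats::rnorm(n_features * length(samples),
                                mean = baseline, sd = noise_sd),
                   nrow = n_features, dimnames = list(probes, samples))
  })
  planted_up <- planted_down <- list()
  idx <- 0
  for (g in names(group_sizes)) {
    up <- planted_pool[idx + seq_len(planted_per_group)]
    down <- planted_pool[idx + planted_per_group + seq_len(planted_per_group)]
    idx <- idx + 2 * planted_per_group
    cols <- names(groups)[groups == g]
    vals[up, cols] <- vals[up, cols] + effect_size * noise_sd
    vals[down, cols] <- vals[down, cols] - effect_size * noise_sd
    planted_up[[g]] <- up
    planted_down[[g]] <- down
  }
  if (scale == "linear") vals <- 2^vals

  truth <- structure(
    list(planted_up = planted_up, planted_down = planted_down,
         seed = seed,
         params = list(n_features = n_features,
                       group_sizes = as.list(group_sizes),
                       planted_per_group = planted_per_group,
                       effect_size = effect_size, noise_sd = noise_sd,
                       baseline = baseline, scale = scale)),
    class = "synthetic_truth"
  )
  list(expression = vals, groups = groups, truth = truth)
}

# unrank 1-based linear indices into strictly-upper-triangle pairs
# (i < j) of an n x n grid, row-major: row i holds the n - i pairs
# (i, i+1) ... (i, n)
unrank_pairs <- function(idx, n) {
  starts <- c(0, cumsum(seq.int(n - 1, 1)))  # pairs preceding each row
  i <- findInterval(idx - 1, starts)
  j <- idx - starts[i] + i
  cbind(i, j)
}

#' Generate a random sparse interactome with an optional planted module
#'
#' Draws `n_edges` distinct unordered symbol pairs uniformly at random
#' (no self-pairs), all flagged physical and within-taxon. If a planted
#' module is given, a connected path through its members is appended, so
#' 1-step expansion from any member reaches its path neighbours.
#'
#' @param symbols Character vector of node symbols.
#' @param n_edges Number of random edges; at most `choose(|symbols|, 2)`.
#' @param planted_module Optional character vector of symbols (subset of
#'   `symbols`) to connect as a path.
#' @param seed Integer seed.
#' @param taxon Taxon id stamped on records (default 9606).
#' @return Data.frame of interaction records (see [read_interactions()]).
#' @export
generate_interactome <- function(symbols, n_edges, planted_module = NULL,
                                 seed = 1, taxon = 9606L) {
  symbols <- toupper(symbols)
  ns <- length(symbols)
  max_edges <- choose(ns, 2)
  if (n_edges > max_edges) {
    stop(sprintf("n_edges = %d exceeds the %d possible pairs", n_edges, max_edges),
         call. = FALSE)
  }
  if (!is.null(planted_module)) {
    planted_module <- toupper(planted_module)
    if (!all(planted_module %in% symbols)) {
      stop("planted module contains symbols outside the universe", call. = FALSE)
    }
  }
  edges <- NULL
  if (n_edges > 0) {
    idx <- withr::with_seed(seed, sample(max_edges, n_edges))
    ij <- unrank_pairs(idx, ns)
    edges <- data.frame(a = symbols[ij[, 1]], b = symbols[ij[, 2]],
                        stringsAsFactors = FALSE)
  }
  if (!is.null(planted_module) && length(planted_module) >= 2) {
    m <- length(planted_module)
    path <- data.frame(a = planted_module[-m], b = planted_module[-1],
                       stringsAsFactors = FALSE)
    edges <- rbind(edges, path)
  }
  if (is.null(edges)) {
    edges <- data.frame(a = character(0), b = character(0))
  }
  pairs <- canonical_pairs(edges$a, edges$b)
  pairs <- pairs[!duplicated(paste(pairs$a, pairs$b, sep = "\r")), , drop = FALSE]
  n <- nrow(pairs)
  data.frame(symbol_a = pairs$a, symbol_b = pairs$b,
             organism_a = rep(taxon, n), organism_b = rep(taxon, n),
             system_type = rep("physical", n), stringsAsFactors = FALSE)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Builds `n_sets - 1` decoy sets drawn uniformly from the universe plus
#' one planted set (`SET_PLANTED`) containing exactly `planted_overlap`
#' members of `planted_query`, the rest drawn from outside the query.
#'
#' @param universe Character vector of gene symbols.
#' @param n_sets Total number of sets (>= 1).
#' @param set_size Members per set.
#' @param planted_query Symbols the planted set must overlap.
#' @param planted_overlap Exact overlap between the planted set and
#'   `planted_query`.
#' @param seed Integer seed.
#' @return A `gene_set_collection`; the planted set's name is attached
#'   as attribute `"planted"`.
#' @export
generate_gene_sets <- function(universe, n_sets, set_size, planted_query,
                               planted_overlap, seed = 1) {
  universe <- unique(toupper(universe))
  planted_query <- unique(toupper(planted_query))
  if (!all(planted_query %in% universe)) {
    stop("planted query contains symbols outside the universe", call. = FALSE)
  }
  if (planted_overlap > min(set_size, length(planted_query))) {
    stop("planted_overlap exceeds set_size or the planted query size",
         call. = FALSE)
  }
  outside <- setdiff(universe, planted_query)
  if (set_size - planted_overlap > length(outside)) {
    stop("universe too small to fill the planted set outside the query",
         call. = FALSE)
  }
  if (set_size > length(universe)) {
    stop("set_size exceeds the universe", call. = FALSE)
  }
  sets <- withr::with_seed(seed, {
    out <- list()
    if (n_sets > 1) {
      for (i in seq_len(n_sets - 1)) {
        out[[sprintf("SET_%03d", i)]] <-
          list(description = "decoy set",
               genes = sort(sample(universe, set_size)))
      }
    }
    out[["SET_PLANTED"]] <- list(
      description = "planted enriched set",
      genes = sort(c(sample(planted_query, planted_overlap),
                     sample(outside, set_size - planted_overlap)))
    )
    out
  })
  structure(sets, class = "gene_set_collection", planted = "SET_PLANTED")
}

#' Generate a qPCR Ct table with stable references and planted fold changes
#'
#' Reference genes are drawn around 20 cycles and target genes around 25
#' cycles (plausible assay ranges, configurable), with Normal noise on
#' the Ct scale. A planted fold change `f` shifts the Ct of that gene by
#' `-log2(f)` in every non-control animal, so noiseless data yields a
#' delta-delta-Ct ratio of exactly `f`. Defaults mirror a two-arm animal
#' study with 6 animals per group and an 80-gene panel plus 3 references.
#'
#' @param n_genes Number of target genes (default 80), excluding
#'   references.
#' @param group_sizes Named integer vector, group -> animal count
#'   (default control/treated, 6 each).
#' @param n_reference Number of reference genes (default 3).
#' @param planted Named numeric vector gene -> fold change; names must
#'   be target genes (e.g. `c(G01 = 2)`).
#' @param ct_noise_sd Ct noise SD in cycles (default 0.25).
#' @param control_group Label of the calibrator group (default the first
#'   group).
#' @param ref_ct,target_ct Baseline cycles for references and targets.
#' @param seed Integer seed.
#' @return A `ct_table`; planted fold changes are attached as attribute
#'   `"planted"`.
#' @export
generate_ct_table <- function(n_genes = 80,
                              group_sizes = c(CONTROL = 6L, TREATED = 6L),
                              n_reference = 3,
                              planted = numeric(0),
                              ct_noise_sd = 0.25,
                              control_group = names(group_sizes)[1],
                              ref_ct = 20, target_ct = 25,
                              seed = 1) {
  stopifnot(n_reference >= 1, length(group_sizes) >= 2)
  refs <- sprintf("REF%d", seq_len(n_reference))
  targets <- sprintf("G%03d", seq_len(n_genes))
  if (length(planted) > 0) {
    if (is.null(names(planted)) || !all(toupper(names(planted)) %in% targets)) {
      stop("planted genes must name non-reference target genes", call. = FALSE)
    }
    if (any(planted <= 0)) stop("planted fold changes must be > 0", call. = FALSE)
    names(planted) <- toupper(names(planted))
  }
  animals <- unlist(lapply(names(group_sizes), function(g) {
    sprintf("%s_A%02d", g, seq_len(group_sizes[[g]]))
  }))
  groups <- stats::setNames(rep(names(group_sizes), group_sizes), animals)
  genes <- c(refs, targets)
  ct <- withr::with_seed(seed, {
    base <- c(rep(ref_ct, n_reference), rep(target_ct, n_genes))
    matrix(stats::rnorm(length(genes) * length(animals), mean = base,
                        sd = ct_noise_sd),
           nrow = length(genes), dimnames = list(genes, animals))
  })
  noncontrol <- names(groups)[groups != control_group]
  for (g in names(planted)) {
    ct[g, noncontrol] <- ct[g, noncontrol] - log2(planted[[g]])
  }
  out <- ct_table(ct, groups, refs)
  attr(out, "planted") <- planted
  out
}

#' Serialize a synthetic-truth object to JSON
#'
#' @param truth A `synthetic_truth` (or any list of planted facts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a synthetic-truth JSON file
#'
#' @param path Path written by [write_truth()].
#' @return The truth list, class `synthetic_truth`.
#' @export
read_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "synthetic_truth")
}
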