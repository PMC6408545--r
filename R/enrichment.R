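# Hypergeometric over-representation with Benjamini-Hochberg control.

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more query genes inside a set of size
#' `K` when `n` genes are drawn without replacement from a universe of
#' size `N` (over-representation; depletion is out of scope).
#'
#' @param N Universe size.
#' @param K Gene-set size within the universe.
#' @param n Query size within the universe.
#' @param k Observed overlap.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; 1 when `k = 0`.
#' @examples
#' hypergeometric_pvalue(10, 5, 4, 4)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeometric_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop(sprintf("inconsistent hypergeometric counts: N=%d K=%d n=%d k=%d",
                 N, K, n, k), call. = FALSE)
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`q(i) = min_{j>=i} m * p(j) / j` in
#' sorted order, capped at 1), returned in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a query list by the
#' upper-tail hypergeometric test within an explicit universe, then
#' adjusts across all tested sets with Benjamini-Hochberg. Query symbols
#' outside the universe are dropped with a reported count. Sets are
#' restricted to `min_size <= K <= max_size` members within the universe
#' before testing (standard over-representation practice, preventing
#' degenerate p-values); the adjustment spans every size-passing set,
#' including those with zero overlap, but only sets overlapping the
#' query appear in the output.
#'
#' @param query Character vector of gene symbols.
#' @param sets A `gene_set_collection` (see [read_gene_sets()]).
#' @param universe Character vector of gene symbols defining the
#'   background (non-empty).
#' @param fdr Significance threshold on q-values (default 0.05).
#' @param min_size,max_size Set-size filter within the universe
#'   (defaults 5 and 2000).
#' @return Data.frame sorted by p ascending with columns `name`, `N`,
#'   `K`, `n`, `k`, `p`, `q`, `significant`, `overlap` (comma-joined
#'   symbols); attribute `"dropped_query"` counts query symbols outside
#'   the universe.
#' @export
enrich <- function(query, sets, universe, fdr = 0.05,
                   min_size = 5, max_size = 2000) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  query <- unique(toupper(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    message("enrich: dropped ", length(dropped),
            " query symbol(s) outside the universe")
  }
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)

  members <- lapply(sets, function(s) intersect(s$genes, universe))
  K <- lengths(members)
  keep <- K >= min_size & K <= max_size
  members <- members[keep]
  K <- K[keep]
  if (length(members) == 0) {
    res <- data.frame(name = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      overlap = character(0), stringsAsFactors = FALSE)
    attr(res, "dropped_query") <- length(dropped)
    return(res)
  }
  hits <- lapply(members, intersect, query)
  k <- lengths(hits)
  p <- vapply(seq_along(members), function(i) {
    hypergeometric_pvalue(N, K[[i]], n, k[[i]])
  }, numeric(1))
  q <- bh_adjust(p)
  res <- data.frame(
    name = names(members), N = N, K = as.integer(K), n = n,
    k = as.integer(k), p = p, q = q,
    significant = q <= fdr,
    overlap = vapply(hits, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  res <- res[res$k >= 1, , drop = FALSE]
  res <- res[order(res$p, res$name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_query") <- length(dropped)
  res
}
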