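# qPCR branch: delta-delta-Ct relative quantification and the
# rank-product permutation test.

#' Relative expression by the delta-delta-Ct method
#'
#' Per animal, the reference level is the arithmetic mean of the
#' reference-gene Ct values (equivalent to normalising expression by the
#' geometric average of the reference genes' `2^-Ct` levels). Then
#' `dCt = Ct - ref`, `ddCt = dCt - mean(dCt over control animals)` per
#' gene, and the relative expression ratio is `2^-ddCt`. Reference genes
#' are excluded from the output rows.
#'
#' @param ct A `ct_table` (see [ct_table()] / [read_ct_table()]).
#' @param control_group Group label of the calibrator animals.
#' @return Object of class `relative_expression`: `list(ratios, groups)`
#'   with `ratios` a genes x animals matrix of `2^-ddCt` values (> 0).
#' @examples
#' m <- rbind(REF1 = c(20, 20), G1 = c(25, 24))
#' colnames(m) <- c("a1", "a2")
#' x <- ct_table(m, c(a1 = "control", a2 = "treated"), "REF1")
#' ddct_relative_expression(x, "control")$ratios["G1", ]
#' @export
ddct_relative_expression <- function(ct, control_group) {
  stopifnot(inherits(ct, "ct_table"))
  control <- names(ct$groups)[ct$groups == control_group]
  if (length(control) == 0) {
    stop("control group '", control_group, "' has no animals", call. = FALSE)
  }
  refs <- ct$reference_genes
  ref_ct <- ct$ct[refs, , drop = FALSE]
  bad <- which(!is.finite(ref_ct), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("reference gene '%s' has no Ct for animal '%s'",
                 refs[bad[1, 1]], colnames(ref_ct)[bad[1, 2]]), call. = FALSE)
  }
  ref_mean <- colMeans(ref_ct)
  targets <- setdiff(rownames(ct$ct), refs)
  dct <- sweep(ct$ct[targets, , drop = FALSE], 2, ref_mean)
  ddct <- dct - rowMeans(dct[, control, drop = FALSE])
  structure(list(ratios = 2^(-ddct), groups = ct$groups),
            class = "relative_expression")
}

#' Two-class rank-product test with permutation p-values
#'
#' Forms every between-group pairwise comparison (one animal of
#' `group_a` against one of `group_b`), computes the per-gene expression
#' ratio of each pair (ranks are taken on log-ratios, which is
#' equivalent), and ranks genes within each comparison: ascending ratio
#' for the down-direction (rank 1 = most down in `group_a`) and
#' descending for the up-direction. The rank product of a gene is the
#' geometric mean of its ranks across comparisons, so values are
#' comparable across comparison counts; ties get average ranks.
#'
#' Significance: the null distribution is sampled by drawing, `n_perm`
#' times, an independent uniform rank per comparison and taking the
#' geometric mean; the p-value is the smoothed fraction
#' `(#\{null RP <= observed RP\} + 1) / (n_perm + 1)`. The same null
#' sample serves both directions (their null laws are identical). An
#' estimated false-positive proportion `pfp = p * n_genes / rank(RP)` is
#' reported per direction.
#'
#' @param expr A `relative_expression` object (or any list with a
#'   positive `ratios` matrix and `groups` vector).
#' @param group_a,group_b Group labels to compare (ratios are
#'   `group_a / group_b`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draw (required for
#'   reproducibility).
#' @return Data.frame with one row per gene: `gene`, `rp_up`, `p_up`,
#'   `pfp_up`, `rp_down`, `p_down`, `pfp_down`, `mean_ratio_a`,
#'   `mean_ratio_b` (geometric means), plus attribute `"n_comparisons"`.
#' @export
rank_product_test <- function(expr, group_a, group_b, n_perm = 10000, seed) {
  ratios <- expr$ratios
  groups <- expr$groups
  stopifnot(is.matrix(ratios), all(ratios > 0), n_perm >= 1)
  a <- names(groups)[groups == group_a]
  b <- names(groups)[groups == group_b]
  if (length(a) == 0) stop("no animals in group '", group_a, "'", call. = FALSE)
  if (length(b) == 0) stop("no animals in group '", group_b, "'", call. = FALSE)
  lg <- log2(ratios)
  genes <- rownames(ratios)
  n_genes <- length(genes)

  pairs <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  n_cmp <- nrow(pairs)
  ranks_up <- ranks_down <- matrix(NA_real_, n_genes, n_cmp)
  for (i in seq_len(n_cmp)) {
    lr <- lg[, pairs$a[i]] - lg[, pairs$b[i]]
    ranks_down[, i] <- rank(lr, ties.method = "average")
    ranks_up[, i] <- rank(-lr, ties.method = "average")
  }
  # geometric mean of ranks; clamp into the mathematical range [1, G]
  # (exp/log round-trips can overshoot by one ulp)
  geomean_ranks <- function(r) pmin(pmax(exp(rowMeans(log(r))), 1), n_genes)
  rp_up <- geomean_ranks(ranks_up)
  rp_down <- geomean_ranks(ranks_down)

  null_rp <- withr::with_seed(seed, {
    draws <- matrix(sample.int(n_genes, n_perm * n_cmp, replace = TRUE),
                    nrow = n_perm)
    sort(exp(rowMeans(log(draws))))
  })
  # findInterval on the sorted null counts values <= each observed RP;
  # nudge guards against floating-point inequality at exact ties
  eps <- 1e-9
  p_of <- function(rp) (findInterval(rp * (1 + eps), null_rp) + 1) / (n_perm + 1)
  p_up <- p_of(rp_up)
  p_down <- p_of(rp_down)

  gm <- function(cols) exp(rowMeans(lg[, cols, drop = FALSE]))
  res <- data.frame(
    gene = genes,
    rp_up = rp_up, p_up = p_up,
    pfp_up = p_up * n_genes / rank(rp_up, ties.method = "min"),
    rp_down = rp_down, p_down = p_down,
    pfp_down = p_down * n_genes / rank(rp_down, ties.method = "min"),
    mean_ratio_a = gm(a), mean_ratio_b = gm(b),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "n_comparisons") <- n_cmp
  res
}
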