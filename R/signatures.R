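# Rank-based signature engine: fold-change profiles, feature selection,
# subject signatures, enrichment-score distances, percentile similarity
# graph and popularity-based consensus signatures.

#' Fold-change profiles against the genewise dataset average
#'
#' Divides each sample's profile by a reference profile obtained as the
#' genewise average across the whole dataset. On the `linear` scale this
#' is `value / rowmean`; on the `log2` scale the same operation is the
#' difference `value - rowmean` (a ratio in log space).
#'
#' @param expr Numeric matrix, probes x samples (see
#'   [read_expression_matrix()]).
#' @param scale `"linear"` for intensity data (requires strictly positive
#'   genewise means) or `"log2"` for log-transformed data. No
#'   auto-detection is attempted.
#' @return Matrix of fold changes with the same dimnames as `expr` and
#'   attribute `"scale"`.
#' @export
fold_change_profiles <- function(expr, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(expr), is.numeric(expr))
  ref <- rowMeans(expr)
  if (scale == "linear") {
    bad <- which(ref <= 0)
    if (length(bad) > 0) {
      stop("zero or negative genewise mean for row(s): ",
           paste(utils::head(rownames(expr)[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    fc <- expr / ref
  } else {
    fc <- expr - ref
  }
  attr(fc, "scale") <- scale
  fc
}

# vectorised two-sample pooled-variance t-test over matrix rows;
# returns two-sided p-values, NA where the test is degenerate
# (zero pooled variance AND equal means)
row_t_pooled <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  p[se == 0 & m1 == m2] <- NA_real_
  p[se == 0 & m1 != m2] <- 0
  p
}

#' Select features separating group pairs by t-test
#'
#' For every feature and every contrast, a two-sample Student's t-test
#' with pooled variance (two-sided) is run on the fold-change values of
#' the two groups. The returned feature set is the union over contrasts
#' of features with p below `alpha`. Features with zero pooled variance
#' and equal group means carry no information and are excluded.
#'
#' @param fc Fold-change matrix from [fold_change_profiles()].
#' @param groups Named character vector sample id -> group label.
#' @param contrasts List of length-2 character vectors naming group pairs,
#'   e.g. `list(c("T2DM_CTRL", "NONT2DM_CTRL"))`.
#' @param alpha Per-test significance threshold (default 0.01).
#' @return Character vector of selected feature ids in matrix row order,
#'   with a `"pvalues"` attribute (features x contrasts matrix).
#' @export
select_features <- function(fc, groups, contrasts, alpha = 0.01) {
  stopifnot(is.matrix(fc), length(contrasts) >= 1, alpha > 0, alpha < 1)
  known <- unique(groups)
  unknown <- setdiff(unlist(contrasts), known)
  if (length(unknown) > 0) {
    stop("contrast names unknown group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pmat <- matrix(NA_real_, nrow = nrow(fc), ncol = length(contrasts),
                 dimnames = list(rownames(fc),
                                 vapply(contrasts, paste, "", collapse = "_vs_")))
  sel <- logical(nrow(fc))
  for (ci in seq_along(contrasts)) {
    ct <- contrasts[[ci]]
    a <- intersect(names(groups)[groups == ct[1]], colnames(fc))
    b <- intersect(names(groups)[groups == ct[2]], colnames(fc))
    if (length(a) < 2 || length(b) < 2) {
      stop(sprintf("contrast %s vs %s needs >=2 samples per group", ct[1], ct[2]),
           call. = FALSE)
    }
    p <- row_t_pooled(fc[, a, drop = FALSE], fc[, b, drop = FALSE])
    pmat[, ci] <- p
    sel <- sel | (!is.na(p) & p < alpha)
  }
  out <- rownames(fc)[sel]
  attr(out, "pvalues") <- pmat
  out
}

#' Extract the rank signature of one sample
#'
#' Ranks the supplied features by fold change, descending, with ties
#' broken by feature id ascending (deterministic across platforms). The
#' signature is the list of the first `n1` (up) and the last `n2` (down)
#' features in that ranking; the down-list keeps ranking order, so its
#' last element is the most down-regulated feature.
#'
#' @param profile Named numeric vector: one sample's fold changes over
#'   the selected features.
#' @param n1,n2 Signature half-lengths (defaults 100 and 100).
#' @param sample Optional sample identifier stored in the signature.
#' @return An object of class `subject_signature`:
#'   `list(sample, up, down, ranked)` where `ranked` is the full ranked
#'   feature list.
#' @export
extract_signature <- function(profile, n1 = 100, n2 = 100, sample = NA_character_) {
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  g <- length(profile)
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be positive", call. = FALSE)
  if (n1 + n2 > g) {
    stop(sprintf("n1 + n2 = %d exceeds the %d available features", n1 + n2, g),
         call. = FALSE)
  }
  ord <- order(-profile, names(profile), method = "radix")
  ranked <- names(profile)[ord]
  structure(
    list(sample = sample,
         up = ranked[seq_len(n1)],
         down = ranked[seq.int(g - n2 + 1L, g)],
         ranked = ranked),
    class = "subject_signature"
  )
}

#' Extract signatures for every sample of a fold-change matrix
#'
#' @param fc Fold-change matrix.
#' @param features Feature ids to rank (e.g. from [select_features()]).
#' @param n1,n2 Signature half-lengths.
#' @return Named list of `subject_signature` objects, one per sample.
#' @export
extract_signatures <- function(fc, features, n1 = 100, n2 = 100) {
  stopifnot(all(features %in% rownames(fc)))
  sub <- fc[features, , drop = FALSE]
  sigs <- lapply(colnames(sub), function(s) {
    extract_signature(sub[, s], n1 = n1, n2 = n2, sample = s)
  })
  stats::setNames(sigs, colnames(sub))
}

#' Enrichment score of a feature set against a ranked list
#'
#' Walks the ranked list accumulating a running sum that adds `1/|S|` at
#' members of `set` and subtracts `1/(G - |S|)` elsewhere, and returns
#' the signed value of the sum at its largest absolute excursion (the
#' classic unweighted Kolmogorov-Smirnov enrichment score). A set
#' concentrated at the top scores near +1, at the bottom near -1.
#'
#' @param ranked Character vector: the full ranked feature list.
#' @param set Character vector: the feature set (must be a strict,
#'   non-empty subset of `ranked`).
#' @return Scalar in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, set) {
  g <- length(ranked)
  s <- length(set)
  if (s == 0 || s >= g) {
    stop("set must be a non-empty strict subset of the ranked list", call. = FALSE)
  }
  hit <- ranked %in% set
  if (sum(hit) != s) {
    stop("set contains features absent from the ranked list", call. = FALSE)
  }
  cs <- cumsum(ifelse(hit, 1 / s, -1 / (g - s)))
  cs[which.max(abs(cs))]
}

#' Enrichment-score distance between two subject signatures
#'
#' Each signature's up- and down-list is scored against the other
#' subject's full ranking; the four scores are symmetrised into
#' `similarity = (ES(upA, R_B) - ES(downA, R_B) + ES(upB, R_A) -
#' ES(downB, R_A)) / 4`, which lies in `[-1, 1]`, and the distance is
#' `1 - similarity` in `[0, 2]`. Identical signatures and rankings give
#' 0; perfectly reversed profiles give 2.
#'
#' @param sig_a,sig_b `subject_signature` objects defined over the same
#'   feature universe.
#' @return Scalar distance in `[0, 2]`.
#' @export
signature_distance <- function(sig_a, sig_b) {
  if (length(sig_a$ranked) != length(sig_b$ranked) ||
      !setequal(sig_a$ranked, sig_b$ranked)) {
    stop("signatures are defined over different feature universes", call. = FALSE)
  }
  sim <- (enrichment_score(sig_b$ranked, sig_a$up) -
          enrichment_score(sig_b$ranked, sig_a$down) +
          enrichment_score(sig_a$ranked, sig_b$up) -
          enrichment_score(sig_a$ranked, sig_b$down)) / 4
  1 - sim
}

#' All-to-all signature distance matrix
#'
#' @param signatures Named list of `subject_signature` objects (>= 2).
#' @return Symmetric numeric matrix with zero diagonal; dimnames are the
#'   sample ids.
#' @export
distance_matrix <- function(signatures) {
  n <- length(signatures)
  if (n < 2) stop("need at least 2 signatures", call. = FALSE)
  ids <- vapply(signatures, function(s) s$sample, character(1))
  if (anyNA(ids)) ids <- names(signatures)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- signature_distance(signatures[[i]], signatures[[j]])
    }
  }
  d
}

#' Similarity graph from the bottom k% of distances
#'
#' The threshold is the k-th percentile (linear interpolation, the
#' default quantile definition in R) of the strictly-upper-triangle
#' distances; samples are connected whenever their distance does not
#' exceed it. Ties at the threshold are included.
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param k Percentile in `(0, 100]` (default 10, i.e. the bottom 10%
#'   of distances).
#' @return List of class `similarity_graph`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `distance`), `threshold`, `k`.
#' @export
similarity_graph <- function(d, k = 10) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2) stop("need at least 2 samples to build a graph", call. = FALSE)
  if (k <= 0 || k > 100) stop("k must lie in (0, 100]", call. = FALSE)
  ut <- d[upper.tri(d)]
  thr <- unname(stats::quantile(ut, probs = k / 100, type = 7))
  idx <- which(upper.tri(d) & d <= thr, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(d)[idx[, 1]],
    to = colnames(d)[idx[, 2]],
    distance = d[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = rownames(d), edges = edges, threshold = thr, k = k),
            class = "similarity_graph")
}

# popularity table for a list of ordered feature lists:
# count = number of lists containing the feature,
# mean_pos = mean 1-based position within those lists
popularity_table <- function(lists) {
  feat <- unlist(lists, use.names = FALSE)
  pos <- unlist(lapply(lists, seq_along), use.names = FALSE)
  count <- rowsum(rep(1L, length(feat)), feat)
  mean_pos <- rowsum(pos, feat) / count
  data.frame(feature = rownames(count),
             count = as.integer(count),
             mean_pos = as.numeric(mean_pos),
             stringsAsFactors = FALSE)
}

#' Consensus signature of a group of subjects
#'
#' Collects the features appearing in at least one subject signature of
#' the group and scores each by its popularity (the number of subject
#' up- or down-lists containing it). The consensus up-list is the `n1`
#' most popular up features, ties broken by smaller mean position within
#' the up-lists (closer to the top), then by feature id; the consensus
#' down-list is symmetric (`n2` features, ties by larger mean position
#' within the down-lists, i.e. closer to the extreme). The full
#' popularity tables are retained.
#'
#' The two lists are kept disjoint so the consensus names exactly
#' `n1 + n2` distinct probes: a feature qualifying for both directions
#' (possible because a mid-ranked feature may fall in different lists
#' across subjects) is assigned to the direction where its popularity is
#' higher (ties go up), and the other list back-fills from its next
#' candidates.
#'
#' @param signatures List of `subject_signature` objects from one group.
#' @param n1,n2 Consensus half-lengths.
#' @param group Optional group label stored in the result.
#' @return Object of class `consensus_signature`: `list(group, up, down,
#'   up_popularity, down_popularity)`; `up_popularity` and
#'   `down_popularity` are data.frames (`feature`, `count`, `mean_pos`)
#'   sorted in consensus order.
#' @export
consensus_signature <- function(signatures, n1 = 100, n2 = 100,
                                group = NA_character_) {
  if (length(signatures) < 1) stop("need at least one signature", call. = FALSE)
  up_tab <- popularity_table(lapply(signatures, function(s) s$up))
  down_tab <- popularity_table(lapply(signatures, function(s) s$down))
  if (nrow(up_tab) < n1) {
    stop(sprintf("only %d distinct up features across the group; n1 = %d",
                 nrow(up_tab), n1), call. = FALSE)
  }
  if (nrow(down_tab) < n2) {
    stop(sprintf("only %d distinct down features across the group; n2 = %d",
                 nrow(down_tab), n2), call. = FALSE)
  }
  up_tab <- up_tab[order(-up_tab$count, up_tab$mean_pos, up_tab$feature), ]
  down_tab <- down_tab[order(-down_tab$count, -down_tab$mean_pos, down_tab$feature), ]
  rownames(up_tab) <- rownames(down_tab) <- NULL

  # resolve features qualifying for both directions, then refill
  up_pool <- up_tab
  down_pool <- down_tab
  repeat {
    if (nrow(up_pool) < n1 || nrow(down_pool) < n2) {
      stop("consensus lists cannot be made disjoint: too few distinct features",
           call. = FALSE)
    }
    up_sel <- up_pool$feature[seq_len(n1)]
    down_sel <- down_pool$feature[seq_len(n2)]
    both <- intersect(up_sel, down_sel)
    if (length(both) == 0) break
    up_count <- up_pool$count[match(both, up_pool$feature)]
    down_count <- down_pool$count[match(both, down_pool$feature)]
    to_up <- both[up_count >= down_count]
    to_down <- both[up_count < down_count]
    up_pool <- up_pool[!up_pool$feature %in% to_down, , drop = FALSE]
    down_pool <- down_pool[!down_pool$feature %in% to_up, , drop = FALSE]
  }

  structure(
    list(group = group,
         up = up_sel,
         # down-lists put the most down-regulated feature last, so the
         # consensus down-list is reversed into the same convention
         down = rev(down_sel),
         up_popularity = up_tab,
         down_popularity = down_tab),
    class = "consensus_signature"
  )
}
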