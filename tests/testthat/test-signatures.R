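test_that("fold-change profiles divide by the genewise average", {
  m <- matrix(c(4, 2, 5, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fc <- fold_change_profiles(m, scale = "linear")
  expect_equal(unname(fc["g1", ]), c(4 / 3, 2 / 3))

  lg <- fold_change_profiles(m, scale = "log2")
  expect_equal(unname(lg["g2", ]), c(-1, 1))

  # single-sample reference equals the profile -> all ratios 1 / diffs 0
  one <- cbind(s1 = c(g1 = 2, g2 = 8), s2 = c(2, 8))
  expect_true(all(fold_change_profiles(one, "linear") == 1))
  expect_true(all(fold_change_profiles(one, "log2") == 0))

  m0 <- m; m0["g1", ] <- c(1, -1)
  expect_error(fold_change_profiles(m0, "linear"), "g1")
})

test_that("feature selection unions contrasts and handles degenerate rows", {
  set.seed(101)
  n <- 5
  groups <- setNames(rep(c("A", "B"), each = n),
                     c(paste0("a", 1:n), paste0("b", 1:n)))
  # f_sep: means 10 SDs apart; f_flat: identical values (degenerate);
  # f_null: pure noise
  fc <- rbind(
    f_sep = c(rnorm(n, 10, 1), rnorm(n, 0, 1)),
    f_flat = rep(1, 2 * n),
    f_null = rnorm(2 * n)
  )
  colnames(fc) <- names(groups)
  sel <- select_features(fc, groups, list(c("A", "B")), alpha = 0.01)
  expect_true("f_sep" %in% sel)
  expect_false("f_flat" %in% sel)

  # the p-value matches an independent t-distribution computation
  p <- attr(sel, "pvalues")["f_sep", 1]
  tt <- t.test(fc["f_sep", 1:n], fc["f_sep", n + 1:n], var.equal = TRUE)
  expect_equal(p, tt$p.value)

  expect_error(select_features(fc, groups, list(c("A", "Z"))), "Z")
})

test_that("signature extraction ranks descending with id tie-break", {
  prof <- c(e = 1, d = 2, c = 3, b = 4, a = 5)
  sig <- extract_signature(prof, n1 = 2, n2 = 1, sample = "x")
  expect_equal(sig$up, c("a", "b"))
  expect_equal(sig$down, "e")
  expect_equal(sig$ranked, c("a", "b", "c", "d", "e"))

  tied <- c(z2 = 5, z1 = 5, y = 1)
  expect_equal(extract_signature(tied, 1, 1)$up, "z1")  # smaller id first

  expect_error(extract_signature(prof, 3, 3), "exceeds")
})

test_that("enrichment score matches the step-by-step oracle on a 6-feature toy", {
  ranked <- c("f1", "f2", "f3", "f4", "f5", "f6")
  for (set in list("f1", "f6", "f3", c("f2", "f5"), c("f1", "f2", "f3"))) {
    expect_equal(enrichment_score(ranked, set),
                 oracle_enrichment_score(ranked, set),
                 info = paste(set, collapse = ","))
  }
  # hit-position invariance: permuting non-members among themselves
  # (hit positions 1 and 3 in both rankings) leaves the score unchanged
  expect_equal(enrichment_score(c("f2", "f4", "f3", "f1"), c("f2", "f3")),
               enrichment_score(c("f2", "f1", "f3", "f4"), c("f2", "f3")))
})

test_that("signature distance hits both extremes and matches a hand enumeration", {
  ranked <- paste0("f", 1:6)
  a <- make_signature(ranked, 1, 1, "a")
  expect_equal(signature_distance(a, a), 0)

  b <- make_signature(rev(ranked), 1, 1, "b")
  expect_equal(signature_distance(a, b), 2)

  # G=6, |up|=|down|=1, a mixed pair checked against the brute oracle
  c_sig <- make_signature(c("f2", "f1", "f4", "f6", "f3", "f5"), 1, 1, "c")
  sim <- (oracle_enrichment_score(c_sig$ranked, a$up) -
          oracle_enrichment_score(c_sig$ranked, a$down) +
          oracle_enrichment_score(a$ranked, c_sig$up) -
          oracle_enrichment_score(a$ranked, c_sig$down)) / 4
  expect_equal(signature_distance(a, c_sig), 1 - sim)

  d_sig <- make_signature(paste0("g", 1:6), 1, 1, "d")
  expect_error(signature_distance(a, d_sig), "universe")
})

test_that("distance matrix is symmetric, zero-diagonal, bounded, and consistent", {
  set.seed(7)
  feats <- paste0("f", 1:30)
  sigs <- lapply(1:5, function(i) {
    make_signature(sample(feats), 4, 4, paste0("s", i))
  })
  names(sigs) <- paste0("s", 1:5)
  d <- distance_matrix(sigs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d["s2", "s4"], signature_distance(sigs$s2, sigs$s4))

  same <- list(a = make_signature(feats, 3, 3, "a"),
               b = make_signature(feats, 3, 3, "b"))
  expect_equal(unname(distance_matrix(same)), matrix(0, 2, 2))
})

test_that("similarity graph thresholds at the interpolated percentile", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[upper.tri(d)] <- c(1, 2, 3, 4, 5, 6)
  d <- d + t(d)
  g <- similarity_graph(d, k = 10)
  expect_equal(g$threshold, 1.5)  # quantile(1:6, 0.1), linear interpolation
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$distance, 1)

  expect_equal(nrow(similarity_graph(d, k = 100)$edges), 6L)  # complete

  tie <- matrix(0.5, 3, 3, dimnames = list(1:3, 1:3)); diag(tie) <- 0
  expect_equal(nrow(similarity_graph(tie, k = 10)$edges), 3L)  # ties included

  expect_error(similarity_graph(d[1, 1, drop = FALSE], 10), "2 samples")
  expect_error(similarity_graph(d, 0), "0, 100")
})

test_that("consensus ranks by popularity with mean-rank tie-breaks", {
  mk <- function(ranked, id) make_signature(ranked, 2, 2, id)
  # g in all three up-lists, h in one
  s1 <- mk(c("g", "h", "x1", "x2", "d1", "d2"), "s1")
  s2 <- mk(c("g", "x3", "x1", "x2", "d1", "d2"), "s2")
  s3 <- mk(c("x3", "g", "x1", "x2", "d2", "d1"), "s3")
  cs <- consensus_signature(list(s1, s2, s3), n1 = 2, n2 = 2, group = "G")
  expect_equal(cs$up[1], "g")   # popularity 3 beats everything
  expect_true("h" %in% cs$up_popularity$feature)
  expect_equal(cs$up_popularity$count[cs$up_popularity$feature == "g"], 3L)
  # x3 (2 up-lists) outranks h (1)
  expect_true(which(cs$up_popularity$feature == "x3") <
              which(cs$up_popularity$feature == "h"))

  # one subject: consensus equals that subject's signature
  solo <- consensus_signature(list(s1), n1 = 2, n2 = 2)
  expect_equal(solo$up, s1$up)
  expect_equal(solo$down, s1$down)

  expect_error(consensus_signature(list(s1), n1 = 5, n2 = 2), "n1")
})
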