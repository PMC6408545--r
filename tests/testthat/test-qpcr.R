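test_that("delta-delta-Ct reproduces the hand-worked toy", {
  # refs (20, 22, 21) -> reference mean 21; control target Ct 25
  # (dCt 4), treated Ct 24 (dCt 3) -> ddCt -1 -> ratio 2
  m <- rbind(REF1 = c(20, 20), REF2 = c(22, 22), REF3 = c(21, 21),
             TARGET = c(25, 24))
  colnames(m) <- c("ctrl1", "trt1")
  x <- ct_table(m, c(ctrl1 = "control", trt1 = "treated"),
                c("REF1", "REF2", "REF3"))
  rel <- ddct_relative_expression(x, "control")
  expect_equal(unname(rel$ratios["TARGET", "trt1"]), 2)
  expect_equal(unname(rel$ratios["TARGET", "ctrl1"]), 1)
  expect_false(any(rownames(rel$ratios) %in% x$reference_genes))
})

test_that("identical animals give all-one ratios; NA reference is fatal", {
  m <- matrix(rep(c(20, 25, 27), 3), nrow = 3,
              dimnames = list(c("REF1", "G1", "G2"), c("a1", "a2", "a3")))
  x <- ct_table(m, c(a1 = "c", a2 = "t", a3 = "t"), "REF1")
  rel <- ddct_relative_expression(x, "c")
  expect_true(all(rel$ratios == 1))

  x$ct["REF1", "a2"] <- NA_real_  # bypasses the constructor on purpose
  expect_error(ddct_relative_expression(x, "c"), "REF1.*a2")
  expect_error(ddct_relative_expression(
    ct_table(m, c(a1 = "c", a2 = "t", a3 = "t"), "REF1"), "missing"),
    "missing")
})

test_that("rank product attains its minimum for a consistently top gene", {
  ratios <- rbind(UP = c(8, 8, 1, 1),
                  MID = c(1.1, 0.9, 1, 1),
                  DOWN = c(0.2, 0.3, 1, 1))
  colnames(ratios) <- c("a1", "a2", "b1", "b2")
  rel <- structure(list(ratios = ratios,
                        groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")),
                   class = "relative_expression")
  rp <- rank_product_test(rel, "A", "B", n_perm = 500, seed = 1)
  expect_equal(attr(rp, "n_comparisons"), 4L)
  expect_equal(rp$rp_up[rp$gene == "UP"], 1)      # rank 1 in all comparisons
  expect_equal(rp$rp_down[rp$gene == "DOWN"], 1)
  expect_true(all(rp$rp_up >= 1 & rp$rp_up <= 3))

  expect_error(rank_product_test(rel, "A", "Z", 10, 1), "Z")
})

test_that("permutation p converges to the exhaustive null (1 comparison)", {
  # 3 genes, |A| = |B| = 1: P(RP_up <= 1) = 1/3 exactly
  ratios <- rbind(G1 = c(4, 1), G2 = c(2, 1), G3 = c(0.5, 1))
  colnames(ratios) <- c("a1", "b1")
  rel <- list(ratios = ratios, groups = c(a1 = "A", b1 = "B"))
  rp <- rank_product_test(rel, "A", "B", n_perm = 10000, seed = 42)
  exact <- oracle_rank_product_null(3, 1, 1)
  expect_equal(exact, 1 / 3)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(rp$p_up[rp$gene == "G1"] - exact), 3 * se + 2e-4)
})

test_that("permutation p converges to the exhaustive null (2 comparisons)", {
  # 3 genes, two independent comparisons: P(RP = 1) = 1/9 for a fixed gene
  ratios <- rbind(G1 = c(4, 5, 1), G2 = c(2, 3, 1), G3 = c(0.5, 0.25, 1))
  colnames(ratios) <- c("a1", "a2", "b1")
  rel <- list(ratios = ratios, groups = c(a1 = "A", a2 = "A", b1 = "B"))
  rp <- rank_product_test(rel, "A", "B", n_perm = 10000, seed = 42)
  exact <- oracle_rank_product_null(3, 2, 1)
  expect_equal(exact, 1 / 9)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(rp$p_up[rp$gene == "G1"] - exact), 3 * se + 2e-4)

  # 4 genes, 2 comparisons, intermediate observed RP
  ratios4 <- rbind(G1 = c(4, 0.5, 1), G2 = c(2, 3, 1),
                   G3 = c(0.5, 2, 1), G4 = c(0.1, 0.2, 1))
  colnames(ratios4) <- colnames(ratios)
  rel4 <- list(ratios = ratios4, groups = rel$groups)
  rp4 <- rank_product_test(rel4, "A", "B", n_perm = 10000, seed = 9)
  for (g in rp4$gene) {
    exact_g <- oracle_rank_product_null(4, 2, rp4$rp_up[rp4$gene == g])
    se_g <- sqrt(exact_g * (1 - exact_g) / 10000)
    expect_lt(abs(rp4$p_up[rp4$gene == g] - exact_g), 3 * se_g + 2e-4,
              label = paste("gene", g))
  }
})

test_that("permutation p-values depend on ranks only", {
  set.seed(5)
  ratios <- matrix(2^rnorm(60), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("an", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(ratios))
  rel <- list(ratios = ratios, groups = groups)
  rp1 <- rank_product_test(rel, "A", "B", n_perm = 1000, seed = 3)
  # a monotone transform of the expression values changes nothing
  rel2 <- list(ratios = ratios^3, groups = groups)
  rp2 <- rank_product_test(rel2, "A", "B", n_perm = 1000, seed = 3)
  expect_equal(rp1$rp_up, rp2$rp_up)
  expect_equal(rp1$p_up, rp2$p_up)
  expect_equal(rp1$p_down, rp2$p_down)

  # gene relabeling permutes rows without changing values
  perm <- sample(nrow(ratios))
  rel3 <- list(ratios = ratios[perm, ], groups = groups)
  rp3 <- rank_product_test(rel3, "A", "B", n_perm = 1000, seed = 3)
  expect_equal(rp3$p_up[match(rp1$gene, rp3$gene)], rp1$p_up)
})

test_that("planted 2-fold qPCR genes rise to the top of RP_up", {
  ct <- generate_ct_table(seed = 42,
                          planted = setNames(rep(2, 5), sprintf("G%03d", 1:5)))
  rel <- ddct_relative_expression(ct, "CONTROL")
  rp <- rank_product_test(rel, "TREATED", "CONTROL", n_perm = 2000, seed = 42)
  top10 <- rp$gene[order(rp$rp_up)][1:10]
  expect_true(all(sprintf("G%03d", 1:5) %in% top10))
})
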