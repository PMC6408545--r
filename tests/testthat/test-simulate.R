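test_that("expression generator is deterministic and plants disjoint sets", {
  gs <- c(A = 4L, B = 4L)
  d1 <- generate_expression_dataset(n_features = 100, group_sizes = gs,
                                    planted_per_group = 5, seed = 42)
  d2 <- generate_expression_dataset(n_features = 100, group_sizes = gs,
                                    planted_per_group = 5, seed = 42)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth, d2$truth)

  planted <- unlist(c(d1$truth$planted_up, d1$truth$planted_down))
  expect_equal(anyDuplicated(planted), 0L)
  expect_true(all(planted %in% rownames(d1$expression)))
  expect_true(all(d1$expression > 0))  # linear scale by exponentiation
  expect_equal(ncol(d1$expression), 8L)
  expect_equal(as.vector(table(d1$groups)[c("A", "B")]), c(4L, 4L))

  expect_error(generate_expression_dataset(n_features = 10, group_sizes = gs,
                                           planted_per_group = 5),
               "plant")
})

test_that("null data yields roughly alpha x n_features selections", {
  gs <- c(A = 10L, B = 10L)
  d <- generate_expression_dataset(n_features = 2000, group_sizes = gs,
                                   planted_per_group = 0, effect_size = 0,
                                   scale = "log2", seed = 7)
  fc <- fold_change_profiles(d$expression, "log2")
  sel <- select_features(fc, d$groups, list(c("A", "B")), alpha = 0.01)
  # Bin(2000, 0.01): mean 20, sd ~4.4; allow 5 sd
  expect_gt(length(sel), 0)
  expect_lt(abs(length(sel) - 20), 23)
})

test_that("t-test power at the planted effect matches the noncentral oracle", {
  # planted effect 2 SD, n = 10 per group: power of the two-sided pooled
  # t-test at alpha 0.01 from the noncentral t distribution
  ncp <- 2 / sqrt(1 / 10 + 1 / 10)
  crit <- qt(1 - 0.01 / 2, df = 18)
  power <- 1 - pt(crit, 18, ncp) + pt(-crit, 18, ncp)

  gs <- c(A = 10L, B = 10L, C = 10L, D = 10L)
  hits <- 0; total <- 0
  for (s in 1:3) {
    d <- generate_expression_dataset(n_features = 2000, group_sizes = gs,
                                     planted_per_group = 10, effect_size = 2,
                                     scale = "log2", seed = 40 + s)
    fc <- fold_change_profiles(d$expression, "log2")
    sel <- select_features(fc, d$groups,
                           list(c("A", "B"), c("C", "D")), alpha = 0.01)
    planted_ab <- c(d$truth$planted_up$A, d$truth$planted_down$A,
                    d$truth$planted_up$B, d$truth$planted_down$B)
    hits <- hits + sum(planted_ab %in% sel)
    total <- total + length(planted_ab)
  }
  # observed recovery within 4 binomial SDs of the theoretical power
  se <- sqrt(power * (1 - power) / total)
  expect_lt(abs(hits / total - power), 4 * se + 0.01)
})

test_that("interactome generator makes distinct physical human pairs", {
  syms <- paste0("G", 1:25)
  rec <- generate_interactome(syms, n_edges = 80, seed = 1)
  expect_equal(nrow(rec), 80L)
  expect_true(all(rec$system_type == "physical"))
  expect_true(all(rec$organism_a == 9606L & rec$organism_b == 9606L))
  expect_true(all(rec$symbol_a != rec$symbol_b))
  keys <- paste(pmin(rec$symbol_a, rec$symbol_b),
                pmax(rec$symbol_a, rec$symbol_b))
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(rec, generate_interactome(syms, n_edges = 80, seed = 1))

  expect_equal(nrow(generate_interactome(syms, 0, seed = 1)), 0L)
  expect_error(generate_interactome(syms, 1000, seed = 1), "exceeds")

  # a planted module is reachable by 1-step expansion from any member
  mod <- c("G1", "G5", "G9")
  rec2 <- generate_interactome(syms, 30, planted_module = mod, seed = 2)
  net <- expand_seed_network(build_interactome(rec2), "G5")
  expect_true(all(c("G1", "G9") %in% net$nodes))
})

test_that("gene-set generator plants the promised overlap", {
  uni <- sprintf("U%03d", 1:200)
  q <- uni[1:30]
  sets <- generate_gene_sets(uni, n_sets = 10, set_size = 15,
                             planted_query = q, planted_overlap = 8, seed = 7)
  expect_equal(length(sets), 10L)
  planted <- sets[[attr(sets, "planted")]]
  expect_equal(length(intersect(planted$genes, q)), 8L)
  expect_identical(
    sets, generate_gene_sets(uni, 10, 15, q, 8, seed = 7))
  expect_error(generate_gene_sets(uni, 10, 15, q, 20, seed = 1), "overlap")
})

test_that("Ct generator plants exact fold changes in the noiseless limit", {
  ct <- generate_ct_table(n_genes = 10, ct_noise_sd = 0,
                          planted = c(G003 = 2), seed = 1)
  rel <- ddct_relative_expression(ct, "CONTROL")
  treated <- names(ct$groups)[ct$groups == "TREATED"]
  expect_equal(unname(rel$ratios["G003", treated]),
               rep(2, length(treated)))
  other <- setdiff(rownames(rel$ratios), "G003")
  expect_true(all(abs(rel$ratios[other, ] - 1) < 1e-12))

  expect_identical(generate_ct_table(seed = 5)$ct,
                   generate_ct_table(seed = 5)$ct)
  expect_error(generate_ct_table(planted = c(REF1 = 2)), "non-reference")
})

test_that("truth files round-trip through JSON", {
  d <- generate_expression_dataset(n_features = 50,
                                   group_sizes = c(A = 3L, B = 3L),
                                   planted_per_group = 2, seed = 9)
  f <- tempfile(fileext = ".json")
  write_truth(d$truth, f)
  back <- read_truth(f)
  expect_equal(back$planted_up, d$truth$planted_up)
  expect_equal(back$planted_down, d$truth$planted_down)
  expect_equal(back$seed, d$truth$seed)
  expect_equal(back$params$effect_size, d$truth$params$effect_size)
})
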