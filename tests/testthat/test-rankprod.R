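test_that("fold change follows the signed ratio convention", {
  fc <- fold_change(tiny_expr(), tiny_groups, "a", "b")
  expect_equal(unname(fc["g1"]), 4)
  expect_equal(unname(fc["g2"]), -4)
  expect_equal(unname(fc["g3"]), 1)
  expect_error(fold_change(tiny_expr(), tiny_groups, "a", "c"),
               "no samples")
})

test_that("rank product equals the geometric mean of pairwise ranks", {
  # one A replicate, two B replicates -> K = 2 comparisons with up-ranks
  # (1,2), (2,1), (3,3): RP_up = (sqrt(2), sqrt(2), 3)
  m <- rbind(g1 = c(1, 10, 5),
             g2 = c(1, 5, 10),
             g3 = c(1, 1, 1))
  colnames(m) <- c("a1", "b1", "b2")
  rp <- rank_product(m, c("a", "b", "b"), "a", "b", "up")
  expect_equal(unname(rp), c(sqrt(2), sqrt(2), 3), tolerance = 1e-12)
  # a gene most up-regulated in every comparison has RP 1
  sim <- simulate_expression(small_config(seed = 2, n_de = 0,
                                          n_cluster = 0))
  ex <- sim$expr
  ex["g00001", sim$groups == "group2"] <- ex["g00001", sim$groups == "group2"] * 1e6
  rp1 <- rank_product(ex, sim$groups, "group1", "group2", "up")
  expect_equal(unname(rp1["g00001"]), 1)
  # all genes identical in both groups: every rank tied, all RP equal
  flat <- matrix(5, nrow = 4, ncol = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  rpf <- rank_product(flat, c("a", "a", "b", "b"), "a", "b", "up")
  expect_true(all(rpf == rpf[1]))
})

test_that("relabelling the groups swaps up and down rank products exactly", {
  sim <- simulate_expression(small_config(seed = 6, n_genes = 300))
  up_ab <- rank_product(sim$expr, sim$groups, "group1", "group2", "up")
  down_ba <- rank_product(sim$expr, sim$groups, "group2", "group1", "down")
  expect_equal(up_ab, down_ba, tolerance = 1e-12)
})

test_that("BH correction matches the min-over-suffix oracle and is monotone", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  # raising one raw p never lowers its q
  p <- runif(15)
  for (i in c(1, 7, 15)) {
    p2 <- p
    p2[i] <- min(1, p[i] + 0.2)
    expect_gte(bh_fdr(p2)[i], bh_fdr(p)[i])
  }
})

test_that("permutation p-values are deterministic and floor correctly", {
  sim <- simulate_expression(small_config(seed = 3, n_genes = 200))
  a <- rank_product_pvalues(sim$expr, sim$groups, "group1", "group2",
                            n_perm = 50, seed = 7)
  b <- rank_product_pvalues(sim$expr, sim$groups, "group1", "group2",
                            n_perm = 50, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$p_up > 0 & a$p_up <= 1))
  expect_true(all(a$rp_up >= 1 & a$rp_down >= 1))
})

test_that("independent-rank null reproduces the closed-form minimum", {
  # K = 2 comparisons, G = 10 genes: P(null RP <= 1) = (1/G)^K = 0.01,
  # so a gene with observed RP = 1 gets p near 0.01 under null="ranks"
  G <- 10
  m <- matrix(exp(rnorm(G * 3, 5, 0.3)), nrow = G,
              dimnames = list(sprintf("g%02d", 1:G), c("a1", "b1", "b2")))
  m[1, 2:3] <- m[1, 2:3] * 1e6  # top-ranked in both comparisons
  pv <- rank_product_pvalues(m, c("a", "b", "b"), "a", "b",
                             n_perm = 2000, seed = 11, null = "ranks")
  expect_equal(unname(pv$rp_up[1]), 1)
  expect_lt(abs(pv$p_up[1] - 0.01), 0.004)
})

test_that("label-permutation p-values are uniform under the null", {
  cfg <- simulation_config(seed = 11, n_genes = 10000, n_de_genes = 0,
                           noise_cv = 0.2,
                           cluster_spec = list(arm = "3L", start = 8.5e6,
                                               width = 5e5, n_genes = 0))
  sim <- simulate_expression(cfg)
  pv <- rank_product_pvalues(sim$expr, sim$groups, "group1", "group2",
                             n_perm = 100, seed = 12)
  ks <- suppressWarnings(ks.test(pv$p_up, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  # combined per-gene p is calibrated in the rejection tail and the
  # BH-corrected calls control FDR under the null
  p <- pmin(1, 2 * pmin(pv$p_up, pv$p_down))
  mc_se <- sqrt(0.05 * 0.95 / length(p))
  expect_lte(mean(p < 0.05), 0.05 + 3 * mc_se)
  expect_lte(mean(bh_fdr(p) < 0.05), 0.05 + 3 * mc_se)
})

test_that("DEG filters apply strict q and fold thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    fold = c(3, 1.5, -2.5, 5),
                    q = c(0.05, 0.01, 0.049, 0.2))
  s <- call_degs(tab)
  expect_setequal(s$deg$gene, c("b", "c"))   # q = 0.05 exactly is excluded
  expect_setequal(s$reported$gene, "c")      # |fold| >= 2 on top of q
  expect_error(call_degs(tab[0, ]), "empty")
})

test_that("planted DE genes are recovered with high sensitivity", {
  cfg <- small_config(seed = 1, n_genes = 600, n_de = 30)
  sim <- simulate_expression(cfg)
  deg <- rankprod_deg(sim$expr, sim$groups, "group1", "group2",
                      n_perm = 200, seed = 2)
  s <- call_degs(deg)
  strong <- sim$truth$de$gene[abs(sim$truth$de$signed_fold) >= 4]
  expect_gte(mean(strong %in% s$reported$gene), 0.9)
  # and the calls are essentially all planted
  expect_gte(mean(s$deg$gene %in% sim$truth$de$gene), 0.9)
})
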