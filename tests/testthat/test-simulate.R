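test_that("generators are deterministic given the config seed", {
  cfg <- small_config(seed = 42)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_catalog(cfg), simulate_catalog(cfg))
  expect_identical(simulate_dose_response(2, c(0, 1, 2, 4), seed = 9),
                   simulate_dose_response(2, c(0, 1, 2, 4), seed = 9))
  expect_identical(simulate_qpcr(c(x = 3), seed = 9),
                   simulate_qpcr(c(x = 3), seed = 9))
})

test_that("zero noise recovers planted folds exactly by group-mean arithmetic", {
  cfg <- simulation_config(seed = 3, n_genes = 100, n_de_genes = 1,
                           noise_cv = 0, de_fold_range = c(4, 4),
                           cluster_spec = list(arm = "3L", start = 8.5e6,
                                               width = 5e5, n_genes = 0))
  sim <- simulate_expression(cfg)
  de <- sim$truth$de
  expect_equal(nrow(de), 1)
  fc <- fold_change(sim$expr, sim$groups, "group1", "group2")
  expect_equal(unname(fc[de$gene]), de$signed_fold, tolerance = 1e-12)
  # all other genes have exactly equal group means
  others <- setdiff(rownames(sim$expr), de$gene)
  expect_true(all(abs(fc[others] - 1) < 1e-12))
  # no DE at all: every gene flat across all three groups
  cfg0 <- simulation_config(seed = 3, n_genes = 50, n_de_genes = 0,
                            noise_cv = 0,
                            cluster_spec = list(arm = "3L", start = 8.5e6,
                                                width = 5e5, n_genes = 0))
  sim0 <- simulate_expression(cfg0)
  for (g in levels(sim0$groups)) {
    mg <- rowMeans(sim0$expr[, sim0$groups == g, drop = FALSE])
    expect_equal(mg, rowMeans(sim0$expr[, sim0$groups == "group1",
                                        drop = FALSE]), tolerance = 1e-12)
  }
})

test_that("planted truth respects the configured structure", {
  cfg <- small_config(seed = 5, n_de = 40, n_cluster = 12)
  sim <- simulate_expression(cfg)
  cat <- simulate_catalog(cfg)
  truth <- sim$truth
  expect_true(all(truth$clustered_genes %in% truth$de$gene))
  expect_true(all(abs(truth$de$signed_fold) >= 2 &
                    abs(truth$de$signed_fold) <= 300))
  expect_true(all(sim$expr > 0))
  # clustered midpoints inside the window, on the right arm
  cs <- cfg$cluster_spec
  g <- cat$genes[match(truth$clustered_genes, cat$genes$gene), ]
  expect_equal(nrow(g), 12)
  expect_true(all(g$arm == cs$arm))
  expect_true(all(g$midpoint >= cs$start & g$midpoint < cs$start + cs$width))
  # every gene lies on its arm with a valid half-open span
  expect_true(all(cat$genes$start < cat$genes$end))
  expect_true(all(cat$genes$end <= cat$arms[cat$genes$arm]))
  # term sizes: a term annotated to M genes appears in exactly M rows
  tt <- table(cat$terms$term)
  per_term_genes <- tapply(cat$terms$gene, cat$terms$term,
                           function(x) length(unique(x)))
  expect_equal(as.integer(tt), as.integer(per_term_genes[names(tt)]))
})

test_that("dose-response generator follows its truth curve", {
  # concentration zero: survival probability 1, everyone survives
  dr0 <- simulate_dose_response(2, 0, n_per_vial = 50, n_vials = 4,
                                seed = 2)
  expect_true(all(dr0$survivors == dr0$total))
  # law of large numbers at the LC50: survival fraction -> 0.5
  dr <- simulate_dose_response(2, 2, n_per_vial = 10000, n_vials = 1,
                               seed = 2)
  expect_lt(abs(dr$survivors / dr$total - 0.5), 0.02)
  expect_error(simulate_dose_response(-1, c(0, 1)), "true_lc50")
})

test_that("noiseless qPCR tables encode the planted ratios exactly", {
  ct <- simulate_qpcr(c(tgt = 2), n_replicates = 3, efficiency = 2,
                      ct_noise_sd = 0, seed = 4)
  # delta-Ct of the target between groups is exactly one cycle
  m <- aggregate(Ct ~ gene + group, ct, mean)
  dct <- function(g) m$Ct[m$gene == g & m$group == "group1"] -
    m$Ct[m$gene == g & m$group == "group2"]
  expect_equal(dct("tgt"), 1, tolerance = 1e-12)
  expect_equal(dct("Sucb"), 0, tolerance = 1e-12)
  r <- expression_ratio(ct, "tgt", c("Sucb", "alphaTub84B"),
                        "group1", "group2")
  expect_equal(unname(r), 2, tolerance = 1e-12)
  expect_error(simulate_qpcr(c(tgt = 2), efficiency = 1), "efficiency")
  expect_error(simulate_qpcr(c(Sucb = 2)), "disjoint")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(group_sizes = c(a = 1, b = 5),
                                 de_group = "a"), "group sizes")
  expect_error(simulation_config(n_de_genes = 20000), "n_de_genes")
  expect_error(simulation_config(
    cluster_spec = list(arm = "3L", start = 24.4e6, width = 5e5,
                        n_genes = 10)), "within its arm")
  expect_error(simulation_config(
    cluster_spec = list(arm = "3L", start = 1e6, width = 100,
                        n_genes = 10)), "narrower")
})
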