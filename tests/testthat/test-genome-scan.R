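test_that("bin tiling covers each arm with overlapping, clipped bins", {
  b <- make_bins(c(chr = 1e6))
  expect_equal(b$start, c(0, 250000, 500000, 750000))
  expect_equal(b$end, c(500000, 750000, 1000000, 1000000))
  b2 <- make_bins(c(chr = 4e5))
  expect_equal(b2$start, c(0, 250000))
  expect_equal(b2$end, c(4e5, 4e5))
  # width = step degenerates to a partition: every position in one bin
  b3 <- make_bins(c(chr = 1e6), width = 250000, step = 250000)
  expect_equal(b3$end, b3$start + 250000)
  expect_equal(sum(b3$end - b3$start), 1e6)
  expect_error(make_bins(c(chr = -5)), "positive")
  expect_error(make_bins(c(chr = 1e6), width = 1e5, step = 2e5),
               "width >= step")
})

test_that("top-fraction selection is deterministic with the tie-break chain", {
  tab <- data.frame(gene = sprintf("g%04d", 1:1000),
                    p = rep(0.5, 1000),
                    fold = rep(1, 1000))
  # all ties: selection falls back to |fold| then lexicographic id
  tab$fold[c(7, 3, 500)] <- c(9, 9, 5)
  top <- select_top_fraction(tab, 0.01)
  expect_length(top, 10)
  expect_equal(top[1:3], c("g0003", "g0007", "g0500"))
  expect_equal(top[4:10], sprintf("g%04d", c(1, 2, 4, 5, 6, 8, 9)))
  # planted smallest p-values are selected exactly
  tab2 <- tab
  tab2$p[101:110] <- 1e-6
  expect_setequal(select_top_fraction(tab2, 0.01),
                  sprintf("g%04d", 101:110))
  expect_error(select_top_fraction(tab[0, ]), "empty")
  expect_error(select_top_fraction(tab, 1e-5), "selects no genes")
})

test_that("binomial tail matches brute-force summation", {
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(2, 2, 0.5), 0.25)
  expect_equal(binomial_tail(1, 1, 0.01), 0.01)
  for (p in c(0.01, 0.1, 0.5)) for (n in c(1, 5, 17, 25)) for (k in 0:n) {
    expect_equal(binomial_tail(k, n, p), brute_binomial_tail(k, n, p),
                 tolerance = 1e-12)
  }
  expect_error(binomial_tail(3, 2, 0.5), "k <= n")
})

test_that("bin scores count midpoints and transform the binomial tail", {
  arms <- c(chr = 2e6)
  bins <- make_bins(arms)
  genes <- data.frame(gene = sprintf("g%02d", 1:30), arm = "chr",
                      midpoint = seq(10000, 590000, length.out = 30))
  catalog <- list(genes = genes, arms = arms)
  top <- genes$gene[1:5]
  tr <- score_bins(bins, catalog, top, p = 0.01)
  # all 30 genes sit below 600 kb: bin [0,500k) holds those below 500k
  expect_equal(tr$n[1], sum(genes$midpoint < 5e5))
  expect_equal(tr$k[1], 5)
  expect_equal(tr$score[1],
               -log10(brute_binomial_tail(5, tr$n[1], 0.01)),
               tolerance = 1e-12)
  # empty bins and bins without top genes score exactly zero
  expect_true(all(tr$score[tr$k == 0] == 0))
  expect_true(all(tr$p_value[tr$n == 0] == 1))
  # a single flagged gene alone in a bin scores exactly 2
  expect_equal(-log10(binomial_tail(1, 1, 0.01)), 2)
  # score is non-decreasing in k at fixed n
  sc <- -log10(binomial_tail(0:20, 20, 0.01))
  expect_true(all(diff(sc) >= 0))
  # off-arm coordinates are rejected
  bad <- catalog
  bad$genes$midpoint[1] <- 3e6
  expect_error(score_bins(bins, bad, top), "off its arm")
})

test_that("interior genes fall in exactly two bins when width = 2 * step", {
  arms <- c(chr = 5e6)
  bins <- make_bins(arms)
  mids <- runif(200, 500000, 4.5e6)  # interior: away from the arm ends
  counts <- vapply(mids, function(m)
    sum(m >= bins$start & m < bins$end), integer(1))
  expect_true(all(counts == 2))
})

test_that("cluster calling merges adjacent enriched bins", {
  tr <- data.frame(arm = "chr", start = c(0, 250000, 500000, 1500000),
                   end = c(500000, 750000, 1000000, 2000000),
                   score = c(2.5, 3.5, 1.0, 2.1))
  cl <- call_clusters(tr, cutoff = 2)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(0, 1500000))
  expect_equal(cl$end, c(750000, 2000000))
  expect_equal(cl$peak_score, c(3.5, 2.1))
  expect_equal(call_clusters(transform(tr, score = 1))$arm, character(0))
})

test_that("a planted cluster is recovered by the full scan", {
  cfg <- small_config(seed = 9, n_genes = 800, n_de = 40, n_cluster = 15)
  sim <- simulate_expression(cfg)
  catalog <- simulate_catalog(cfg)
  deg <- rankprod_deg(sim$expr, sim$groups, "group1", "group2",
                      n_perm = 200, seed = 10)
  scan <- genome_scan(deg, catalog, q_frac = 0.02)
  cs <- cfg$cluster_spec
  hit <- scan$clusters$arm == cs$arm &
    scan$clusters$start < cs$start + cs$width &
    scan$clusters$end > cs$start
  expect_true(any(hit))
  # the called cluster contains planted clustered genes
  members <- unlist(strsplit(scan$clusters$genes[hit], ","))
  expect_gt(length(intersect(members, sim$truth$clustered_genes)), 5)
})

test_that("scan null calibration respects the one-in-hundred contract", {
  # reduced-size version of the calibration experiment (fewer placements)
  res <- scan_null_calibration(n_genes = 5000, n_seeds = 10, seed = 3)
  expect_lte(res$fraction, 0.01 + 3 * sqrt(0.01 * 0.99 / res$n_bins))
})
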