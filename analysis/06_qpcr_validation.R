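#!/usr/bin/env Rscript
# Validate expression changes by qPCR: reference-normalized expression
# ratios for each target gene and a randomization test over biological
# replicates (B = 2000).

library(amaresist)

seed <- 20260921
ct <- read_qpcr("results/synthetic/qpcr_ct.tsv")
res <- qpcr_ratio_test(ct, references = c("Sucb", "alphaTub84B"),
                       group_a = "group1", group_b = "group2",
                       B = 2000, seed = derive_seed(seed, "qpcr_test"))

write_tsv(res, "results/qpcr_ratios.tsv", list(seed = seed))
cat("qPCR validation (group2 vs group1, normalized to Sucb/alphaTub84B):\n")
print(res, row.names = FALSE)
cat("true ratios were Cyp6a2 = 10, Cyp316a1 = 8\n")
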