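#!/usr/bin/env Rscript
# Hypergeometric enrichment of the DEG list: gene-based over GO-style
# terms, and instance-based over protein domains (EF and E_score), both
# BH-corrected within the run.

library(amaresist)

deg <- read_tsv("results/deg.tsv")
deg_genes <- deg$gene[deg$is_deg]
terms <- read_annotations("results/synthetic/terms.tsv")
domains <- read_annotations("results/synthetic/domains.tsv")

enr_terms <- run_enrichment(deg_genes, terms, mode = "gene")
enr_domains <- run_enrichment(deg_genes, domains, mode = "domain")

write_tsv(enr_terms, "results/enrichment_terms.tsv")
write_tsv(enr_domains, "results/enrichment_domains.tsv")

cat(sprintf("%d DEGs against %d terms: %d significant (q < 0.05)\n",
            length(deg_genes), nrow(enr_terms),
            sum(enr_terms$significant)))
cat(sprintf("domain instances: %d DEG-side of %d total; %d of %d domains significant\n",
            enr_domains$n[1], enr_domains$N[1],
            sum(enr_domains$significant), nrow(enr_domains)))
cat("top rows (domain mode):\n")
print(head(enr_domains[, c("id", "k", "n", "M", "N", "EF", "p_raw", "q")],
           3), row.names = FALSE)
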