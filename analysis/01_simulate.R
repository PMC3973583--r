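#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an expression matrix shaped like the
# three-group larval design (5/5/6 biological replicates, ~11,890 genes),
# a gene catalog on the five major chromosome arms with term and domain
# annotations, dose-response survival counts, and a qPCR Ct table.
# All downstream scripts read the files written here.

library(amaresist)

seed <- 20260921
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_expression(cfg)
catalog <- simulate_catalog(cfg)

pars <- list(seed = seed, n_genes = cfg$n_genes,
             n_de_genes = cfg$n_de_genes, noise_cv = cfg$noise_cv)
write_expression(sim$expr, file.path(out, "expression.tsv"), pars)
write_group_map(sim$groups, file.path(out, "groups.tsv"), pars)
write_catalog(catalog, file.path(out, "catalog.tsv"), pars)
write_annotations(catalog$terms, file.path(out, "terms.tsv"), pars)
write_annotations(catalog$domains, file.path(out, "domains.tsv"), pars)
# ground truth, kept for the recovery summaries of later scripts
write_tsv(sim$truth$de, file.path(out, "truth_de.tsv"), pars)
writeLines(sim$truth$clustered_genes,
           file.path(out, "truth_clustered_genes.txt"))

dr <- simulate_dose_response(
  true_lc50 = 2, concentrations = exp(seq(log(0.25), log(16),
                                          length.out = 11)),
  n_per_vial = 10, n_vials = 10, seed = derive_seed(seed, "dose"))
write_dose_response(dr, file.path(out, "dose_response.tsv"),
                    list(seed = seed, true_lc50 = 2))

ct <- simulate_qpcr(c(Cyp6a2 = 10, Cyp316a1 = 8),
                    n_replicates = 5, ct_noise_sd = 0.1,
                    seed = derive_seed(seed, "qpcr"))
write_qpcr(ct, file.path(out, "qpcr_ct.tsv"), list(seed = seed))

cat(sprintf("simulated %d genes x %d samples; %d planted DE genes (%d clustered on %s)\n",
            nrow(sim$expr), ncol(sim$expr), nrow(sim$truth$de),
            length(sim$truth$clustered_genes), cfg$cluster_spec$arm))
cat(sprintf("wrote inputs under %s\n", out))
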