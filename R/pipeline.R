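# End-to-end driver: simulate (or accept) inputs, call DEGs by rank
# product, scan the genome for DEG clusters, run both enrichment modes,
# and write every table plus a run report. One global seed derives every
# stage seed, so reruns with the same config are identical.

#' Pipeline configuration
#'
#' @param seed Global integer seed; per-stage seeds are derived from it
#'   with [derive_seed()].
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param sim A [simulation_config()] used to generate the inputs.
#' @param group_a,group_b The compared groups.
#' @param n_perm Rank-product permutations.
#' @param q_cutoff,fold_cutoff DEG filters (corrected p, |fold|).
#' @param q_frac,width,step,scan_cutoff Genome-scan parameters.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            sim = simulation_config(seed = seed),
                            group_a = "group1", group_b = "group2",
                            n_perm = 1000L, q_cutoff = 0.05,
                            fold_cutoff = 2, q_frac = 0.01,
                            width = 500000, step = 250000,
                            scan_cutoff = 2) {
  stopifnot(inherits(sim, "simulation_config"), n_perm >= 1,
            q_cutoff > 0, q_cutoff < 1, fold_cutoff >= 1,
            q_frac > 0, q_frac < 1, width >= step, step > 0,
            scan_cutoff >= 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 group_a = group_a, group_b = group_b,
                 n_perm = as.integer(n_perm), q_cutoff = q_cutoff,
                 fold_cutoff = fold_cutoff, q_frac = q_frac,
                 width = width, step = step, scan_cutoff = scan_cutoff),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Chains simulation, rank-product DEG calling, the binomial coincidence
#' genome scan and both enrichment modes; writes all tables (with '#'
#' parameter headers) under `config$out_dir` when set, and returns a run
#' report. Identical configs produce identical reports and files.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`: counts of DEGs, clusters
#'   and significant terms/domains, planted-truth recovery, parameters and
#'   seeds.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- .stage("simulate", {
    list(e = simulate_expression(config$sim),
         catalog = simulate_catalog(config$sim))
  })
  deg <- .stage("deg", rankprod_deg(
    sim$e$expr, sim$e$groups, config$group_a, config$group_b,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "rankprod"),
    q_cutoff = config$q_cutoff))
  sets <- .stage("deg", call_degs(deg, config$q_cutoff,
                                  config$fold_cutoff))
  scan <- .stage("scan", genome_scan(
    deg, sim$catalog, width = config$width, step = config$step,
    q_frac = config$q_frac, null_p = config$q_frac,
    cutoff = config$scan_cutoff))
  no_enr <- data.frame(id = character(), k = integer(), n = integer(),
                       M = integer(), N = integer(), EF = numeric(),
                       p_raw = numeric(), q = numeric(),
                       significant = logical())
  if (nrow(sets$deg) > 0) {
    enr_gene <- .stage("enrichment", run_enrichment(
      sets$deg$gene, sim$catalog$terms, mode = "gene"))
    enr_dom <- .stage("enrichment", run_enrichment(
      sets$deg$gene, sim$catalog$domains, mode = "domain"))
  } else {
    enr_gene <- enr_dom <- no_enr  # nothing to test against
  }

  truth <- sim$e$truth
  planted <- truth$de
  strong <- planted$gene[abs(planted$signed_fold) >= 4]
  recovered <- intersect(strong, sets$reported$gene)
  cs <- config$sim$cluster_spec
  cl <- scan$clusters
  hit <- cl$arm == cs$arm & cl$start < cs$start + cs$width &
    cl$end > cs$start
  G <- config$sim$n_genes
  report <- structure(list(
    seed = config$seed,
    parameters = config[c("group_a", "group_b", "n_perm", "q_cutoff",
                          "fold_cutoff", "q_frac", "width", "step",
                          "scan_cutoff")],
    n_genes = G,
    n_deg = nrow(sets$deg),
    n_reported = nrow(sets$reported),
    pct_reported = format_percent(nrow(sets$reported), G),
    n_clusters = nrow(cl),
    cluster_arms = unique(cl$arm),
    planted_cluster_recovered = any(hit),
    n_planted_strong = length(strong),
    n_planted_strong_recovered = length(recovered),
    sensitivity_strong = if (length(strong))
      length(recovered) / length(strong) else NA_real_,
    n_sig_terms = sum(enr_gene$significant),
    n_sig_domains = sum(enr_dom$significant)),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pars <- c(list(seed = config$seed), report$parameters)
    out <- function(f) file.path(config$out_dir, f)
    write_expression(sim$e$expr, out("expression.tsv"), pars)
    write_group_map(sim$e$groups, out("groups.tsv"), pars)
    write_catalog(sim$catalog, out("catalog.tsv"), pars)
    write_annotations(sim$catalog$terms, out("terms.tsv"), pars)
    write_annotations(sim$catalog$domains, out("domains.tsv"), pars)
    .write_tsv(deg, out("deg.tsv"), pars)
    .write_tsv(scan$track, out("scan_bins.tsv"), pars)
    .write_tsv(scan$clusters, out("scan_clusters.tsv"), pars)
    write_bedgraph(scan$track, out("scan.bedgraph"), config$step)
    .write_tsv(enr_gene, out("enrichment_terms.tsv"), pars)
    .write_tsv(enr_dom, out("enrichment_domains.tsv"), pars)
    writeLines(utils::capture.output(print(report)), out("report.txt"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("amaresist pipeline report\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  genes: %d\n", x$n_genes))
  cat(sprintf("  DEGs (q < %.2g): %d\n", x$parameters$q_cutoff, x$n_deg))
  cat(sprintf("  reported DEGs (|fold| >= %.3g): %d (%.1f%%)\n",
              x$parameters$fold_cutoff, x$n_reported, x$pct_reported))
  cat(sprintf("  clusters called: %d%s\n", x$n_clusters,
              if (x$n_clusters) paste0(" on ",
                paste(x$cluster_arms, collapse = ", ")) else ""))
  cat(sprintf("  planted cluster recovered: %s\n",
              x$planted_cluster_recovered))
  if (!is.na(x$sensitivity_strong))
    cat(sprintf("  planted |fold|>=4 sensitivity: %d/%d (%.1f%%)\n",
                x$n_planted_strong_recovered, x$n_planted_strong,
                100 * x$sensitivity_strong))
  cat(sprintf("  significant terms: %d; significant domains: %d\n",
              x$n_sig_terms, x$n_sig_domains))
  invisible(x)
}
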