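# Synthetic-data generators: expression matrix, gene catalog, dose-response
# survival counts, qPCR Ct tables. All generators are deterministic given the
# config seed; planted effects are recorded as ground truth for recovery tests.

#' Configuration for the synthetic study design
#'
#' Captures the design being emulated: a ~11,890-gene transcriptome on the
#' five major chromosome arms, three groups with 5/5/6 biological replicates,
#' planted differentially expressed (DE) genes with linear fold effects
#' between 2 and 300, multiplicative intensity noise, and one planted 500-kb
#' cluster of DE genes.
#'
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @param n_genes Number of genes.
#' @param arms Named numeric vector of chromosome arm lengths in bp.
#' @param group_sizes Named counts of biological replicates per group
#'   (all must be >= 2).
#' @param de_group Group in which planted DE genes change expression;
#'   comparisons of this group against the first group recover the truth.
#' @param n_de_genes Number of planted DE genes.
#' @param de_fold_range Linear fold-effect range (min, max); folds are drawn
#'   log-uniformly and half the genes are down-regulated.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (log-normal) intensity noise, applied independently per sample.
#' @param cluster_spec List with `arm`, `start`, `width` (bp) and `n_genes`:
#'   that many planted DE genes get midpoints inside the window.
#' @param term_spec List with `n_terms` and `size_range` for the GO-style
#'   term catalog (term sizes drawn log-uniformly in the range).
#' @param domain_spec List with `n_domains` and `mean_instances`: per-gene
#'   domain-instance counts are Poisson with that mean, instance identities
#'   follow a Zipf-like weight over domains.
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 500, n_de_genes = 20,
#'                          cluster_spec = list(arm = "3L", start = 1e6,
#'                                              width = 5e5, n_genes = 5))
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 11890L,
                              arms = c(X = 22.4e6, `2L` = 23.0e6,
                                       `2R` = 21.1e6, `3L` = 24.5e6,
                                       `3R` = 27.9e6),
                              group_sizes = c(group1 = 5L, group2 = 5L,
                                              group3 = 6L),
                              de_group = "group2",
                              n_de_genes = 300L,
                              de_fold_range = c(2, 300),
                              noise_cv = 0.2,
                              cluster_spec = list(arm = "3L", start = 8.5e6,
                                                  width = 5e5,
                                                  n_genes = 40L),
                              term_spec = list(n_terms = 150L,
                                               size_range = c(10L, 400L)),
                              domain_spec = list(n_domains = 120L,
                                                 mean_instances = 1.5)) {
  if (length(n_genes) != 1L || n_genes < 1)
    stop("'n_genes' must be a positive count")
  if (is.null(names(arms)) || any(arms <= 0))
    stop("'arms' must be a named vector of positive lengths")
  if (is.null(names(group_sizes)) || any(group_sizes < 2))
    stop("all group sizes must be >= 2")
  if (!de_group %in% names(group_sizes))
    stop("'de_group' must name one of the groups")
  if (n_de_genes < 0 || n_de_genes > n_genes)
    stop("'n_de_genes' must lie in [0, n_genes]")
  if (length(de_fold_range) != 2L || any(de_fold_range < 1) ||
      de_fold_range[1] > de_fold_range[2])
    stop("'de_fold_range' must be an increasing pair of folds >= 1")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  cs <- cluster_spec
  if (!all(c("arm", "start", "width", "n_genes") %in% names(cs)))
    stop("'cluster_spec' needs arm, start, width, n_genes")
  if (!cs$arm %in% names(arms)) stop("cluster arm is not a known arm")
  if (cs$start < 0 || cs$start + cs$width > arms[[cs$arm]])
    stop("cluster window must lie within its arm")
  if (cs$n_genes > n_de_genes)
    stop("clustered genes must be a subset of the DE genes")
  if (cs$n_genes > 0 && cs$width < 2 * .gene_halfspan + 2)
    stop("cluster window narrower than the gene spacing it must hold")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 arms = arms, group_sizes = group_sizes, de_group = de_group,
                 n_de_genes = as.integer(n_de_genes),
                 de_fold_range = de_fold_range, noise_cv = noise_cv,
                 cluster_spec = cs, term_spec = term_spec,
                 domain_spec = domain_spec),
            class = "simulation_config")
}

# half-width of the fixed 1-kb gene span around each midpoint
.gene_halfspan <- 500

# Planted truth is derived from the config alone so that the expression
# generator and the catalog generator agree on which genes are DE/clustered
# without sharing state.
.planted_truth <- function(config) {
  set.seed(derive_seed(config$seed, "planted"))
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  n_de <- config$n_de_genes
  de_idx <- if (n_de > 0) sample.int(config$n_genes, n_de) else integer()
  # sample.int order is already random; the first entries seed the cluster
  up <- rep(c(TRUE, FALSE), length.out = n_de)
  fr <- config$de_fold_range
  mag <- exp(runif(n_de, log(fr[1]), log(fr[2])))
  signed <- ifelse(up, mag, -mag)
  clustered <- de_idx[seq_len(min(config$cluster_spec$n_genes, n_de))]
  list(gene_ids = gene_ids,
       de = data.frame(gene = gene_ids[de_idx], signed_fold = signed,
                       stringsAsFactors = FALSE),
       de_idx = de_idx,
       linear_mult = ifelse(up, mag, 1 / mag),
       clustered_genes = gene_ids[clustered])
}

#' Simulate a gene-by-sample expression matrix with planted DE genes
#'
#' Baseline intensities are log-normal (meanlog 6, sdlog 1), DE genes are
#' multiplied by their true linear fold in `de_group`, and multiplicative
#' log-normal noise with the configured coefficient of variation is applied
#' independently per sample. All entries are strictly positive.
#'
#' @param config A [simulation_config()].
#' @return A list with `expr` (numeric matrix, genes x samples), `groups`
#'   (factor of group labels per sample) and `truth` (list with the planted
#'   DE table `de`, `clustered_genes`, and the group the effects act in).
#' @examples
#' sim <- simulate_expression(simulation_config(seed = 1, n_genes = 200,
#'   n_de_genes = 10, cluster_spec = list(arm = "3L", start = 1e6,
#'                                        width = 5e5, n_genes = 2)))
#' dim(sim$expr)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- .planted_truth(config)
  set.seed(derive_seed(config$seed, "expression"))
  G <- config$n_genes
  sizes <- config$group_sizes
  groups <- factor(rep(names(sizes), sizes), levels = names(sizes))
  sample_ids <- unlist(lapply(names(sizes), function(g)
    paste0(g, "_r", seq_len(sizes[[g]]))), use.names = FALSE)
  baseline <- rlnorm(G, meanlog = 6, sdlog = 1)
  S <- length(groups)
  mean_mat <- matrix(baseline, nrow = G, ncol = S)
  de_cols <- which(groups == config$de_group)
  if (length(truth$de_idx) > 0)
    mean_mat[truth$de_idx, de_cols] <-
      baseline[truth$de_idx] * truth$linear_mult
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log1p(config$noise_cv^2))
    noise <- matrix(rlnorm(G * S, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = G, ncol = S)
    expr <- mean_mat * noise
  } else {
    expr <- mean_mat
  }
  dimnames(expr) <- list(truth$gene_ids, sample_ids)
  list(expr = expr, groups = setNames(groups, sample_ids),
       truth = list(de = truth$de, clustered_genes = truth$clustered_genes,
                    de_group = config$de_group))
}

#' Simulate the gene catalog: coordinates plus term and domain annotations
#'
#' Each gene receives a 1-kb span centred on a uniform-random midpoint on an
#' arm chosen with probability proportional to arm length; planted clustered
#' genes are placed inside the configured 500-kb window instead. GO-style
#' terms of log-uniform sizes and Zipf-weighted protein-domain instances
#' (Poisson multiplicity per gene) are assigned at random.
#'
#' @param config A [simulation_config()].
#' @return A `gene_catalog`: list with `genes` (data.frame gene, arm, start,
#'   end, midpoint; 0-based half-open), `arms` (named lengths), `terms` and
#'   `domains` (two-column data.frames; repeated domain rows encode instance
#'   multiplicity).
#' @examples
#' cat <- simulate_catalog(simulation_config(seed = 1, n_genes = 200,
#'   n_de_genes = 10, cluster_spec = list(arm = "3L", start = 1e6,
#'                                        width = 5e5, n_genes = 2)))
#' head(cat$genes)
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- .planted_truth(config)
  set.seed(derive_seed(config$seed, "catalog"))
  G <- config$n_genes
  arms <- config$arms
  gene_ids <- truth$gene_ids
  arm_of <- sample(names(arms), G, replace = TRUE, prob = arms)
  mid <- runif(G, .gene_halfspan, arms[arm_of] - .gene_halfspan)
  cl_idx <- match(truth$clustered_genes, gene_ids)
  if (length(cl_idx) > 0) {
    cs <- config$cluster_spec
    arm_of[cl_idx] <- cs$arm
    mid[cl_idx] <- runif(length(cl_idx),
                         cs$start + .gene_halfspan,
                         cs$start + cs$width - .gene_halfspan)
  }
  mid <- round(mid)
  genes <- data.frame(gene = gene_ids, arm = arm_of,
                      start = mid - .gene_halfspan,
                      end = mid + .gene_halfspan,
                      midpoint = mid, stringsAsFactors = FALSE)
  ts <- config$term_spec
  sizes <- pmin(G, round(exp(runif(ts$n_terms, log(ts$size_range[1]),
                                   log(ts$size_range[2])))))
  terms <- do.call(rbind, lapply(seq_len(ts$n_terms), function(i)
    data.frame(gene = sample(gene_ids, sizes[i]),
               term = sprintf("T%04d", i), stringsAsFactors = FALSE)))
  ds <- config$domain_spec
  n_inst <- rpois(G, ds$mean_instances)
  inst_gene <- rep(gene_ids, n_inst)
  w <- 1 / seq_len(ds$n_domains)
  inst_dom <- sprintf("D%04d",
                      sample.int(ds$n_domains, length(inst_gene),
                                 replace = TRUE, prob = w))
  domains <- data.frame(gene = inst_gene, domain = inst_dom,
                        stringsAsFactors = FALSE)
  structure(list(genes = genes, arms = arms, terms = terms,
                 domains = domains),
            class = "gene_catalog")
}

#' Simulate survival-to-adulthood dose-response counts
#'
#' Survivors per vial are binomial draws from a monotone-decreasing truth
#' curve `survival = 1 / (1 + (C / LC50)^h)`, which equals 0.5 at the true
#' LC50 and 1 at concentration zero.
#'
#' @param true_lc50 True LC50 (same units as `concentrations`), > 0.
#' @param concentrations Non-negative toxin concentrations (ug per g food).
#' @param n_per_vial Larvae per vial.
#' @param n_vials Vials per concentration.
#' @param hill Slope of the truth curve (default 2).
#' @param seed Integer seed.
#' @return Data frame (concentration, vial, survivors, total) with the truth
#'   attached as attribute `true_lc50`.
#' @examples
#' dr <- simulate_dose_response(2, c(0, 0.5, 1, 2, 4, 8), seed = 1)
#' head(dr)
#' @export
simulate_dose_response <- function(true_lc50, concentrations,
                                   n_per_vial = 10L, n_vials = 10L,
                                   hill = 2, seed = 1L) {
  if (true_lc50 <= 0) stop("'true_lc50' must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (n_per_vial < 1 || n_vials < 1) stop("counts must be >= 1")
  if (hill <= 0) stop("'hill' must be > 0")
  set.seed(seed)
  p <- 1 / (1 + (concentrations / true_lc50)^hill)
  out <- do.call(rbind, lapply(seq_along(concentrations), function(i)
    data.frame(concentration = concentrations[i], vial = seq_len(n_vials),
               survivors = rbinom(n_vials, n_per_vial, p[i]),
               total = n_per_vial)))
  attr(out, "true_lc50") <- true_lc50
  out
}

#' Simulate a qPCR Ct table from known expression ratios
#'
#' Ct values follow `Ct = intercept - log_E(expression) + noise`, where `E`
#' is the amplification efficiency (2 = perfect doubling). Target genes have
#' group-2 expression equal to `true_ratios` times their group-1 baseline;
#' reference genes have identical expected expression in both groups.
#'
#' @param true_ratios Named vector of true group2/group1 expression ratios
#'   for the target genes.
#' @param n_replicates Biological replicates per group.
#' @param efficiency Amplification factor per cycle, in (1, 2].
#' @param ct_noise_sd Gaussian noise SD (cycles) per measurement.
#' @param seed Integer seed.
#' @param reference_genes Names of the reference genes (true ratio 1).
#' @param n_tech Technical replicates per biological replicate.
#' @param group_labels The two group labels, baseline group first.
#' @return Data frame (gene, group, bio_rep, tech_rep, Ct) with attributes
#'   `efficiency`, `reference_genes` and `true_ratios`.
#' @examples
#' ct <- simulate_qpcr(c(Cyp6a2 = 10), n_replicates = 3, ct_noise_sd = 0,
#'                     seed = 1)
#' head(ct)
#' @export
simulate_qpcr <- function(true_ratios, n_replicates = 5L, efficiency = 2,
                          ct_noise_sd = 0.1, seed = 1L,
                          reference_genes = c("Sucb", "alphaTub84B"),
                          n_tech = 3L,
                          group_labels = c("group1", "group2")) {
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must lie in (1, 2]")
  if (is.null(names(true_ratios)) || any(true_ratios <= 0))
    stop("'true_ratios' must be a named vector of positive ratios")
  if (n_replicates < 2) stop("need >= 2 biological replicates per group")
  if (ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0")
  if (any(reference_genes %in% names(true_ratios)))
    stop("reference genes must be disjoint from targets")
  set.seed(seed)
  genes <- c(names(true_ratios), reference_genes)
  ratios <- c(true_ratios, setNames(rep(1, length(reference_genes)),
                                    reference_genes))
  base_expr <- setNames(2^runif(length(genes), 8, 14), genes)
  intercept <- 34
  grid <- expand.grid(gene = genes, group = group_labels,
                      bio_rep = seq_len(n_replicates),
                      tech_rep = seq_len(n_tech),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expr <- base_expr[grid$gene] *
    ifelse(grid$group == group_labels[2], ratios[grid$gene], 1)
  ct_true <- intercept - log(expr) / log(efficiency)
  grid$Ct <- ct_true + rnorm(nrow(grid), 0, ct_noise_sd)
  attr(grid, "efficiency") <- efficiency
  attr(grid, "reference_genes") <- reference_genes
  attr(grid, "true_ratios") <- true_ratios
  grid
}
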