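# Relative qPCR expression ratios normalized against multiple reference
# genes, with a randomization test over biological replicates (two-sided,
# statistic |log ratio|, replicates reallocated jointly across genes).

# Average technical replicates into biological replicates and return a
# genes x replicate-units Ct matrix plus the unit -> group map.
.bio_ct_matrix <- function(data, genes, group_a, group_b) {
  stopifnot(is.data.frame(data),
            all(c("gene", "group", "bio_rep", "Ct") %in% names(data)))
  d <- data[data$gene %in% genes &
              data$group %in% c(group_a, group_b), , drop = FALSE]
  for (g in c(group_a, group_b))
    if (!any(d$group == g)) stop(sprintf("group '%s' missing", g))
  for (g in genes) {
    miss <- setdiff(c(group_a, group_b), unique(d$group[d$gene == g]))
    if (length(miss))
      stop(sprintf("gene '%s' not measured in group '%s'", g, miss[1]))
  }
  agg <- aggregate(Ct ~ gene + group + bio_rep, data = d, FUN = mean)
  unit <- paste(agg$group, agg$bio_rep, sep = "::")
  units <- unique(unit[order(agg$group, agg$bio_rep)])
  ct <- matrix(NA_real_, nrow = length(genes), ncol = length(units),
               dimnames = list(genes, units))
  ct[cbind(match(agg$gene, genes), match(unit, units))] <- agg$Ct
  if (anyNA(ct)) stop("unbalanced Ct table: missing (gene, replicate) cells")
  unit_group <- sub("::.*$", "", units)
  list(ct = ct, unit_group = unit_group)
}

# efficiency per gene: default 2 (perfect doubling), named overrides allowed
.gene_eff <- function(genes, efficiencies) {
  eff <- setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) {
    if (any(efficiencies <= 1 | efficiencies > 2))
      stop("efficiencies must lie in (1, 2]")
    hit <- intersect(names(efficiencies), genes)
    eff[hit] <- efficiencies[hit]
  }
  eff
}

# log expression ratio for one assignment of units to groups
.log_ratio <- function(ct, in_a, target, references, log_eff) {
  dct <- rowMeans(ct[, in_a, drop = FALSE]) -
    rowMeans(ct[, !in_a, drop = FALSE])
  unname(log_eff[target] * dct[target] -
           mean(log_eff[references] * dct[references]))
}

#' Reference-normalized relative expression ratio
#'
#' Technical replicates are averaged into their biological replicate, then
#' `ratio = E_t^(dCt_t) / geometric mean over references r of E_r^(dCt_r)`
#' with `dCt = mean Ct(group_a) - mean Ct(group_b)`, so the result is the
#' expression of the target in `group_b` relative to `group_a`, normalized
#' for input amount by the reference genes.
#'
#' @param data Data frame (gene, group, bio_rep, tech_rep, Ct).
#' @param target Target gene id.
#' @param references Character vector of reference gene ids (non-empty,
#'   disjoint from the target).
#' @param group_a,group_b Baseline and comparison group labels.
#' @param efficiencies Optional named per-gene amplification factors in
#'   (1, 2]; genes not named default to 2.
#' @return The positive expression ratio.
#' @export
expression_ratio <- function(data, target, references, group_a, group_b,
                             efficiencies = NULL) {
  if (length(references) == 0) stop("need at least one reference gene")
  if (target %in% references)
    stop("references must be disjoint from the target")
  genes <- c(target, references)
  m <- .bio_ct_matrix(data, genes, group_a, group_b)
  log_eff <- log(.gene_eff(genes, efficiencies))
  exp(.log_ratio(m$ct, m$unit_group == group_a, target, references,
                 log_eff))
}

#' Randomization test for a qPCR expression ratio
#'
#' Builds a null distribution by `B` random reallocations of the
#' biological replicates between the two group labels (target and
#' reference Ct rows move jointly per replicate) and compares the observed
#' |log ratio| against it: `p = (1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @inheritParams expression_ratio
#' @param B Number of randomizations (>= 100; the study convention is
#'   2000).
#' @param seed Integer seed.
#' @return List with `ratio`, `p_value`, `B`.
#' @export
randomization_test <- function(data, target, references, group_a, group_b,
                               B = 2000L, seed = 1L,
                               efficiencies = NULL) {
  if (B < 100) stop("'B' must be >= 100")
  if (length(references) == 0) stop("need at least one reference gene")
  genes <- c(target, references)
  m <- .bio_ct_matrix(data, genes, group_a, group_b)
  n_a <- sum(m$unit_group == group_a)
  n_b <- sum(m$unit_group == group_b)
  if (n_a < 2 || n_b < 2)
    stop("need at least 2 biological replicates per group")
  log_eff <- log(.gene_eff(genes, efficiencies))
  obs_lr <- .log_ratio(m$ct, m$unit_group == group_a, target, references,
                       log_eff)
  obs <- abs(obs_lr)
  n_units <- n_a + n_b
  set.seed(seed)
  null_stat <- numeric(B)
  for (b in seq_len(B)) {
    in_a <- logical(n_units)
    in_a[sample.int(n_units, n_a)] <- TRUE
    null_stat[b] <- abs(.log_ratio(m$ct, in_a, target, references,
                                   log_eff))
  }
  p <- (1 + sum(null_stat >= obs - 1e-12)) / (B + 1)
  list(ratio = exp(obs_lr), p_value = p, B = as.integer(B))
}

#' Ratio and randomization p-value for a panel of target genes
#'
#' Runs [expression_ratio()] and [randomization_test()] for every target,
#' mirroring the validation report of a relative-expression qPCR study.
#'
#' @inheritParams randomization_test
#' @param targets Character vector of target genes; defaults to every
#'   measured gene that is not a reference.
#' @return Data frame with columns gene, ratio, p_value, B.
#' @export
qpcr_ratio_test <- function(data, references, group_a, group_b,
                            targets = NULL, B = 2000L, seed = 1L,
                            efficiencies = NULL) {
  if (is.null(targets))
    targets <- setdiff(unique(data$gene), references)
  if (length(targets) == 0) stop("no target genes")
  rows <- lapply(seq_along(targets), function(i) {
    r <- randomization_test(data, targets[i], references, group_a,
                            group_b, B = B,
                            seed = derive_seed(seed, targets[i]),
                            efficiencies = efficiencies)
    data.frame(gene = targets[i], ratio = r$ratio, p_value = r$p_value,
               B = r$B, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
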