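# Rank-product differential expression between two groups, with a
# permutation null, Benjamini-Hochberg FDR, and the DEG filters
# (corrected p < 0.05; reported set additionally |fold| >= 2).

#' Signed linear fold change between two groups
#'
#' The ratio `r = mean(group_b) / mean(group_a)` per gene, reported as `r`
#' when `r >= 1` and `-1/r` otherwise, so a 4-fold down-regulation is -4.
#'
#' @param expr Positive numeric matrix, genes x samples, gene ids as
#'   rownames.
#' @param groups Group label per sample column.
#' @param group_a,group_b The baseline and comparison group labels.
#' @return Named numeric vector of signed folds (|fold| >= 1).
#' @examples
#' m <- rbind(g1 = c(10, 10, 40, 40), g2 = c(40, 40, 10, 10))
#' fold_change(m, c("a", "a", "b", "b"), "a", "b")
#' @export
fold_change <- function(expr, groups, group_a, group_b) {
  .check_expr(expr, groups)
  ca <- .group_cols(groups, group_a)
  cb <- .group_cols(groups, group_b)
  r <- rowMeans(expr[, cb, drop = FALSE]) /
    rowMeans(expr[, ca, drop = FALSE])
  ifelse(r >= 1, r, -1 / r)
}

#' Rank-product statistic over all pairwise replicate comparisons
#'
#' For each of the `K = |A| x |B|` pairwise replicate comparisons, genes are
#' ranked by pairwise fold change (rank 1 = most changed in the requested
#' direction, ties share the average rank); the rank product is the
#' geometric mean of a gene's K ranks. Small values indicate consistent
#' regulation in that direction.
#'
#' @inheritParams fold_change
#' @param direction `"up"` (higher in `group_b`) or `"down"`.
#' @return Named numeric vector of rank products (all >= 1).
#' @export
rank_product <- function(expr, groups, group_a, group_b,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  .check_expr(expr, groups)
  ca <- .group_cols(groups, group_a)
  cb <- .group_cols(groups, group_b)
  setNames(.rp_core(expr, ca, cb, direction), rownames(expr))
}

# rank product over all |ca| x |cb| pairwise comparisons of the given
# column sets; no validation, used by the permutation loop
.rp_core <- function(expr, ca, cb, direction) {
  G <- nrow(expr)
  logsum <- numeric(G)
  K <- 0L
  for (i in ca) for (j in cb) {
    ratio <- expr[, j] / expr[, i]
    rk <- if (direction == "up") rank(-ratio, ties.method = "average")
          else rank(ratio, ties.method = "average")
    logsum <- logsum + log(rk)
    K <- K + 1L
  }
  exp(logsum / K)
}

#' Permutation p-values for the rank-product statistic
#'
#' Null rank products are pooled over `n_perm` permutations and `G` genes,
#' and each observed rank product is referred to the pooled null:
#' `p = (1 + #\{null RP <= observed RP\}) / (1 + G * n_perm)`. The +1
#' pseudo-count keeps every p-value strictly positive.
#'
#' Two null schemes are available. `"labels"` (the default) recomputes the
#' rank product after a uniform-random reassignment of the pooled samples
#' to the two groups; because the pairwise comparisons share replicates, a
#' gene's ranks are correlated across comparisons, and relabelling
#' preserves that dependence, giving calibrated (uniform-under-null)
#' p-values. `"ranks"` replaces each comparison's rank vector by an
#' independent uniform-random permutation of `1..G`; it is cheaper and has
#' a closed-form minimum (`P(RP = 1) = G^-K`), but ignores the
#' cross-comparison dependence and is anti-conservative on replicated
#' designs, so it is kept for reference rather than inference.
#'
#' @inheritParams fold_change
#' @param n_perm Number of null permutations (>= 1; >= 100 recommended).
#' @param seed Integer seed for the permutation stream.
#' @param null Null scheme, `"labels"` (default) or `"ranks"`.
#' @return List with `rp_up`, `rp_down`, `p_up`, `p_down` (named vectors).
#' @export
rank_product_pvalues <- function(expr, groups, group_a, group_b,
                                 n_perm = 1000L, seed = 1L,
                                 null = c("labels", "ranks")) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  null <- match.arg(null)
  rp_up <- rank_product(expr, groups, group_a, group_b, "up")
  rp_down <- rank_product(expr, groups, group_a, group_b, "down")
  G <- nrow(expr)
  ca <- .group_cols(groups, group_a)
  cb <- .group_cols(groups, group_b)
  K <- length(ca) * length(cb)
  set.seed(seed)
  null_rp <- numeric(G * n_perm)
  if (null == "ranks") {
    for (b in seq_len(n_perm)) {
      ls <- numeric(G)
      for (k in seq_len(K)) ls <- ls + log(sample.int(G))
      null_rp[((b - 1L) * G + 1L):(b * G)] <- exp(ls / K)
    }
  } else {
    pool <- c(ca, cb)
    n_a <- length(ca)
    # The observed assignment (and its mirror) would inject full copies of
    # any real signal into the null pool; the +1 pseudo-count already
    # accounts for the observed statistic, so those draws are rejected
    # whenever other relabellings exist (Phipson-Smyth convention).
    set_a <- sort(ca)
    set_b <- sort(cb)
    can_reject <- choose(length(pool), n_a) > 2
    for (b in seq_len(n_perm)) {
      repeat {
        z <- pool[sample.int(length(pool))]
        za <- sort(z[seq_len(n_a)])
        if (!can_reject ||
            !(identical(za, set_a) || identical(za, set_b))) break
      }
      null_rp[((b - 1L) * G + 1L):(b * G)] <-
        .rp_core(expr, z[seq_len(n_a)], z[-seq_len(n_a)], "up")
    }
  }
  null_rp <- sort(null_rp)
  denom <- 1 + as.numeric(G) * n_perm
  p_up <- (1 + findInterval(rp_up, null_rp)) / denom
  p_down <- (1 + findInterval(rp_down, null_rp)) / denom
  list(rp_up = rp_up, rp_down = rp_down,
       p_up = setNames(p_up, names(rp_up)),
       p_down = setNames(p_down, names(rp_down)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up corrected q-values: `q_i = min over p_j >= p_i of
#' (p_j * m / rank_j)`, capped at 1 and order-preserving.
#'
#' @param pvals Raw p-values, all in (0, 1].
#' @return Vector of q-values, `q >= p` elementwise.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("all p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Rank-product DEG table for one two-group comparison
#'
#' Combines signed fold changes, directional rank products and their
#' permutation p-values into the per-gene table the downstream stages
#' consume. The per-gene p-value is `min(p_up, p_down)` Bonferroni-doubled
#' for the two one-sided tests, then BH-corrected; genes with `q <
#' q_cutoff` are flagged as DEGs.
#'
#' @inheritParams rank_product_pvalues
#' @param q_cutoff Corrected-p threshold for the DEG flag (default 0.05).
#' @return Data frame with columns gene, fold, rp_up, rp_down, p_up,
#'   p_down, p, q, is_deg.
#' @export
rankprod_deg <- function(expr, groups, group_a, group_b, n_perm = 1000L,
                         seed = 1L, q_cutoff = 0.05) {
  fc <- fold_change(expr, groups, group_a, group_b)
  pv <- rank_product_pvalues(expr, groups, group_a, group_b, n_perm, seed)
  p <- pmin(1, 2 * pmin(pv$p_up, pv$p_down))
  q <- bh_fdr(p)
  data.frame(gene = rownames(expr), fold = unname(fc),
             rp_up = unname(pv$rp_up), rp_down = unname(pv$rp_down),
             p_up = unname(pv$p_up), p_down = unname(pv$p_down),
             p = unname(p), q = unname(q), is_deg = unname(q < q_cutoff),
             stringsAsFactors = FALSE)
}

#' Apply the DEG significance and fold filters
#'
#' Two nested sets: the DEG set (corrected p strictly below `q_cutoff`) and
#' the reported set (additionally at least a `fold_cutoff`-fold change in
#' either direction).
#'
#' @param deg_table Output of [rankprod_deg()].
#' @param q_cutoff Strict corrected-p threshold (default 0.05).
#' @param fold_cutoff Minimum |signed fold| for the reported set.
#' @return List with data frames `deg` and `reported`.
#' @export
call_degs <- function(deg_table, q_cutoff = 0.05, fold_cutoff = 2) {
  stopifnot(is.data.frame(deg_table),
            all(c("gene", "fold", "q") %in% names(deg_table)))
  if (nrow(deg_table) == 0) stop("empty DEG table")
  deg <- deg_table[deg_table$q < q_cutoff, , drop = FALSE]
  reported <- deg[abs(deg$fold) >= fold_cutoff, , drop = FALSE]
  list(deg = deg, reported = reported)
}
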