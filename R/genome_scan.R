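# Binomial coincidence detection: tile overlapping bins along each
# chromosome arm, score the enrichment of top differentially expressed
# genes per bin by an exact binomial tail, and call clusters of bins whose
# log10-inverse score rises above the cutoff (default 2, i.e. 1-in-100
# under the null).

#' Tile overlapping bins along chromosome arms
#'
#' Bins start at 0, `step`, `2*step`, ... on each arm; each bin is
#' `[start, min(start + width, arm length))` (0-based half-open) and
#' generation stops once a start reaches the arm end, so every coordinate
#' is covered and terminal bins may be truncated.
#'
#' @param arm_lengths Named vector of arm lengths in bp.
#' @param width Bin width in bp (default 500 kb).
#' @param step Start-to-start spacing in bp (default 250 kb); must satisfy
#'   `width >= step > 0`.
#' @return Data frame with columns arm, start, end.
#' @examples
#' make_bins(c(chr = 1e6))
#' @export
make_bins <- function(arm_lengths, width = 500000, step = 250000) {
  if (is.null(names(arm_lengths)) || any(arm_lengths <= 0))
    stop("'arm_lengths' must be a named vector of positive lengths")
  if (!(width >= step && step > 0)) stop("need width >= step > 0")
  out <- lapply(names(arm_lengths), function(a) {
    len <- arm_lengths[[a]]
    starts <- seq(0, by = step, length.out = ceiling(len / step))
    data.frame(arm = a, start = starts, end = pmin(starts + width, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the top fraction of most differentially expressed genes
#'
#' Returns the `floor(G * q_frac)` genes with the smallest per-gene
#' p-value; ties at the boundary are broken by larger |signed fold|, then
#' lexicographic gene id, so the selection is fully deterministic.
#'
#' @param deg_table Data frame with columns gene, p, fold.
#' @param q_frac Fraction of genes to keep (default 0.01).
#' @return Character vector of selected gene ids.
#' @export
select_top_fraction <- function(deg_table, q_frac = 0.01) {
  stopifnot(is.data.frame(deg_table),
            all(c("gene", "p", "fold") %in% names(deg_table)))
  if (nrow(deg_table) == 0) stop("empty DEG table")
  if (!(q_frac > 0 && q_frac < 1)) stop("'q_frac' must lie in (0, 1)")
  n_top <- floor(nrow(deg_table) * q_frac)
  if (n_top < 1) stop("'q_frac' selects no genes")
  ord <- order(deg_table$p, -abs(deg_table$fold), deg_table$gene)
  deg_table$gene[ord[seq_len(n_top)]]
}

#' Exact upper-tail binomial probability P(X >= k)
#'
#' @param k Observed count (0 <= k <= n).
#' @param n Number of trials.
#' @param p Per-trial success probability.
#' @return `P(Binomial(n, p) >= k)`; 1 when `k = 0`.
#' @examples
#' binomial_tail(2, 2, 0.5)  # 0.25
#' @export
binomial_tail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  if (any(p < 0) || any(p > 1)) stop("'p' must lie in [0, 1]")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Score bins by binomial enrichment of top genes
#'
#' A gene belongs to a bin iff its midpoint lies in the bin's half-open
#' interval. For each bin, `n` is the number of catalog genes it holds and
#' `k` the number of top-set genes among them; the bin's tail probability
#' is `P(Binomial(n, p) >= k)` and its score is `log10(1 / p_value)`, so
#' empty bins and bins without top genes score exactly 0.
#'
#' @param bins Bin grid from [make_bins()].
#' @param catalog A `gene_catalog` (or any list with a `genes` data frame
#'   carrying gene, arm, midpoint and named `arms` lengths).
#' @param top_genes Character vector of top-set gene ids; must all be
#'   present in the catalog.
#' @param p Null per-gene probability of being a top gene (default 0.01,
#'   the selection fraction).
#' @return The bin grid with added columns n, k, p_value, score.
#' @export
score_bins <- function(bins, catalog, top_genes, p = 0.01) {
  genes <- catalog$genes
  stopifnot(is.data.frame(bins),
            all(c("arm", "start", "end") %in% names(bins)),
            all(c("gene", "arm", "midpoint") %in% names(genes)))
  if (!all(top_genes %in% genes$gene))
    stop("every top-set gene must be present in the catalog")
  if (!is.null(catalog$arms)) {
    len <- catalog$arms[genes$arm]
    bad <- is.na(len) | genes$midpoint < 0 | genes$midpoint >= len
    if (any(bad))
      stop(sprintf("gene '%s' has coordinates off its arm",
                   genes$gene[which(bad)[1]]))
  }
  n_b <- integer(nrow(bins))
  k_b <- integer(nrow(bins))
  is_top <- genes$gene %in% top_genes
  for (a in unique(bins$arm)) {
    on_arm <- genes$arm == a
    mids <- genes$midpoint[on_arm]
    tmids <- genes$midpoint[on_arm & is_top]
    idx <- which(bins$arm == a)
    n_b[idx] <- vapply(idx, function(i)
      sum(mids >= bins$start[i] & mids < bins$end[i]), integer(1))
    k_b[idx] <- vapply(idx, function(i)
      sum(tmids >= bins$start[i] & tmids < bins$end[i]), integer(1))
  }
  p_value <- binomial_tail(k_b, n_b, p)
  out <- bins
  out$n <- n_b
  out$k <- k_b
  out$p_value <- p_value
  out$score <- -log10(p_value)
  out
}

#' Call clusters of consecutively enriched bins
#'
#' Bins whose score is strictly greater than `cutoff` are flagged;
#' overlapping or adjacent flagged bins on the same arm are merged into one
#' cluster interval. When a catalog and top set are supplied, the top-set
#' genes whose midpoints fall in the merged interval are listed as members.
#'
#' @param track Scored bins from [score_bins()].
#' @param cutoff Log10-inverse-probability cutoff (default 2, the
#'   1-in-100 contract).
#' @param catalog,top_genes Optional; used to list member genes.
#' @return Data frame with columns arm, start, end, peak_score, n_bins,
#'   genes (comma-separated ids, empty when no catalog is given).
#' @export
call_clusters <- function(track, cutoff = 2, catalog = NULL,
                          top_genes = NULL) {
  stopifnot(is.data.frame(track),
            all(c("arm", "start", "end", "score") %in% names(track)))
  empty <- data.frame(arm = character(), start = numeric(),
                      end = numeric(), peak_score = numeric(),
                      n_bins = integer(), genes = character(),
                      stringsAsFactors = FALSE)
  flagged <- track[track$score > cutoff, , drop = FALSE]
  if (nrow(flagged) == 0) return(empty)
  out <- list()
  for (a in unique(flagged$arm)) {
    fa <- flagged[flagged$arm == a, , drop = FALSE]
    fa <- fa[order(fa$start), , drop = FALSE]
    cur_start <- fa$start[1]; cur_end <- fa$end[1]
    cur_peak <- fa$score[1]; cur_n <- 1L
    flush <- function() {
      members <- ""
      if (!is.null(catalog) && !is.null(top_genes)) {
        g <- catalog$genes
        hit <- g$arm == a & g$midpoint >= cur_start & g$midpoint < cur_end &
          g$gene %in% top_genes
        members <- paste(sort(g$gene[hit]), collapse = ",")
      }
      data.frame(arm = a, start = cur_start, end = cur_end,
                 peak_score = cur_peak, n_bins = cur_n, genes = members,
                 stringsAsFactors = FALSE)
    }
    if (nrow(fa) > 1) for (i in 2:nrow(fa)) {
      if (fa$start[i] <= cur_end) {
        cur_end <- max(cur_end, fa$end[i])
        cur_peak <- max(cur_peak, fa$score[i])
        cur_n <- cur_n + 1L
      } else {
        out[[length(out) + 1L]] <- flush()
        cur_start <- fa$start[i]; cur_end <- fa$end[i]
        cur_peak <- fa$score[i]; cur_n <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  do.call(rbind, out)
}

#' Run the full genome scan on a DEG table
#'
#' Convenience wrapper: selects the top fraction of most differentially
#' expressed genes, tiles bins over the catalog's arms, scores them, and
#' calls clusters.
#'
#' @param deg_table Data frame with gene, p, fold (e.g. [rankprod_deg()]).
#' @param catalog A `gene_catalog`.
#' @param width,step Bin geometry in bp.
#' @param q_frac Top fraction of genes to scan (default 0.01).
#' @param null_p Null per-gene flag probability (default the selection
#'   fraction, 0.01).
#' @param cutoff Cluster-calling score cutoff (default 2).
#' @return List with `top_genes`, `track`, `clusters`.
#' @export
genome_scan <- function(deg_table, catalog, width = 500000, step = 250000,
                        q_frac = 0.01, null_p = 0.01, cutoff = 2) {
  top <- select_top_fraction(deg_table, q_frac)
  bins <- make_bins(catalog$arms, width, step)
  track <- score_bins(bins, catalog, top, null_p)
  clusters <- call_clusters(track, cutoff, catalog, top)
  list(top_genes = top, track = track, clusters = clusters)
}

#' Null calibration of the genome scan
#'
#' Places `n_genes` genes uniformly on the arms, flags a uniform-random
#' `q_frac` of them as "top" (no clustering), scores all bins, and pools
#' the fraction of bins whose score exceeds `cutoff` over `n_seeds`
#' independent placements. Under the binomial null this fraction should not
#' exceed `10^-cutoff` beyond Monte-Carlo error.
#'
#' @param n_genes Genes per placement.
#' @param arms Named arm lengths in bp.
#' @param q_frac Flagged fraction (default 0.01).
#' @param n_seeds Number of independent placements.
#' @param seed Base seed.
#' @param width,step,cutoff Scan geometry and cutoff.
#' @return List with `fraction` (pooled exceedance fraction), `n_bins`
#'   (total bins scored) and `mc_se` (binomial Monte-Carlo standard error
#'   of the nominal rate).
#' @export
scan_null_calibration <- function(n_genes = 11890, arms = c(
                                    X = 22.4e6, `2L` = 23.0e6,
                                    `2R` = 21.1e6, `3L` = 24.5e6,
                                    `3R` = 27.9e6),
                                  q_frac = 0.01, n_seeds = 50, seed = 1,
                                  width = 500000, step = 250000,
                                  cutoff = 2) {
  bins <- make_bins(arms, width, step)
  n_top <- floor(n_genes * q_frac)
  exceed <- 0L
  total <- 0L
  for (s in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, paste0("scan_null_", s)))
    arm_of <- sample(names(arms), n_genes, replace = TRUE, prob = arms)
    mid <- runif(n_genes, 0, arms[arm_of])
    genes <- data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
                        arm = arm_of, midpoint = mid,
                        stringsAsFactors = FALSE)
    top <- genes$gene[sample.int(n_genes, n_top)]
    track <- score_bins(bins, list(genes = genes, arms = arms), top,
                        p = q_frac)
    exceed <- exceed + sum(track$score > cutoff)
    total <- total + nrow(track)
  }
  rate <- 10^-cutoff
  list(fraction = exceed / total, n_bins = total,
       mc_se = sqrt(rate * (1 - rate) / total))
}
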