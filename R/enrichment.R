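# Hypergeometric enrichment in two counting modes: gene-based (GO-style
# term enrichment) and domain-instance-based (protein-domain EF / E_score,
# where a gene carrying two copies of a domain contributes two instances).

#' Exact upper-tail hypergeometric probability P(X >= k)
#'
#' The E_score: the probability of observing at least `k` annotated items
#' among `n` drawn without replacement from a population of `N` items of
#' which `M` are annotated.
#'
#' @param k Observed annotated count among the draws.
#' @param n Number of draws.
#' @param M Annotated items in the population.
#' @param N Population size.
#' @return `P(X >= k)`; 1 when `k = 0`.
#' @examples
#' hypergeom_tail(2, 2, 2, 4)  # 1/6
#' @export
hypergeom_tail <- function(k, n, M, N) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  if (any(n > N)) stop("need n <= N")
  if (any(M < 0) || any(M > N)) stop("need 0 <= M <= N")
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Enrichment factor EF = k / (n M / N)
#'
#' Observed-over-expected count of an annotation among the DEG-side items.
#'
#' @inheritParams hypergeom_tail
#' @return `k * N / (n * M)`.
#' @examples
#' enrichment_factor(48, 2609, 91, 11890)
#' @export
enrichment_factor <- function(k, n, M, N) {
  if (any(n <= 0) || any(M <= 0)) stop("need n > 0 and M > 0")
  if (any(k < 0) || any(N <= 0)) stop("need k >= 0 and N > 0")
  k * N / (n * M)
}

# standardize a two-column annotation table to (gene, id)
.std_annot <- function(annotations) {
  stopifnot(is.data.frame(annotations), ncol(annotations) >= 2)
  ann <- annotations[, 1:2]
  names(ann) <- c("gene", "id")
  ann$gene <- as.character(ann$gene)
  ann$id <- as.character(ann$id)
  if (nrow(ann) == 0) stop("empty annotation table")
  ann
}

#' Gene-mode contingency counts for one term
#'
#' Counts genes: `N` = background genes (genes with at least one
#' annotation, or `all_genes` when a whole-genome background is wanted),
#' `M` = background genes carrying the term, `n` = DEG genes within the
#' background, `k` = DEG genes carrying the term.
#'
#' @param deg_genes Character vector of DEG ids.
#' @param annotations Two-column data frame (gene, term).
#' @param term The term id to count.
#' @param background `"annotated"` (default) or `"all"`.
#' @param all_genes Full gene universe, required for `background = "all"`.
#' @return Named vector `c(k, n, M, N)`.
#' @export
gene_mode_counts <- function(deg_genes, annotations, term,
                             background = c("annotated", "all"),
                             all_genes = NULL) {
  background <- match.arg(background)
  ann <- unique(.std_annot(annotations))
  if (!term %in% ann$id) stop(sprintf("term '%s' not in catalog", term))
  bg <- if (background == "annotated") unique(ann$gene) else {
    if (is.null(all_genes)) stop("'all_genes' required for background='all'")
    unique(as.character(all_genes))
  }
  if (length(bg) == 0) stop("empty background")
  deg_in <- intersect(unique(deg_genes), bg)
  with_term <- unique(ann$gene[ann$id == term])
  with_term <- intersect(with_term, bg)
  c(k = length(intersect(deg_in, with_term)), n = length(deg_in),
    M = length(with_term), N = length(bg))
}

#' Domain-instance-mode contingency counts for one domain
#'
#' Counts domain instances (a gene with two copies contributes two): `N` =
#' all instances genome-wide, `M` = instances of this domain genome-wide,
#' `n` = all instances on DEG genes, `k` = instances of this domain on DEG
#' genes.
#'
#' @param deg_genes Character vector of DEG ids.
#' @param annotations Two-column data frame (gene, domain) with repeated
#'   rows encoding multiplicity.
#' @param domain The domain id to count.
#' @return Named vector `c(k, n, M, N)`.
#' @export
domain_mode_counts <- function(deg_genes, annotations, domain) {
  ann <- .std_annot(annotations)
  if (!domain %in% ann$id) stop(sprintf("domain '%s' not in catalog", domain))
  on_deg <- ann$gene %in% deg_genes
  is_dom <- ann$id == domain
  c(k = sum(on_deg & is_dom), n = sum(on_deg),
    M = sum(is_dom), N = nrow(ann))
}

#' Run a full enrichment analysis over all terms or domains
#'
#' One row per annotation id occurring in the background, with counts,
#' enrichment factor, raw hypergeometric tail probability, and BH-corrected
#' q-value; the BH family is all rows of the run. Rows are sorted by raw
#' p-value, ties by id.
#'
#' @param deg_genes Character vector of DEG ids (non-empty).
#' @param annotations Two-column data frame; in `"gene"` mode repeated
#'   (gene, id) pairs are collapsed, in `"domain"` mode every row is one
#'   instance.
#' @param mode `"gene"` or `"domain"`.
#' @param background,all_genes Gene-mode background choice, see
#'   [gene_mode_counts()].
#' @param q_cutoff Significance threshold on the corrected p (default
#'   0.05).
#' @return Data frame with columns id, k, n, M, N, EF, p_raw, q,
#'   significant.
#' @export
run_enrichment <- function(deg_genes, annotations,
                           mode = c("gene", "domain"),
                           background = c("annotated", "all"),
                           all_genes = NULL, q_cutoff = 0.05) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  if (length(deg_genes) == 0) stop("empty DEG set")
  ann <- .std_annot(annotations)
  if (mode == "gene") {
    ann <- unique(ann)
    bg <- if (background == "annotated") unique(ann$gene) else {
      if (is.null(all_genes))
        stop("'all_genes' required for background='all'")
      unique(as.character(all_genes))
    }
    ann <- ann[ann$gene %in% bg, , drop = FALSE]
    N <- length(bg)
    deg_in <- intersect(unique(deg_genes), bg)
    n <- length(deg_in)
    if (n == 0) stop("no DEG genes in the background")
    M_tab <- table(ann$id)
    k_tab <- table(factor(ann$id[ann$gene %in% deg_in],
                          levels = names(M_tab)))
  } else {
    N <- nrow(ann)
    on_deg <- ann$gene %in% deg_genes
    n <- sum(on_deg)
    if (n == 0) stop("no DEG genes in the background")
    M_tab <- table(ann$id)
    k_tab <- table(factor(ann$id[on_deg], levels = names(M_tab)))
  }
  ids <- names(M_tab)
  k <- as.integer(k_tab)
  M <- as.integer(M_tab)
  p_raw <- hypergeom_tail(k, n, M, N)
  q <- bh_fdr(p_raw)
  out <- data.frame(id = ids, k = k, n = n, M = M, N = N,
                    EF = k * N / (n * M), p_raw = p_raw, q = q,
                    significant = q < q_cutoff, stringsAsFactors = FALSE)
  out[order(out$p_raw, out$id), , drop = FALSE]
}
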