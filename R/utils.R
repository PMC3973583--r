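#' Derive a stage-specific random seed from a global seed
#'
#' Mixes a global integer seed with a stage label so that each stage of a
#' multi-stage run draws from its own reproducible stream, while a single
#' `seed` argument controls the whole run. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"rankprod"`).
#' @return An integer seed in `[0, 2^31 - 19)`.
#' @examples
#' derive_seed(1, "rankprod")
#' derive_seed(1, "scan")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer(((abs(as.numeric(seed)) %% 2039) * 1048573 + h * 7919 + 17) %%
               2147483629)
}

#' Format a count as a percentage of a total
#'
#' The percentage formatter used in run reports: `100 * k / n` rounded to
#' `digits` decimal places (one by default, matching how percentages are
#' reported in summaries, e.g. 20 of 234 genes is 8.5).
#'
#' @param k Numerator count.
#' @param n Denominator count, must be positive.
#' @param digits Decimal places to keep.
#' @return Numeric percentage on the 0-100 scale.
#' @examples
#' format_percent(20, 234)
#' format_percent(11, 143)
#' @export
format_percent <- function(k, n, digits = 1) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round(100 * k / n, digits)
}

# shared argument checks ------------------------------------------------

.check_expr <- function(expr, groups) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr))) stop("'expr' must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop("gene ids must be unique")
  if (any(!is.finite(expr)) || any(expr <= 0))
    stop("all intensities must be strictly positive and finite")
  if (length(groups) != ncol(expr))
    stop("'groups' must have one label per sample column")
  invisible(TRUE)
}

.group_cols <- function(groups, g) {
  idx <- which(as.character(groups) == g)
  if (length(idx) < 1L) stop(sprintf("group '%s' has no samples", g))
  idx
}
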