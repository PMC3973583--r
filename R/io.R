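# TSV readers/writers for every table the pipeline exchanges. All writers
# prepend '#' comment headers recording the package version and the
# parameters of the run; all readers skip such headers and validate the
# payload, reporting line numbers on parse errors.

.write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# amaresist %s",
                     as.character(packageVersion("amaresist"))), con)
  if (length(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(v)
                         paste(format(v, trim = TRUE), collapse = ","),
                         character(1))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  lines <- readLines(path)
  n_header <- 0L
  while (n_header < length(lines) && startsWith(lines[n_header + 1L], "#"))
    n_header <- n_header + 1L
  body <- lines[-seq_len(n_header)]
  if (n_header == 0L) body <- lines
  if (length(body) < 1L || !nzchar(body[1])) stop("no data rows")
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != nf[1]))
    stop(sprintf("ragged row at line %d",
                 n_header + which(nf != nf[1])[1]))
  df <- read.table(text = body, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  attr(df, "n_header") <- n_header
  df
}

#' Read / write a generic stage table TSV
#'
#' The plain-table convention used by every stage output: '#' comment
#' headers recording version and parameters, then a tab-separated table.
#'
#' @param path File path.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
read_tsv <- function(path) {
  df <- .read_tsv(path)
  attr(df, "n_header") <- NULL
  df
}

#' @rdname read_tsv
#' @param df Data frame to write.
#' @param params Named list recorded in the '#' header.
#' @export
write_tsv <- function(df, path, params = list()) {
  .write_tsv(df, path, params)
}

#' Read / write an expression matrix TSV
#'
#' Layout: '#' comment headers, then a header row of sample ids, first
#' column the gene id, remaining cells positive linear-scale intensities.
#' Reading and writing are inverse on canonical files.
#'
#' @param path File path.
#' @return `read_expression()` returns a numeric matrix with gene rownames;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  off <- attr(df, "n_header") + 1L  # data line i sits at file line off + i
  if (nrow(df) == 0) stop("no genes")
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("duplicate gene id '%s' at line %d", ids[dup[1]],
                 off + dup[1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_col <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    bad_row <- which(is.na(suppressWarnings(
      as.numeric(df[[bad_col]]))))[1]
    stop(sprintf("non-numeric intensity at line %d",
                 off + ifelse(is.na(bad_row), 1L, bad_row)))
  }
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix, genes x samples.
#' @param params Named list recorded in the '#' header.
#' @export
write_expression <- function(expr, path, params = list()) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, params)
}

#' Read / write the sample-to-group map
#'
#' Two columns: sample, group.
#'
#' @param path File path.
#' @return A named factor of group labels (names = sample ids).
#' @export
read_group_map <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("sample", "group") %in% names(df)))
  setNames(factor(df$group), df$sample)
}

#' @rdname read_group_map
#' @param groups Named factor or character vector (names = sample ids).
#' @param params Named list recorded in the '#' header.
#' @export
write_group_map <- function(groups, path, params = list()) {
  .write_tsv(data.frame(sample = names(groups),
                        group = as.character(groups),
                        stringsAsFactors = FALSE), path, params)
}

#' Read / write the gene catalog (BED-like TSV)
#'
#' Columns gene, arm, start, end with 0-based half-open coordinates;
#' midpoints are computed on read. Arm lengths are taken from
#' `arm_lengths` when given, otherwise from the maximum end coordinate
#' observed per arm.
#'
#' @param path File path.
#' @param arm_lengths Optional named arm lengths in bp.
#' @return A `gene_catalog` (without annotation tables).
#' @export
read_catalog <- function(path, arm_lengths = NULL) {
  df <- .read_tsv(path)
  off <- attr(df, "n_header") + 1L
  stopifnot(all(c("gene", "arm", "start", "end") %in% names(df)))
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(sprintf("start >= end at line %d", off + bad[1]))
  if (any(df$start < 0)) stop("negative coordinates")
  if (!is.null(arm_lengths)) {
    unknown <- setdiff(unique(df$arm), names(arm_lengths))
    if (length(unknown))
      stop(sprintf("unknown arm '%s'", unknown[1]))
    arms <- arm_lengths
  } else {
    arms <- tapply(df$end, df$arm, max)
    arms <- setNames(as.numeric(arms), names(arms))
  }
  genes <- df[, c("gene", "arm", "start", "end")]
  genes$midpoint <- floor((genes$start + genes$end) / 2)
  structure(list(genes = genes, arms = arms, terms = NULL,
                 domains = NULL),
            class = "gene_catalog")
}

#' @rdname read_catalog
#' @param catalog A `gene_catalog`.
#' @param params Named list recorded in the '#' header.
#' @export
write_catalog <- function(catalog, path, params = list()) {
  .write_tsv(catalog$genes[, c("gene", "arm", "start", "end")], path,
             params)
}

#' Read / write a two-column annotation table
#'
#' (gene, term) or (gene, domain); repeated rows encode domain-instance
#' multiplicity.
#'
#' @param path File path.
#' @return Two-column data frame.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("annotation tables need two columns")
  df[, 1:2]
}

#' @rdname read_annotations
#' @param annotations Two-column data frame.
#' @param params Named list recorded in the '#' header.
#' @export
write_annotations <- function(annotations, path, params = list()) {
  .write_tsv(annotations, path, params)
}

#' Read / write dose-response vial counts
#'
#' Columns concentration, vial, survivors, total (optionally experiment).
#'
#' @param path File path.
#' @return Data frame of vial counts.
#' @export
read_dose_response <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("concentration", "survivors", "total") %in% names(df)))
  df
}

#' @rdname read_dose_response
#' @param data Data frame of vial counts.
#' @param params Named list recorded in the '#' header.
#' @export
write_dose_response <- function(data, path, params = list()) {
  .write_tsv(data, path, params)
}

#' Read / write a qPCR Ct table
#'
#' Columns gene, group, bio_rep, tech_rep, Ct.
#'
#' @param path File path.
#' @return Data frame of Ct values.
#' @export
read_qpcr <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("gene", "group", "bio_rep", "Ct") %in% names(df)))
  df
}

#' @rdname read_qpcr
#' @param data Data frame of Ct values.
#' @param params Named list recorded in the '#' header.
#' @export
write_qpcr <- function(data, path, params = list()) {
  .write_tsv(data, path, params)
}

#' Write the scan score track as BedGraph
#'
#' One line per bin covering the bin's leading `step` interval, suitable
#' for genome-browser display of the log10-inverse-probability score.
#'
#' @param track Scored bins from [score_bins()].
#' @param path File path.
#' @param step Interval written per bin (default the bin spacing, 250 kb).
#' @export
write_bedgraph <- function(track, path, step = 250000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=\"binomial coincidence score\"", con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", track$arm,
                     as.integer(track$start),
                     as.integer(pmin(track$start + step, track$end)),
                     track$score), con)
  invisible(path)
}
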