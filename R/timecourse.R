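#' Construct a time-course expression matrix
#'
#' The central container for one condition's expression series: a gene x
#' sample matrix sampled at \code{T} zeitgeber times with a fixed number of
#' replicates per timepoint.  Columns are ordered timepoint-major
#' (all replicates of the first timepoint, then the second, ...) and named
#' \code{"<ZT>_r<rep>"}.  Values are nonnegative (FPKM-like); samples pruned
#' by outlier filtering are tracked in \code{missing_mask} rather than
#' dropped, so downstream rank statistics can condition on the exact tie
#' structure that remains.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param times_h sampling times in ZT hours, strictly increasing, all in
#'   \code{[0, 24)}.
#' @param n_replicates integer vector of per-timepoint replicate counts
#'   (length \code{length(times_h)}), or a single count recycled.
#' @param condition condition label string.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   \code{rownames(values)}.
#' @param missing_mask optional logical matrix of the same dimension as
#'   \code{values}; \code{TRUE} marks a pruned/missing sample.
#' @return an object of class \code{"timecourse_matrix"}.
#' @examples
#' tc <- timecourse_matrix(matrix(1:36, 2, 18,
#'                                dimnames = list(c("g1", "g2"), NULL)),
#'                         times_h = c(3, 7, 11, 15, 19, 23),
#'                         n_replicates = 3, condition = "saline")
#' dim(tc$values)
#' @export
timecourse_matrix <- function(values, times_h, n_replicates, condition,
                              gene_ids = rownames(values),
                              missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (length(n_replicates) == 1L)
    n_replicates <- rep(as.integer(n_replicates), length(times_h))
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) != length(times_h))
    stopf("'n_replicates' must have one entry per timepoint")
  if (any(diff(times_h) <= 0) || any(times_h < 0) || any(times_h >= 24))
    stopf("'times_h' must be strictly increasing within [0, 24)")
  if (ncol(values) != sum(n_replicates))
    stopf("matrix has %d sample columns but replicate counts sum to %d",
          ncol(values), sum(n_replicates))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stopf("'gene_ids' length does not match row count")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  if (!is.logical(missing_mask) || !all(dim(missing_mask) == dim(values)))
    stopf("'missing_mask' must be a logical matrix matching 'values'")
  missing_mask <- missing_mask | is.na(values)
  present <- values[!missing_mask]
  if (any(!is.finite(present)))
    stopf("non-finite expression values present outside the missing mask")
  if (any(present < 0))
    stopf("negative expression values are not allowed")
  rownames(values) <- gene_ids
  rownames(missing_mask) <- gene_ids
  cn <- tc_sample_names(times_h, n_replicates)
  colnames(values) <- cn
  colnames(missing_mask) <- cn
  structure(
    list(values = values, times_h = as.numeric(times_h),
         n_replicates = n_replicates, condition = as.character(condition),
         gene_ids = gene_ids, missing_mask = missing_mask),
    class = "timecourse_matrix")
}

tc_sample_names <- function(times_h, n_replicates) {
  unlist(mapply(function(t, r) paste0(t, "_r", seq_len(r)),
                times_h, n_replicates, SIMPLIFY = FALSE))
}

#' Timepoint index of each sample column
#' @param tc a \code{timecourse_matrix}
#' @return integer vector, one entry per column of \code{tc$values}
#' @export
tc_timepoint_index <- function(tc) {
  rep(seq_along(tc$times_h), tc$n_replicates)
}

#' Sampling time (ZT hours) of each sample column
#' @param tc a \code{timecourse_matrix}
#' @return numeric vector, one entry per column
#' @export
tc_sample_times <- function(tc) {
  tc$times_h[tc_timepoint_index(tc)]
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf(
    "timecourse_matrix: %d genes x %d samples (condition '%s')\n",
    nrow(x$values), ncol(x$values), x$condition))
  cat(sprintf("  ZT %s; replicates %s; %d masked cells\n",
              paste(x$times_h, collapse = ","),
              paste(x$n_replicates, collapse = ","),
              sum(x$missing_mask)))
  invisible(x)
}

#' Write a time-course matrix to TSV
#'
#' Layout: header \code{gene_id} plus one column per sample named
#' \code{"<ZT>_r<rep>"}, timepoint-major.  Masked cells are written as
#' \code{NA}.
#'
#' @param tc a \code{timecourse_matrix}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_expression_matrix <- function(tc, path) {
  out <- tc$values
  out[tc$missing_mask] <- NA
  df <- data.frame(gene_id = tc$gene_ids, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-course expression matrix from TSV
#'
#' Strictly validated reader for the layout written by
#' \code{\link{write_expression_matrix}}: a header line with
#' \code{gene_id} followed by sample names, one row per gene.  Cells must
#' be nonnegative numbers or the literal \code{NA} (a pruned sample);
#' anything else is rejected with the offending gene and column named.
#'
#' @param path TSV file path.
#' @param condition_label label to attach to the returned matrix.
#' @param times_h sampling grid in ZT hours.
#' @param n_replicates per-timepoint replicate counts (or one count,
#'   recycled).
#' @return a \code{\link{timecourse_matrix}}.
#' @export
read_expression_matrix <- function(path, condition_label, times_h,
                                   n_replicates) {
  if (length(n_replicates) == 1L)
    n_replicates <- rep(as.integer(n_replicates), length(times_h))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L)
    stopf("malformed expression TSV '%s': fewer than 2 columns", path)
  n_samp <- ncol(raw) - 1L
  if (n_samp != sum(n_replicates))
    stopf(paste0("column-count mismatch in '%s': %d sample columns, ",
                 "expected %d (= sum of replicate counts)"),
          path, n_samp, sum(n_replicates))
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stopf("duplicate gene id(s) in '%s': %s", path,
          paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  missing_cell <- is.na(cells) | cells %in% c("NA", "")
  bad <- which(is.na(num) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-numeric cell in '%s' at gene '%s', column '%s': '%s'",
          path, gene_ids[bad[1L, 1L]], colnames(raw)[-1L][bad[1L, 2L]],
          cells[bad[1L, , drop = FALSE]])
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative value in '%s' at gene '%s', column '%s'",
          path, gene_ids[neg[1L, 1L]], colnames(raw)[-1L][neg[1L, 2L]])
  timecourse_matrix(num, times_h = times_h, n_replicates = n_replicates,
                    condition = condition_label, gene_ids = gene_ids)
}
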