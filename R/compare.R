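#' Partition two rhythmic gene sets (Venn decomposition)
#'
#' Splits the union of two conditions' rhythmic sets into genes exclusive
#' to the first, common to both, and exclusive to the second, with counts
#' and percentages of the combined union (rounded half-up to integers,
#' the convention used when such Venn counts are reported as
#' "50% / ~13% / ~37%").
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param label_a,label_b condition labels for reporting.
#' @return list of class \code{"rhythm_partition"}: the three gene-id
#'   sets, \code{counts}, \code{percent} (integer convention),
#'   \code{fraction} (raw), \code{total}, and per-input totals
#'   \code{n_a}, \code{n_b}.
#' @examples
#' p <- partition_rhythm_sets(c("a", "b", "c"), c("b", "c", "d"))
#' p$counts
#' @export
partition_rhythm_sets <- function(set_a, set_b, label_a = "A",
                                  label_b = "B") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  exclusive_a <- setdiff(set_a, set_b)
  common <- intersect(set_a, set_b)
  exclusive_b <- setdiff(set_b, set_a)
  counts <- c(exclusive_a = length(exclusive_a), common = length(common),
              exclusive_b = length(exclusive_b))
  total <- sum(counts)
  fraction <- if (total > 0) counts / total else counts * 0
  structure(
    list(label_a = label_a, label_b = label_b,
         exclusive_a = exclusive_a, common = common,
         exclusive_b = exclusive_b, counts = counts, total = total,
         fraction = fraction,
         percent = round_half_up(100 * fraction),
         n_a = length(set_a), n_b = length(set_b)),
    class = "rhythm_partition")
}

#' @export
print.rhythm_partition <- function(x, ...) {
  cat(sprintf("rhythm_partition: %s vs %s, union %d genes\n", x$label_a,
              x$label_b, x$total))
  cat(sprintf("  %s-only %d (%d%%), common %d (%d%%), %s-only %d (%d%%)\n",
              x$label_a, x$counts[1L], x$percent[1L], x$counts[2L],
              x$percent[2L], x$label_b, x$counts[3L], x$percent[3L]))
  invisible(x)
}

#' Phase histogram of a rhythmic gene set
#'
#' Counts of fitted peak phases in half-open bins over ZT \code{[0, 24)};
#' the numeric basis of radar-style phase plots.
#'
#' @param results data.frame from \code{\link{jtk_cycle}}.
#' @param gene_set gene ids to tabulate (must all be present in
#'   \code{results} with a defined phase).
#' @param bin_h bin width in hours; must divide 24.
#' @return integer vector of counts named by bin start, summing to
#'   \code{length(unique(gene_set))}.
#' @export
phase_histogram <- function(results, gene_set, bin_h = 2) {
  if (24 %% bin_h != 0) stopf("'bin_h' must divide 24")
  gene_set <- unique(as.character(gene_set))
  idx <- match(gene_set, results$gene_id)
  if (anyNA(idx))
    stopf("gene(s) without rhythm results: %s",
          paste(utils::head(gene_set[is.na(idx)], 3L), collapse = ", "))
  ph <- results$phase_zt[idx]
  if (anyNA(ph)) stopf("gene(s) with undefined phase in 'gene_set'")
  breaks <- seq(0, 24, by = bin_h)
  counts <- table(cut(ph %% 24, breaks = breaks, right = FALSE,
                      labels = breaks[-length(breaks)]))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Classify amplitude changes of common oscillators
#'
#' For genes rhythmic in both conditions, the ratio of the second
#' condition's fitted amplitude to the first is classed as
#' \code{higher} (ratio > 1 + tol), \code{lower} (ratio < 1 - tol) or
#' \code{equal}; the tolerance absorbs estimator noise around a true
#' ratio of 1 and is a reporting convention, not a test.
#'
#' @param results_a,results_b \code{\link{jtk_cycle}} outputs for the two
#'   conditions.
#' @param common gene ids rhythmic in both.
#' @param tol relative tolerance for "equal" (default 0.05).
#' @return list of class \code{"amplitude_taxonomy"}: per-gene data.frame
#'   (\code{gene_id, amplitude_a, amplitude_b, ratio, class}),
#'   \code{counts}, \code{percent} (half-up integers) and
#'   \code{fraction}.
#' @export
classify_amplitude_change <- function(results_a, results_b, common,
                                      tol = 0.05) {
  common <- unique(as.character(common))
  ia <- match(common, results_a$gene_id)
  ib <- match(common, results_b$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stopf("every common gene needs amplitudes in both result sets")
  a <- results_a$amplitude[ia]
  b <- results_b$amplitude[ib]
  ratio <- ifelse(a > 0, b / a, ifelse(b > 0, Inf, 1))
  if (any(a == 0 & b > 0))
    warnf("%d gene(s) with zero amplitude in the first condition classed 'higher'",
          sum(a == 0 & b > 0))
  cls <- ifelse(abs(ratio - 1) <= tol, "equal",
                ifelse(ratio > 1 + tol, "higher", "lower"))
  per_gene <- data.frame(gene_id = common, amplitude_a = a,
                         amplitude_b = b, ratio = ratio, class = cls,
                         stringsAsFactors = FALSE)
  counts <- c(higher = sum(cls == "higher"), lower = sum(cls == "lower"),
              equal = sum(cls == "equal"))
  fraction <- if (length(common)) counts / length(common) else counts * 0
  structure(list(per_gene = per_gene, counts = counts,
                 fraction = fraction,
                 percent = round_half_up(100 * fraction), tol = tol),
            class = "amplitude_taxonomy")
}

#' @export
print.amplitude_taxonomy <- function(x, ...) {
  cat(sprintf(
    "amplitude_taxonomy: %d common genes; higher %d%%, lower %d%%, equal %d%% (tol %.2f)\n",
    nrow(x$per_gene), x$percent["higher"], x$percent["lower"],
    x$percent["equal"], x$tol))
  invisible(x)
}

#' Phase-sorted, row-normalized heatmap matrix
#'
#' Per gene: missing-aware replicate means at each timepoint, then a row
#' z-score (mean 0, sd 1; constant rows map to all zeros).  Rows are
#' ordered by ascending fitted phase, ties broken by gene id — the matrix
#' behind phase-sorted heatmaps of circadian transcripts.
#'
#' @param tc a \code{\link{timecourse_matrix}}.
#' @param results \code{\link{jtk_cycle}} output for the same genes.
#' @param gene_set genes to include (subset of the matrix's genes).
#' @return numeric matrix, one row per gene (rownames = gene ids), one
#'   column per timepoint (colnames = ZT hours).
#' @export
heatmap_matrix <- function(tc, results, gene_set) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  gene_set <- unique(as.character(gene_set))
  gi <- match(gene_set, tc$gene_ids)
  if (anyNA(gi))
    stopf("gene(s) absent from the expression matrix: %s",
          paste(utils::head(gene_set[is.na(gi)], 3L), collapse = ", "))
  tp_idx <- tc_timepoint_index(tc)
  vals <- tc$values
  vals[tc$missing_mask] <- NA
  means <- t(vapply(gi, function(g) {
    vapply(seq_along(tc$times_h), function(tp) {
      mean(vals[g, tp_idx == tp], na.rm = TRUE)
    }, 0)
  }, numeric(length(tc$times_h))))
  z <- t(apply(means, 1L, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  rownames(z) <- gene_set
  colnames(z) <- tc$times_h
  ph <- results$phase_zt[match(gene_set, results$gene_id)]
  ord <- order(ph, gene_set)
  z[ord, , drop = FALSE]
}
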