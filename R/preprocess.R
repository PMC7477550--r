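# Dean-Dixon one-sided 95% critical values for the r10 ratio, n = 3..7.
DIXON_Q_CRIT <- c(`3` = 0.941, `4` = 0.765, `5` = 0.642, `6` = 0.560,
                  `7` = 0.507)

#' Dixon's Q test for a single outlier among replicates
#'
#' The suspect value is the extreme (minimum or maximum) whose gap to its
#' nearest neighbour is larger; \code{Q = gap / range}.  The suspect is
#' flagged when Q exceeds the Dean-Dixon critical value at alpha = 0.05
#' (one-sided; 0.941 for n = 3).  A zero range makes the test undefined
#' and nothing is flagged.
#'
#' @param values 3 to 7 finite replicate values.
#' @return list with \code{q} (the statistic, \code{NA} for zero range)
#'   and \code{outlier_index} (index into \code{values}, or \code{NA}).
#' @examples
#' dixon_q(c(1.0, 1.1, 9.0))  # flags the third value
#' @export
dixon_q <- function(values) {
  n <- length(values)
  if (n < 3L) stopf("Dixon's test needs at least 3 values, got %d", n)
  if (n > 7L) stopf("Dixon's test (r10) supported for n <= 7, got %d", n)
  if (any(!is.finite(values))) stopf("values must be finite")
  rng <- max(values) - min(values)
  if (rng == 0) return(list(q = NA_real_, outlier_index = NA_integer_))
  s <- sort(values)
  gap_low <- s[2L] - s[1L]
  gap_high <- s[n] - s[n - 1L]
  if (gap_high >= gap_low) {
    q <- gap_high / rng
    idx <- which(values == s[n])[1L]
  } else {
    q <- gap_low / rng
    idx <- which(values == s[1L])[1L]
  }
  crit <- DIXON_Q_CRIT[[as.character(n)]]
  list(q = q,
       outlier_index = if (q > crit) idx else NA_integer_)
}

#' Prune replicate outliers with Dixon's Q test
#'
#' For every gene x timepoint with at least 3 non-missing replicates,
#' Dixon's test is run on the replicate values and at most one flagged
#' replicate is masked.  Timepoints with fewer than 3 usable replicates
#' are skipped, so a second pass is a no-op.
#'
#' @param tc a \code{\link{timecourse_matrix}}.
#' @param alpha kept for interface clarity; only the tabulated 0.05 level
#'   is available.
#' @return list with \code{matrix} (the pruned \code{timecourse_matrix})
#'   and \code{report}, a data.frame of pruned cells (\code{gene_id},
#'   \code{timepoint}, \code{time_h}, \code{replicate}, \code{q}).
#' @export
prune_outliers <- function(tc, alpha = 0.05) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  if (alpha != 0.05)
    stopf("only the tabulated alpha = 0.05 critical values are available")
  tp_idx <- tc_timepoint_index(tc)
  mask <- tc$missing_mask
  rep_rows <- list()
  for (tp in seq_along(tc$times_h)) {
    cols <- which(tp_idx == tp)
    for (g in seq_len(nrow(tc$values))) {
      usable <- cols[!mask[g, cols]]
      if (length(usable) < 3L || length(usable) > 7L) next
      res <- dixon_q(tc$values[g, usable])
      if (!is.na(res$outlier_index)) {
        col <- usable[res$outlier_index]
        mask[g, col] <- TRUE
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          gene_id = tc$gene_ids[g], timepoint = tp,
          time_h = tc$times_h[tp],
          replicate = match(col, cols), q = res$q,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(gene_id = character(), timepoint = integer(),
               time_h = numeric(), replicate = integer(), q = numeric(),
               stringsAsFactors = FALSE)
  out <- tc
  out$missing_mask <- mask
  list(matrix = out, report = report)
}

#' Low-expression filter and enrichment background
#'
#' A gene is dropped from the pairwise analysis when all of its
#' non-missing values in every supplied condition fall below
#' \code{threshold} (the "consistently low" rule; FPKM < 1 by default).
#' The enrichment background keeps every gene with any positive value in
#' any condition, so the background is a superset of the analysis set.
#' With \code{rule = "mean"} a gene is instead dropped when its mean
#' non-missing value is below threshold in every condition.
#'
#' @param matrices list of \code{\link{timecourse_matrix}} objects sharing
#'   the same gene ids (typically the two conditions of one pairwise
#'   comparison).
#' @param threshold expression floor (default 1, FPKM-like units).
#' @param rule \code{"all_below"} (default) or \code{"mean"}.
#' @return list with \code{matrices} (gene-filtered copies),
#'   \code{analysis_genes}, \code{background} (gene ids with any value
#'   > 0), and \code{dropped}.
#' @export
filter_low_expression <- function(matrices, threshold = 1,
                                  rule = c("all_below", "mean")) {
  rule <- match.arg(rule)
  if (inherits(matrices, "timecourse_matrix")) matrices <- list(matrices)
  ids <- matrices[[1L]]$gene_ids
  for (m in matrices)
    if (!identical(m$gene_ids, ids))
      stopf("all matrices must share the same gene ids")
  low <- rep(TRUE, length(ids))
  any_pos <- rep(FALSE, length(ids))
  for (m in matrices) {
    v <- m$values
    v[m$missing_mask] <- NA
    if (rule == "all_below") {
      cond_low <- apply(v, 1L, function(r) {
        r <- r[!is.na(r)]
        length(r) == 0L || all(r < threshold)
      })
    } else {
      cond_low <- apply(v, 1L, function(r) {
        r <- r[!is.na(r)]
        length(r) == 0L || mean(r) < threshold
      })
    }
    low <- low & cond_low
    any_pos <- any_pos | apply(v, 1L, function(r) any(r > 0, na.rm = TRUE))
  }
  keep <- !low
  out <- lapply(matrices, function(m) {
    m$values <- m$values[keep, , drop = FALSE]
    m$missing_mask <- m$missing_mask[keep, , drop = FALSE]
    m$gene_ids <- m$gene_ids[keep]
    m
  })
  list(matrices = out, analysis_genes = ids[keep],
       background = ids[any_pos], dropped = ids[low])
}
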