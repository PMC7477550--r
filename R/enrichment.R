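#' Motif-quality site filter
#'
#' The site-quality rule applied before any promoter lookup: keep sites
#' with \code{bbls > min_bbls} and \code{site_fdr < max_site_fdr} (both
#' strict), and exclude a TF outright from enrichment testing when more
#' than \code{max_sites_per_tf} of its sites survive — such motifs are too
#' short or degenerate to be informative.
#'
#' @param min_bbls minimum BBLS conservation score (strict; default 1).
#' @param max_site_fdr maximum per-site FDR (strict; default 0.25).
#' @param max_sites_per_tf degenerate-motif cutoff (default 50000).
#' @return list of class \code{"site_filter"}.
#' @export
site_filter <- function(min_bbls = 1, max_site_fdr = 0.25,
                        max_sites_per_tf = 50000) {
  if (!is.finite(min_bbls) || !is.finite(max_site_fdr))
    stopf("filter thresholds must be finite")
  if (max_sites_per_tf < 1) stopf("'max_sites_per_tf' must be >= 1")
  structure(list(min_bbls = min_bbls, max_site_fdr = max_site_fdr,
                 max_sites_per_tf = max_sites_per_tf),
            class = "site_filter")
}

apply_site_filter <- function(sites, filter) {
  sites[sites$bbls > filter$min_bbls &
          sites$site_fdr < filter$max_site_fdr, , drop = FALSE]
}

#' Strand-aware promoter windows
#'
#' For a + strand gene the window is \code{[tss - upstream,
#' tss + downstream)}; for a - strand gene upstream extends to larger
#' coordinates, so the window reflects to \code{[tss - downstream,
#' tss + upstream)}.  Coordinates are 0-based half-open and clamped at 0.
#'
#' @param annotation data.frame \code{gene_id, chrom, tss, strand}.
#' @param upstream_bp,downstream_bp window extent relative to the TSS.
#' @return data.frame \code{gene_id, chrom, start, end}.
#' @export
promoter_windows <- function(annotation, upstream_bp = 10000,
                             downstream_bp = 2000) {
  if (upstream_bp < 0 || downstream_bp < 0 ||
      upstream_bp + downstream_bp <= 0)
    stopf("window extents must be >= 0 and the window nonempty")
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream_bp,
                  annotation$tss - downstream_bp)
  end <- ifelse(plus, annotation$tss + downstream_bp,
                annotation$tss + upstream_bp)
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = pmax(0, start), end = pmax(1, end),
             stringsAsFactors = FALSE)
}

# >= 1 bp overlap between each gene window and any of the intervals;
# both sides are 0-based half-open.
windows_overlap_any <- function(win, ivl) {
  hit <- logical(nrow(win))
  if (!nrow(ivl)) return(hit)
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    ii <- which(ivl$chrom == ch)
    if (!length(ii)) next
    q <- IRanges::IRanges(start = win$start[wi] + 1L, end = win$end[wi])
    s <- IRanges::IRanges(start = ivl$start[ii] + 1L, end = ivl$end[ii])
    hit[wi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Genes with a quality-filtered binding site in their promoter window
#'
#' A gene qualifies when at least one site of \code{tf} passing the
#' quality filter overlaps (>= 1 bp) its strand-aware promoter window.
#'
#' @param tf TF name.
#' @param sites a site table (see \code{\link{read_bed_intervals}}).
#' @param annotation TSS annotation data.frame.
#' @param window \code{c(upstream_bp, downstream_bp)}; default the
#'   enrichment window \code{c(10000, 2000)}.
#' @param filter a \code{\link{site_filter}}.
#' @return character vector of gene ids.
#' @export
genes_with_site <- function(tf, sites, annotation,
                            window = c(10000, 2000),
                            filter = site_filter()) {
  if (!tf %in% sites$tf_name) {
    warnf("TF '%s' has no sites in the table", tf)
    return(character())
  }
  keep <- apply_site_filter(sites[sites$tf_name == tf, , drop = FALSE],
                            filter)
  win <- promoter_windows(annotation, window[1L], window[2L])
  annotation$gene_id[windows_overlap_any(win, keep)]
}

#' Promoter TFBS Fisher enrichment
#'
#' For every TF, genes of the study set and of the rest of the background
#' are classed by presence/absence of a quality-filtered site in the
#' promoter window, and the 2x2 table (study set vs background-minus-set,
#' disjoint cells) is scored with the one-sided exact hypergeometric
#' enrichment p-value.  TFs whose filtered site count exceeds the
#' degenerate-motif cutoff are excluded from testing.  Records are ranked
#' by \code{-log10 p} descending.
#'
#' @param gene_set study gene ids (must be a subset of
#'   \code{background}).
#' @param background background gene universe (ids).
#' @param sites site table.
#' @param annotation TSS annotation covering the background genes.
#' @param tf_names TFs to test; defaults to all TFs in \code{sites}.
#' @param window promoter window \code{c(upstream, downstream)}; default
#'   \code{c(10000, 2000)}.
#' @param filter a \code{\link{site_filter}}.
#' @return data.frame with one row per TF: \code{tf_name, k, m, K, M,
#'   odds_ratio, p_one_sided, neg_log10_p, excluded_reason, n_sites}.
#' @export
fisher_enrichment <- function(gene_set, background, sites, annotation,
                              tf_names = NULL, window = c(10000, 2000),
                              filter = site_filter()) {
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  if (!all(gene_set %in% background))
    stopf("'gene_set' must be a subset of 'background'")
  tf_names <- tf_names %||% sort(unique(sites$tf_name))
  win <- promoter_windows(annotation, window[1L], window[2L])
  win <- win[win$gene_id %in% background, , drop = FALSE]
  in_set <- win$gene_id %in% gene_set
  n_set <- length(gene_set)
  n_rest <- length(background) - n_set
  filt <- apply_site_filter(sites, filter)
  rows <- lapply(tf_names, function(tf) {
    tf_sites <- filt[filt$tf_name == tf, , drop = FALSE]
    n_sites <- nrow(tf_sites)
    if (n_sites > filter$max_sites_per_tf) {
      return(data.frame(tf_name = tf, k = NA_integer_, m = NA_integer_,
                        K = NA_integer_, M = NA_integer_,
                        odds_ratio = NA_real_, p_one_sided = NA_real_,
                        neg_log10_p = NA_real_,
                        excluded_reason = "degenerate motif",
                        n_sites = n_sites, stringsAsFactors = FALSE))
    }
    hit <- windows_overlap_any(win, tf_sites)
    k <- sum(hit & in_set)
    m <- n_set - k
    K <- sum(hit & !in_set)
    M <- n_rest - K
    p <- stats::phyper(k - 1L, k + K, m + M, n_set, lower.tail = FALSE)
    orr <- if (m * K > 0) (k * M) / (m * K) else if (k * M > 0) Inf
      else NA_real_
    data.frame(tf_name = tf, k = k, m = m, K = K, M = M,
               odds_ratio = orr, p_one_sided = p,
               neg_log10_p = -log10(p), excluded_reason = NA_character_,
               n_sites = n_sites, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-replace(out$neg_log10_p, is.na(out$neg_log10_p), -Inf),
            out$tf_name), , drop = FALSE]
}

#' Cross-condition meta-analysis of TFBS enrichment
#'
#' Flags TFs whose promoter enrichment is condition-exclusive.  Under the
#' default threshold rule a TF is exclusive to condition c when its
#' enrichment p is <= \code{alpha_tf} there and > \code{alpha_tf} in every
#' other condition; the \code{"top_k"} rule instead deems a TF
#' "significant" in a condition when it ranks among that condition's top
#' k TFs by \code{-log10 p}.  Excluded (degenerate-motif) TFs count as
#' non-significant everywhere.
#'
#' @param records_by_condition named list of
#'   \code{\link{fisher_enrichment}} outputs, one per condition, over the
#'   same TF universe.
#' @param alpha_tf significance threshold (default 0.01).
#' @param rule \code{"threshold"} (default) or \code{"top_k"}.
#' @param top_k rank cutoff for the \code{"top_k"} rule.
#' @return data.frame: \code{tf_name}, one \code{neg_log10_p.<condition>}
#'   column per condition, \code{n_significant} and \code{exclusive}
#'   (a condition name, \code{"shared"} or \code{"none"}).
#' @export
meta_exclusive_tfs <- function(records_by_condition, alpha_tf = 0.01,
                               rule = c("threshold", "top_k"),
                               top_k = 1L) {
  rule <- match.arg(rule)
  conds <- names(records_by_condition)
  if (is.null(conds) || any(!nzchar(conds)))
    stopf("'records_by_condition' must be a named list")
  universes <- lapply(records_by_condition, function(r) sort(r$tf_name))
  if (!length(Reduce(intersect, universes)))
    stopf("conditions have disjoint TF universes")
  if (!all(vapply(universes, identical, TRUE, universes[[1L]])))
    stopf("all conditions must test the same TF universe")
  tfs <- universes[[1L]]
  pmat <- sapply(records_by_condition, function(r) {
    p <- r$p_one_sided[match(tfs, r$tf_name)]
    replace(p, is.na(p), 1)  # excluded motifs: non-significant
  })
  sig <- if (rule == "threshold") {
    pmat <= alpha_tf
  } else {
    apply(pmat, 2L, function(p) rank(p, ties.method = "min") <= top_k)
  }
  n_sig <- rowSums(sig)
  exclusive <- ifelse(n_sig == 0L, "none",
                      ifelse(n_sig > 1L, "shared",
                             conds[max.col(sig, ties.method = "first")]))
  nlp <- -log10(pmat)
  colnames(nlp) <- paste0("neg_log10_p.", conds)
  out <- data.frame(tf_name = tfs, nlp, n_significant = n_sig,
                    exclusive = exclusive, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a TF's target-gene set from motifs and ChIP peaks
#'
#' A gene is a target when it carries a quality-filtered motif site of
#' the TF in the (narrow, default -3000/+1000) promoter window and — when
#' \code{require_peak} — at least one ChIP peak overlaps the same window.
#' With \code{require_peak = FALSE} this reduces exactly to
#' \code{\link{genes_with_site}}; with \code{combine = "union"} either
#' kind of evidence suffices.
#'
#' @param tf TF name.
#' @param sites site table.
#' @param peaks peak table (ChIP evidence).
#' @param annotation TSS annotation.
#' @param window promoter window, default \code{c(3000, 1000)}.
#' @param filter a \code{\link{site_filter}}.
#' @param require_peak require ChIP support in addition to the motif
#'   (default TRUE).
#' @param combine \code{"intersection"} (default) or \code{"union"} of
#'   motif and peak evidence when \code{require_peak} is TRUE.
#' @return character vector of gene ids.
#' @export
build_target_set <- function(tf, sites, peaks, annotation,
                             window = c(3000, 1000),
                             filter = site_filter(),
                             require_peak = TRUE,
                             combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  motif_genes <- genes_with_site(tf, sites, annotation, window, filter)
  if (!require_peak) return(motif_genes)
  win <- promoter_windows(annotation, window[1L], window[2L])
  peak_genes <- annotation$gene_id[windows_overlap_any(win, peaks)]
  if (combine == "intersection") intersect(motif_genes, peak_genes)
  else union(motif_genes, peak_genes)
}

#' Generic gene-set (pathway) Fisher enrichment
#'
#' One-sided hypergeometric enrichment of a study set against each set of
#' a GMT-style collection, members intersected with the background before
#' testing, with Benjamini-Hochberg q-values across tested sets.  Serves
#' the role pathway servers play in published analyses, on local
#' collections.
#'
#' @param gene_set study gene ids (subset of \code{background}).
#' @param background gene universe.
#' @param collection named list of member-id vectors
#'   (\code{\link{read_gene_sets}}).
#' @return data.frame ranked by \code{-log10 p}: \code{set_name,
#'   n_overlap, n_set, n_study, p_one_sided, neg_log10_p, q_bh}.
#' @export
gene_set_enrichment <- function(gene_set, background, collection) {
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  if (!all(gene_set %in% background))
    stopf("'gene_set' must be a subset of 'background'")
  eff <- lapply(collection, intersect, background)
  eff <- eff[lengths(eff) > 0L]
  if (!length(eff)) {
    warnf("no gene set overlaps the background")
    return(data.frame(set_name = character(), n_overlap = integer(),
                      n_set = integer(), n_study = integer(),
                      p_one_sided = numeric(), neg_log10_p = numeric(),
                      q_bh = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(gene_set)
  rows <- lapply(names(eff), function(nm) {
    members <- eff[[nm]]
    k <- length(intersect(members, gene_set))
    K <- length(members)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, n_overlap = k, n_set = K, n_study = n,
               p_one_sided = p, neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_one_sided, method = "BH")
  out <- out[order(-out$neg_log10_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
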