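#' Read TF binding sites or ChIP peaks from a BED-like file
#'
#' Intervals are 0-based half-open, exactly as in BED: a 1-bp site at
#' position k is \code{(k, k+1)}.  For \code{kind = "sites"} columns 4-6
#' carry the TF name, the BBLS conservation score and the per-site FDR;
#' for \code{kind = "peaks"} only the first three columns are used.  Extra
#' columns beyond the first six are ignored with a warning.
#'
#' @param path BED-like TSV file (no header).
#' @param kind \code{"sites"} or \code{"peaks"}.
#' @return a data.frame: for sites, columns \code{tf_name, chrom, start,
#'   end, bbls, site_fdr}; for peaks, \code{chrom, start, end}.
#' @export
read_bed_intervals <- function(path, kind = c("sites", "peaks")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(if (kind == "sites") empty_site_table() else empty_peak_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (kind == "sites") 6L else 3L
  nf <- lengths(fields)
  if (any(nf < need))
    stopf("line %d of '%s': expected >= %d tab-separated columns, got %d",
          which(nf < need)[1L], path, need, min(nf))
  if (any(nf > 6L))
    warnf("'%s': columns beyond the sixth are ignored", path)
  get <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get(1L)
  start <- suppressWarnings(as.numeric(get(2L)))
  end <- suppressWarnings(as.numeric(get(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stopf("line %d of '%s': non-integer interval coordinates", bad[1L], path)
  bad <- which(start >= end)
  if (length(bad))
    stopf("line %d of '%s': start >= end (%d >= %d); intervals are 0-based half-open",
          bad[1L], path, start[bad[1L]], end[bad[1L]])
  if (kind == "peaks") {
    out <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), stringsAsFactors = FALSE)
    class(out) <- c("peak_table", "data.frame")
    return(out)
  }
  bbls <- suppressWarnings(as.numeric(get(5L)))
  fdr <- suppressWarnings(as.numeric(get(6L)))
  if (anyNA(bbls))
    stopf("line %d of '%s': non-numeric BBLS score", which(is.na(bbls))[1L],
          path)
  bad <- which(is.na(fdr) | fdr < 0 | fdr > 1)
  if (length(bad))
    stopf("line %d of '%s': site FDR outside [0, 1]", bad[1L], path)
  out <- data.frame(tf_name = get(4L), chrom = chrom,
                    start = as.integer(start), end = as.integer(end),
                    bbls = bbls, site_fdr = fdr, stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  out
}

empty_site_table <- function() {
  out <- data.frame(tf_name = character(), chrom = character(),
                    start = integer(), end = integer(), bbls = numeric(),
                    site_fdr = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  out
}

empty_peak_table <- function() {
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Write a site or peak table back to BED
#'
#' Inverse of \code{\link{read_bed_intervals}}; sites are written as
#' 6-column BED (\code{chrom start end tf_name bbls site_fdr}), peaks as
#' 3-column BED.
#'
#' @param x a site or peak data.frame from \code{read_bed_intervals} or
#'   the synthetic generator.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
write_bed_intervals <- function(x, path) {
  df <- if (all(c("tf_name", "bbls", "site_fdr") %in% names(x))) {
    data.frame(x$chrom, x$start, x$end, x$tf_name,
               format(x$bbls, digits = 15, trim = TRUE, scientific = FALSE),
               format(x$site_fdr, digits = 15, trim = TRUE,
                      scientific = FALSE))
  } else {
    data.frame(x$chrom, x$start, x$end)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene TSS annotation from BED
#'
#' Expects 6-column BED with the gene id in column 4 and strand in column
#' 6; the TSS is the interval start for + strand genes and \code{end - 1}
#' for - strand genes (both 0-based).
#'
#' @param path BED6 file.
#' @return data.frame \code{gene_id, chrom, tss, strand}.
#' @export
read_tss_annotation <- function(path) {
  raw <- read_bed_like(path, 6L)
  strand <- raw[[6L]]
  if (!all(strand %in% c("+", "-")))
    stopf("'%s': strand column must be '+' or '-'", path)
  tss <- ifelse(strand == "+", as.integer(raw[[2L]]),
                as.integer(raw[[3L]]) - 1L)
  out <- data.frame(gene_id = raw[[4L]], chrom = raw[[1L]], tss = tss,
                    strand = strand, stringsAsFactors = FALSE)
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup))
    stopf("duplicate gene id(s) in annotation '%s': %s", path,
          paste(dup, collapse = ", "))
  if (any(out$tss < 0)) stopf("'%s': negative TSS coordinate", path)
  out
}

read_bed_like <- function(path, need) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need))
    stopf("line %d of '%s': expected >= %d columns", which(nf < need)[1L],
          path, need)
  as.data.frame(do.call(rbind, lapply(fields, `[`, seq_len(need))),
                stringsAsFactors = FALSE)
}

#' Write gene TSS annotation as BED6
#' @param annotation data.frame \code{gene_id, chrom, tss, strand}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_tss_annotation <- function(annotation, path) {
  start <- ifelse(annotation$strand == "+", annotation$tss,
                  annotation$tss)
  df <- data.frame(annotation$chrom, start, start + 1L,
                   annotation$gene_id, 0L, annotation$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' GMT format: one set per line, \code{name<TAB>description<TAB>member...}.
#' Duplicate members within a set are collapsed; empty sets and duplicate
#' set names are rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors, with a \code{"descriptions"}
#'   attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("line %d of '%s': a GMT set needs a name, description and >= 1 member",
          which(nf < 3L)[1L], path)
  names_ <- vapply(fields, `[[`, "", 1L)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup))
    stopf("duplicate gene-set name(s) in '%s': %s", path,
          paste(dup, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), names_)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors (optionally with a
#'   \code{"descriptions"} attribute)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
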