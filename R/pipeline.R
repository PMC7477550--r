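#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with defaults equal
#' to the conventional published values where one exists: rhythm cutoff
#' alpha = 0.01 on the adjusted p, period window 20-28 h, enrichment
#' promoter window -10000/+2000, target window -3000/+1000, BBLS > 1,
#' site FDR < 0.25, degenerate-motif cutoff 50000 sites, expression floor
#' FPKM 1.  A configuration round-trips losslessly through YAML.
#'
#' @param simulation NULL, or a list of \code{\link{simulation_spec}}
#'   arguments — the pipeline then generates its own inputs.
#' @param inputs NULL, or a named list of per-condition expression TSV
#'   paths (read with \code{\link{read_expression_matrix}}).
#' @param times_h,n_replicates sampling design of file inputs.
#' @param annotation_bed,sites_bed,peaks_bed interval-file paths for file
#'   inputs.
#' @param pairs list of 2-vectors of condition labels to compare
#'   pairwise; defaults to treatment-within-genotype and
#'   genotype-within-treatment pairs for 4 conditions, or all pairs
#'   otherwise.
#' @param alpha,period_min,period_max,lag_step rhythm-scan parameters.
#' @param fpkm_min,filter_rule low-expression filter.
#' @param q_alpha Dixon pruning level (tabulated 0.05 only).
#' @param enrich_window,target_window promoter windows (up, down).
#' @param min_bbls,max_site_fdr,max_sites_per_tf site-quality filter.
#' @param alpha_tf exclusivity threshold of the meta-analysis.
#' @param amp_tol amplitude-taxonomy tolerance.
#' @param bin_h phase-histogram bin width (hours).
#' @param require_peak,combine_evidence target-set construction.
#' @param focal_tf TF whose target set is built (default from the
#'   simulation, if any).
#' @param seed root seed.
#' @param out_dir output directory (NULL: nothing written).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(simulation = list(), inputs = NULL,
                            times_h = c(3, 7, 11, 15, 19, 23),
                            n_replicates = 3, annotation_bed = NULL,
                            sites_bed = NULL, peaks_bed = NULL,
                            pairs = NULL, alpha = 0.01, period_min = 20,
                            period_max = 28, lag_step = NULL,
                            fpkm_min = 1, filter_rule = "all_below",
                            q_alpha = 0.05,
                            enrich_window = c(10000, 2000),
                            target_window = c(3000, 1000), min_bbls = 1,
                            max_site_fdr = 0.25, max_sites_per_tf = 50000,
                            alpha_tf = 0.01, amp_tol = 0.05, bin_h = 2,
                            require_peak = TRUE,
                            combine_evidence = "intersection",
                            focal_tf = NULL, seed = 1L, out_dir = NULL) {
  cfg <- list(simulation = simulation, inputs = inputs,
              times_h = times_h, n_replicates = n_replicates,
              annotation_bed = annotation_bed, sites_bed = sites_bed,
              peaks_bed = peaks_bed, pairs = pairs, alpha = alpha,
              period_min = period_min, period_max = period_max,
              lag_step = lag_step, fpkm_min = fpkm_min,
              filter_rule = filter_rule, q_alpha = q_alpha,
              enrich_window = enrich_window,
              target_window = target_window, min_bbls = min_bbls,
              max_site_fdr = max_site_fdr,
              max_sites_per_tf = max_sites_per_tf, alpha_tf = alpha_tf,
              amp_tol = amp_tol, bin_h = bin_h,
              require_peak = require_peak,
              combine_evidence = combine_evidence, focal_tf = focal_tf,
              seed = as.integer(seed), out_dir = out_dir)
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    stopf("either 'simulation' or 'inputs' must be provided")
  if (cfg$alpha < 0 || cfg$alpha > 1) stopf("'alpha' must lie in [0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config a \code{\link{pipeline_config}}
#' @param path YAML file path
#' @return \code{path} invisibly (write); the configuration (read)
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, TRUE)]
  do.call(pipeline_config, raw)
}

default_pairs <- function(conds) {
  if (length(conds) == 4L) {
    list(c(conds[1L], conds[2L]), c(conds[3L], conds[4L]),
         c(conds[1L], conds[3L]), c(conds[2L], conds[4L]))
  } else {
    out <- list()
    for (i in seq_along(conds)) for (j in seq_along(conds))
      if (i < j) out[[length(out) + 1L]] <- c(conds[i], conds[j])
    out
  }
}

#' Run the full pairwise circadian-reprogramming analysis
#'
#' Stages: obtain per-condition matrices (synthetic generation or TSV
#' input), inject simulated outliers (synthetic runs only), Dixon-prune
#' replicates, apply the low-expression filter jointly across conditions,
#' scan every gene for rhythmicity, then for each configured condition
#' pair build the Venn partition, phase histograms and amplitude
#' taxonomy, and finally run the promoter TFBS enrichment per condition
#' with the cross-condition exclusivity meta-analysis and the focal TF's
#' ChIP-supported target set.  Deterministic given the config seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"pipeline_result"}: \code{report} (all
#'   summary tables), \code{rhythm} (per-condition scan data.frames),
#'   \code{manifest} (config snapshot, seed, output checksums) and, for
#'   synthetic runs, \code{truth}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  synthetic <- !is.null(config$simulation) &&
    (length(config$simulation) > 0L || is.null(config$inputs))
  truth <- NULL
  if (synthetic) {
    spec <- do.call(simulation_spec,
                    c(config$simulation,
                      if (!"seed" %in% names(config$simulation))
                        list(seed = config$seed)))
    sim <- generate_timecourse(spec)
    matrices <- sim$matrices
    truth <- sim$truth
    if (spec$outlier_rate > 0) {
      for (i in seq_along(matrices)) {
        inj <- inject_outliers(matrices[[i]], spec$outlier_rate,
                               spec$outlier_factor,
                               seed = spec$seed + 100L + i)
        matrices[[i]] <- inj$matrix
      }
    }
    ann <- generate_motif_annotation(spec, truth)
    annotation <- ann$annotation
    sites <- ann$sites
    peaks <- ann$peaks
    focal_tf <- config$focal_tf %||% spec$focal_tf
  } else {
    matrices <- lapply(names(config$inputs), function(cond) {
      read_expression_matrix(config$inputs[[cond]], cond,
                             config$times_h, config$n_replicates)
    })
    names(matrices) <- names(config$inputs)
    annotation <- if (!is.null(config$annotation_bed))
      read_tss_annotation(config$annotation_bed) else NULL
    sites <- if (!is.null(config$sites_bed))
      read_bed_intervals(config$sites_bed, "sites") else NULL
    peaks <- if (!is.null(config$peaks_bed))
      read_bed_intervals(config$peaks_bed, "peaks") else empty_peak_table()
    focal_tf <- config$focal_tf
  }
  conds <- names(matrices)
  # replicate-level outlier pruning
  prune_reports <- list()
  for (c in conds) {
    pr <- prune_outliers(matrices[[c]], alpha = config$q_alpha)
    matrices[[c]] <- pr$matrix
    prune_reports[[c]] <- pr$report
  }
  # low-expression filter, jointly across all conditions
  fl <- filter_low_expression(matrices, threshold = config$fpkm_min,
                              rule = config$filter_rule)
  matrices <- fl$matrices
  names(matrices) <- conds
  background <- fl$background
  # rhythm detection per condition
  rhythm <- lapply(matrices, jtk_cycle, period_min = config$period_min,
                   period_max = config$period_max, alpha = config$alpha,
                   lag_step = config$lag_step)
  rhythmic_sets <- lapply(rhythm, call_rhythmic, alpha = config$alpha)
  # pairwise comparison layer
  pairs <- config$pairs %||% default_pairs(conds)
  comparisons <- lapply(pairs, function(pp) {
    a <- pp[1L]; b <- pp[2L]
    part <- partition_rhythm_sets(rhythmic_sets[[a]], rhythmic_sets[[b]],
                                  a, b)
    hist_a <- if (length(part$exclusive_a))
      phase_histogram(rhythm[[a]], part$exclusive_a, config$bin_h)
    hist_b <- if (length(part$exclusive_b))
      phase_histogram(rhythm[[b]], part$exclusive_b, config$bin_h)
    hist_common <- if (length(part$common))
      phase_histogram(rhythm[[a]], part$common, config$bin_h)
    amp <- if (length(part$common))
      classify_amplitude_change(rhythm[[a]], rhythm[[b]], part$common,
                                tol = config$amp_tol)
    list(pair = pp, partition = part,
         phase_hist = list(exclusive_a = hist_a, common = hist_common,
                           exclusive_b = hist_b),
         amplitude = amp)
  })
  names(comparisons) <- vapply(pairs, paste, "", collapse = "_vs_")
  # enrichment layer
  enrich <- NULL
  meta <- NULL
  target_set <- NULL
  if (!is.null(annotation) && !is.null(sites)) {
    filt <- site_filter(config$min_bbls, config$max_site_fdr,
                        config$max_sites_per_tf)
    enrich <- lapply(conds, function(c) {
      fisher_enrichment(intersect(rhythmic_sets[[c]], background),
                        background, sites, annotation,
                        window = config$enrich_window, filter = filt)
    })
    names(enrich) <- conds
    meta <- meta_exclusive_tfs(enrich, alpha_tf = config$alpha_tf)
    if (!is.null(focal_tf)) {
      target_set <- build_target_set(
        focal_tf, sites, peaks, annotation,
        window = config$target_window, filter = filt,
        require_peak = config$require_peak,
        combine = config$combine_evidence)
    }
  }
  report <- list(
    conditions = conds,
    n_genes_analysis = length(fl$analysis_genes),
    n_background = length(background),
    n_rhythmic = vapply(rhythmic_sets, length, 0L),
    n_pruned_replicates = vapply(prune_reports, nrow, 0L),
    comparisons = comparisons, enrichment = enrich, meta = meta,
    focal_tf = focal_tf, target_set = target_set)
  manifest <- list(config = unclass(config), seed = config$seed,
                   version = as.character(utils::packageVersion("diurnal")),
                   checksums = NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (c in conds) {
      p <- file.path(config$out_dir, paste0("rhythm_", c, ".tsv"))
      utils::write.table(rhythm[[c]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
    rp <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report_to_json(report), rp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    paths <- c(paths, rp)
    manifest$checksums <- as.list(tools::md5sum(paths))
    names(manifest$checksums) <- basename(paths)
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  structure(list(report = report, rhythm = rhythm, manifest = manifest,
                 truth = truth, background = background,
                 rhythmic_sets = rhythmic_sets),
            class = "pipeline_result")
}

# flatten S3 bits into plain lists for JSON serialization
report_to_json <- function(report) {
  report$comparisons <- lapply(report$comparisons, function(cmp) {
    list(pair = cmp$pair,
         partition = list(counts = as.list(cmp$partition$counts),
                          percent = as.list(cmp$partition$percent),
                          fraction = as.list(cmp$partition$fraction),
                          total = cmp$partition$total),
         phase_hist = lapply(cmp$phase_hist, function(h)
           if (is.null(h)) NULL else as.list(h)),
         amplitude = if (is.null(cmp$amplitude)) NULL else
           list(counts = as.list(cmp$amplitude$counts),
                percent = as.list(cmp$amplitude$percent)))
  })
  report$enrichment <- lapply(report$enrichment, function(e)
    e[!is.na(e$p_one_sided), c("tf_name", "k", "odds_ratio",
                               "p_one_sided", "neg_log10_p")])
  report
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  conditions: %s\n",
              paste(x$report$conditions, collapse = ", ")))
  cat(sprintf("  rhythmic genes: %s\n",
              paste(sprintf("%s=%d", names(x$report$n_rhythmic),
                            x$report$n_rhythmic), collapse = ", ")))
  if (!is.null(x$report$meta)) {
    excl <- x$report$meta[x$report$meta$exclusive %in%
                            x$report$conditions, , drop = FALSE]
    cat(sprintf("  condition-exclusive TFs: %s\n",
                if (nrow(excl)) paste(sprintf("%s (%s)", excl$tf_name,
                                              excl$exclusive),
                                      collapse = ", ") else "none"))
  }
  invisible(x)
}
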