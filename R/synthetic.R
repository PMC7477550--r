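#' Specification of a synthetic circadian study
#'
#' Describes a multi-condition circadian expression experiment with known
#' ground truth, emulating a 2-genotype x 2-treatment design sampled every
#' 4 h over one cycle with 3 replicates.  Genes fall into four classes:
#' \describe{
#'   \item{exclusive_a}{oscillate only in the baseline condition (rhythm
#'     lost under treatment);}
#'   \item{common}{oscillate in every condition (core clock-like);}
#'   \item{de_novo}{oscillate only in the treatment condition, with phases
#'     clustered at ZT7 (circular-normal jitter, sd 1.5 h by default);}
#'   \item{flat}{the remainder, no planted rhythm.}
#' }
#' The expression model is multiplicative:
#' \code{mu_g * (1 + a * cos(2*pi*(t - phi)/P)) * exp(eps)} with
#' \code{eps ~ N(0, noise_sd^2)}, keeping FPKM-like values positive with
#' noise that scales with the mean.  A focal TF is planted whose motif
#' sites concentrate in de-novo-gene promoters (probability \code{p_in}
#' per de-novo gene vs \code{p_out} elsewhere).
#'
#' @param n_genes number of genes (default 2000).
#' @param conditions condition labels; the first is the baseline, and
#'   \code{de_novo_condition} names the treated condition gaining the
#'   de-novo oscillators.
#' @param times_h,n_replicates sampling design (default ZT 3,7,...,23 x 3).
#' @param frac_exclusive_a,frac_common,frac_de_novo class fractions.
#' @param phase_de_novo,phase_jitter_sd de-novo phase cluster (ZT h).
#' @param amplitude_range relative-amplitude range, within (0, 1].
#' @param period_h planted period (default 24; the 4-h 6-point design
#'   cannot resolve finer structure).
#' @param baseline_log_mean,baseline_log_sd lognormal parameters of the
#'   gene baselines \code{mu_g}.
#' @param noise_sd multiplicative lognormal noise sd (log scale).
#' @param outlier_rate,outlier_factor single-replicate outlier process
#'   (see \code{\link{inject_outliers}}).
#' @param focal_tf,p_in,p_out,n_decoy_tfs,decoy_sites_per_tf motif-layer
#'   parameters.
#' @param seed root seed; all randomness is derived from it.
#' @return a validated list of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(n_genes = 2000,
                            conditions = c("WT_saline", "WT_cocaine",
                                           "KO_saline", "KO_cocaine"),
                            times_h = c(3, 7, 11, 15, 19, 23),
                            n_replicates = 3,
                            frac_exclusive_a = 0.10,
                            frac_common = 0.05,
                            frac_de_novo = 0.10,
                            de_novo_condition = conditions[2L],
                            phase_de_novo = 7,
                            phase_jitter_sd = 1.5,
                            amplitude_range = c(0.3, 0.8),
                            period_h = 24,
                            baseline_log_mean = log(10),
                            baseline_log_sd = 1,
                            noise_sd = 0.1,
                            outlier_rate = 0.02,
                            outlier_factor = 8,
                            focal_tf = "PPARG",
                            p_in = 0.5,
                            p_out = 0.05,
                            n_decoy_tfs = 20,
                            decoy_sites_per_tf = 2000,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), conditions = conditions,
               times_h = times_h, n_replicates = as.integer(n_replicates),
               frac_exclusive_a = frac_exclusive_a,
               frac_common = frac_common, frac_de_novo = frac_de_novo,
               de_novo_condition = de_novo_condition,
               phase_de_novo = phase_de_novo,
               phase_jitter_sd = phase_jitter_sd,
               amplitude_range = amplitude_range, period_h = period_h,
               baseline_log_mean = baseline_log_mean,
               baseline_log_sd = baseline_log_sd, noise_sd = noise_sd,
               outlier_rate = outlier_rate, outlier_factor = outlier_factor,
               focal_tf = focal_tf, p_in = p_in, p_out = p_out,
               n_decoy_tfs = as.integer(n_decoy_tfs),
               decoy_sites_per_tf = as.integer(decoy_sites_per_tf),
               seed = as.integer(seed))
  fr <- c(frac_exclusive_a, frac_common, frac_de_novo)
  if (any(fr < 0) || sum(fr) > 1)
    stopf("class fractions must be nonnegative and sum to <= 1")
  if (any(c(p_in, p_out, outlier_rate) < 0) ||
      any(c(p_in, p_out, outlier_rate) > 1))
    stopf("probabilities must lie in [0, 1]")
  if (amplitude_range[1L] <= 0 || amplitude_range[2L] > 1)
    stopf(paste0("relative amplitudes must lie in (0, 1] so the ",
                 "oscillation factor stays nonnegative"))
  if (any(times_h < 0) || any(times_h >= 24))
    stopf("'times_h' must lie in [0, 24)")
  if (!de_novo_condition %in% conditions)
    stopf("'de_novo_condition' must be one of 'conditions'")
  if (noise_sd < 0 || outlier_factor <= 0)
    stopf("'noise_sd' must be >= 0 and 'outlier_factor' > 0")
  class(spec) <- "simulation_spec"
  spec
}

#' Generate synthetic multi-condition expression time courses
#'
#' Draws gene baselines, class memberships, phases and amplitudes once,
#' then builds one \code{\link{timecourse_matrix}} per condition from the
#' multiplicative cosine model.  All randomness flows from
#' \code{spec$seed}, so identical specs reproduce identical output.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{matrices} (named list of
#'   \code{timecourse_matrix}, one per condition) and \code{truth}, a
#'   ground-truth list: \code{class} (per gene), \code{oscillates},
#'   \code{phase}, \code{amplitude} (gene x condition), \code{mu},
#'   \code{period_h} and \code{is_focal_target}.
#' @export
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(n))
  n_ex <- round(n * spec$frac_exclusive_a)
  n_co <- round(n * spec$frac_common)
  n_dn <- round(n * spec$frac_de_novo)
  cls <- rep("flat", n)
  cls[seq_len(n_ex)] <- "exclusive_a"
  if (n_co) cls[n_ex + seq_len(n_co)] <- "common"
  if (n_dn) cls[n_ex + n_co + seq_len(n_dn)] <- "de_novo"
  mu <- stats::rlnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)
  phase <- stats::runif(n, 0, 24)
  phase[cls == "de_novo"] <- (spec$phase_de_novo +
    stats::rnorm(sum(cls == "de_novo"), 0, spec$phase_jitter_sd)) %% 24
  amp <- stats::runif(n, spec$amplitude_range[1L], spec$amplitude_range[2L])
  conds <- spec$conditions
  osc <- matrix(FALSE, n, length(conds),
                dimnames = list(gene_ids, conds))
  osc[cls == "common", ] <- TRUE
  osc[cls == "exclusive_a", conds[1L]] <- TRUE
  osc[cls == "de_novo", spec$de_novo_condition] <- TRUE
  phase_m <- matrix(NA_real_, n, length(conds),
                    dimnames = list(gene_ids, conds))
  amp_m <- matrix(0, n, length(conds), dimnames = list(gene_ids, conds))
  for (c in conds) {
    phase_m[osc[, c], c] <- phase[osc[, c]]
    amp_m[osc[, c], c] <- amp[osc[, c]]
  }
  is_target <- stats::runif(n) <
    ifelse(cls == "de_novo", spec$p_in, spec$p_out)
  t_all <- rep(spec$times_h, rep(spec$n_replicates, length(spec$times_h)))
  matrices <- list()
  for (c in conds) {
    det <- outer(seq_len(n), seq_along(t_all), function(g, s) {
      mu[g] * (1 + amp_m[g, c] *
                 ifelse(osc[g, c],
                        cos(2 * pi * (t_all[s] - phase_m[g, c]) /
                              spec$period_h), 0))
    })
    det[!osc[, c], ] <- mu[!osc[, c]]  # guard NA phases for flat genes
    noise <- if (spec$noise_sd > 0)
      exp(matrix(stats::rnorm(n * length(t_all), 0, spec$noise_sd),
                 n, length(t_all))) else 1
    vals <- det * noise
    rownames(vals) <- gene_ids
    matrices[[c]] <- timecourse_matrix(
      vals, times_h = spec$times_h, n_replicates = spec$n_replicates,
      condition = c, gene_ids = gene_ids)
  }
  truth <- list(class = stats::setNames(cls, gene_ids), oscillates = osc,
                phase = phase_m, amplitude = amp_m,
                mu = stats::setNames(mu, gene_ids),
                period_h = spec$period_h,
                is_focal_target = stats::setNames(is_target, gene_ids))
  list(matrices = matrices, truth = truth)
}

#' Inject single-replicate outliers
#'
#' For each gene x timepoint independently with probability \code{q},
#' exactly one replicate (chosen uniformly among non-missing ones) is
#' multiplied by \code{factor}.  Emulates the occasional aberrant
#' replicate that Dixon pruning is meant to remove.
#'
#' @param tc a \code{\link{timecourse_matrix}}.
#' @param q per-(gene, timepoint) injection probability.
#' @param factor multiplicative distortion (> 0).
#' @param seed RNG seed for the injection pattern.
#' @return list with \code{matrix} (distorted copy) and \code{log}, a
#'   data.frame of injected positions (\code{gene_id}, \code{timepoint},
#'   \code{replicate}, \code{column}).
#' @export
inject_outliers <- function(tc, q, factor, seed = 1L) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  if (q < 0 || q > 1) stopf("'q' must lie in [0, 1]")
  if (factor <= 0) stopf("'factor' must be > 0")
  set.seed(seed)
  tp_idx <- tc_timepoint_index(tc)
  out <- tc
  rows <- list()
  for (g in seq_len(nrow(tc$values))) {
    for (tp in seq_along(tc$times_h)) {
      if (stats::runif(1) >= q) next
      cols <- which(tp_idx == tp & !tc$missing_mask[g, ])
      if (!length(cols)) next
      col <- cols[sample.int(length(cols), 1L)]
      out$values[g, col] <- out$values[g, col] * factor
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tc$gene_ids[g], timepoint = tp,
        replicate = match(col, which(tp_idx == tp)), column = col,
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), timepoint = integer(),
               replicate = integer(), column = integer(),
               stringsAsFactors = FALSE)
  list(matrix = out, log = log)
}

#' Generate a matched synthetic motif/peak annotation
#'
#' Each gene owns a non-overlapping 20-kb territory on one synthetic
#' chromosome with its TSS at the territory centre and a random strand.
#' Every ground-truth focal-target gene receives one focal-TF site placed
#' uniformly inside its strand-aware -3000/+1000 promoter window; decoy
#' TFs receive sites uniformly along the chromosome.  BBLS scores are
#' Exponential(mean 2) and site FDRs Uniform(0, 0.5), so roughly 30% of
#' sites survive the default BBLS > 1, FDR < 0.25 quality filter.  ChIP
#' peaks cover focal-TF sites of true targets with probability 0.9.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param truth ground truth from \code{\link{generate_timecourse}}.
#' @param seed RNG seed (defaults to \code{spec$seed + 1}).
#' @return list with \code{annotation} (gene_id/chrom/tss/strand),
#'   \code{sites} (a site table) and \code{peaks} (a peak table).
#' @export
generate_motif_annotation <- function(spec, truth,
                                      seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  n <- spec$n_genes
  gene_ids <- names(truth$is_focal_target)
  territory <- 20000L
  tss <- as.integer((seq_len(n) - 1L) * territory + territory / 2L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  annotation <- data.frame(gene_id = gene_ids, chrom = "chrS", tss = tss,
                           strand = strand, stringsAsFactors = FALSE)
  site_len <- 10L
  rows <- list()
  targets <- which(truth$is_focal_target)
  for (g in targets) {
    lo <- if (strand[g] == "+") tss[g] - 3000L else tss[g] - 1000L
    hi <- if (strand[g] == "+") tss[g] + 1000L else tss[g] + 3000L
    start <- lo + sample.int(hi - lo - site_len, 1L) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      tf_name = spec$focal_tf, chrom = "chrS", start = start,
      end = start + site_len, stringsAsFactors = FALSE)
  }
  chrom_len <- n * territory
  if (spec$n_decoy_tfs > 0) {
    for (d in seq_len(spec$n_decoy_tfs)) {
      starts <- sort(sample.int(chrom_len - site_len,
                                spec$decoy_sites_per_tf))
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = sprintf("DECOY_%02d", d), chrom = "chrS",
        start = starts - 1L, end = starts - 1L + site_len,
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rows) %||% empty_site_table()
  sites$bbls <- stats::rexp(nrow(sites), rate = 0.5)
  sites$site_fdr <- stats::runif(nrow(sites), 0, 0.5)
  sites <- sites[, c("tf_name", "chrom", "start", "end", "bbls",
                     "site_fdr")]
  class(sites) <- c("site_table", "data.frame")
  focal <- sites$tf_name == spec$focal_tf
  covered <- which(focal)[stats::runif(sum(focal)) < 0.9]
  peaks <- if (length(covered)) {
    data.frame(chrom = "chrS",
               start = pmax(0L, sites$start[covered] - 200L),
               end = sites$end[covered] + 200L, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }
  class(peaks) <- c("peak_table", "data.frame")
  list(annotation = annotation, sites = sites, peaks = peaks)
}
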