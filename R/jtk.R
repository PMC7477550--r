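#' Period/lag scan grid for the rhythm test
#'
#' Candidate periods are integer multiples of the sampling interval inside
#' the period window (default 20-28 h, the conventional circadian window);
#' candidate lags are multiples of the lag step in \code{[0, P)}.  For the
#' default 4-h, 6-timepoint design this yields periods {20, 24, 28} with
#' {5, 6, 7} lags, i.e. 18 period/lag combinations.
#'
#' @param times_h equally spaced sampling times (ZT hours).
#' @param period_min,period_max period window bounds in hours.
#' @param lag_step lag resolution in hours; defaults to the sampling
#'   interval.  Some rhythm-detection builds scan half-interval lags;
#'   pass \code{interval/2} to match them.
#' @return data.frame with columns \code{period_h}, \code{lag_h}, ordered
#'   by period then lag.
#' @export
jtk_grid <- function(times_h, period_min = 20, period_max = 28,
                     lag_step = NULL) {
  if (length(times_h) < 3L) stopf("need at least 3 timepoints")
  dt <- diff(times_h)
  if (max(dt) - min(dt) > 1e-9)
    stopf("sampling grid must be equally spaced")
  delta <- dt[1L]
  lag_step <- lag_step %||% delta
  periods <- seq(ceiling(period_min / delta) * delta,
                 floor(period_max / delta) * delta, by = delta)
  periods <- periods[periods >= period_min & periods <= period_max]
  if (!length(periods))
    stopf("no multiple of the %g-h sampling interval lies in [%g, %g]",
          delta, period_min, period_max)
  grid <- do.call(rbind, lapply(periods, function(p) {
    data.frame(period_h = p, lag_h = seq(0, p - lag_step, by = lag_step))
  }))
  attr(grid, "interval_h") <- delta
  grid
}

#' Reference cosine pattern for one period/lag combination
#'
#' \code{ref(t) = cos(2*pi*(t - t0 - lag)/period)} evaluated at each
#' sample's timepoint and repeated per replicate, so replicates at one
#' timepoint are exact ties in the reference.  \code{t0} is the first
#' sampling time; the pattern peaks at \code{t0 + lag}.
#'
#' @param period_h,lag_h grid combination (hours).
#' @param times_h sampling times.
#' @param n_replicates per-timepoint replicate counts (or one count).
#' @return numeric vector of reference values, one per sample column.
#' @export
reference_pattern <- function(period_h, lag_h, times_h, n_replicates) {
  if (length(n_replicates) == 1L)
    n_replicates <- rep(n_replicates, length(times_h))
  vals <- cos(2 * pi * (times_h - times_h[1L] - lag_h) / period_h)
  # round so symmetric cosine values tie exactly across timepoints
  rep(round(vals, 9), n_replicates)
}

pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

tie_pattern <- function(x) {
  as.integer(table(match(x, sort(unique(x)))))
}

#' Kendall S statistic against a reference pattern
#'
#' \code{S} sums \code{sign(x_i - x_j) * sign(ref_i - ref_j)} over all
#' sample pairs; pairs tied in either vector contribute zero.  The tie
#' patterns (multisets of tie-group sizes, in ascending value order) of
#' both vectors are returned because the exact null distribution of S is
#' conditional on them.  \code{tau = S / max|S|} where the maximum is
#' taken over arrangements with the same tie patterns.
#'
#' @param x numeric data vector.
#' @param ref reference pattern of the same length.
#' @param missing_mask optional logical vector; \code{TRUE} entries are
#'   dropped from both vectors before scoring.
#' @return list with \code{S}, \code{tie_pattern_x}, \code{tie_pattern_ref},
#'   \code{tau}, \code{n}.
#' @export
kendall_s <- function(x, ref, missing_mask = NULL) {
  if (length(x) != length(ref))
    stopf("'x' and 'ref' must have equal length")
  keep <- !(missing_mask %||% rep(FALSE, length(x))) & !is.na(x)
  x <- x[keep]; ref <- ref[keep]
  n <- length(x)
  if (n < 2L) stopf("fewer than 2 usable values")
  pr <- pair_index(n)
  s_terms <- sign(x[pr[, 1L]] - x[pr[, 2L]]) *
    sign(ref[pr[, 1L]] - ref[pr[, 2L]])
  S <- sum(s_terms)
  tx <- tie_pattern(x)
  tr <- tie_pattern(ref)
  smax <- max_kendall_s(tx, tr)
  list(S = S, tie_pattern_x = tx, tie_pattern_ref = tr,
       tau = if (smax > 0) S / smax else 0, n = n)
}

# Maximum attainable S given both tie patterns: align the sorted data
# multiset with the sorted reference multiset (rearrangement argument).
max_kendall_s <- function(tie_x, tie_ref) {
  x <- rep(seq_along(tie_x), tie_x)
  r <- rep(seq_along(tie_ref), tie_ref)
  n <- length(x)
  if (n != length(r)) stopf("inconsistent tie patterns")
  if (n < 2L) return(0L)
  pr <- pair_index(n)
  sum(sign(x[pr[, 1L]] - x[pr[, 2L]]) * sign(r[pr[, 1L]] - r[pr[, 2L]]))
}

## ---- exact conditional null distribution -------------------------------

# polynomial helpers: numeric coefficient vectors, coef[k+1] = q^k term
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(b)) {
    if (b[k] != 0)
      out[k:(k + length(a) - 1L)] <- out[k:(k + length(a) - 1L)] + a * b[k]
  }
  out
}

poly_times_one_minus_qk <- function(a, k) {
  out <- c(a, numeric(k)) - c(numeric(k), a)
  out
}

poly_div_one_minus_qk <- function(a, k) {
  # exact synthetic division by (1 - q^k); remainder must vanish
  out <- a
  for (i in seq_along(out)) {
    if (i + k <= length(out)) out[i + k] <- out[i + k] + out[i]
  }
  # trailing k coefficients are the remainder, all ~0 for exact division
  out[seq_len(max(0L, length(out) - k))]
}

# Gaussian binomial [m + c choose c]_q: generating function of the number
# of inversions added when a block of c tied-in-reference items is merged
# into m earlier items (Mann-Whitney null distribution).
gaussian_binomial <- function(m, c) {
  if (m == 0L || c == 0L) return(1)
  g <- 1
  for (j in seq_len(c)) g <- poly_times_one_minus_qk(g, m + j)
  for (j in seq_len(c)) g <- poly_div_one_minus_qk(g, j)
  g
}

# Null distribution of S when data values are all distinct: the inversion
# count across reference tie groups is a convolution of Mann-Whitney
# distributions (Harding's product of Gaussian binomials); S = T - 2u
# with T the number of reference-untied pairs.
null_dist_distinct <- function(ref_groups) {
  n <- sum(ref_groups)
  T_pairs <- (n * n - sum(ref_groups^2)) %/% 2L
  poly <- 1
  m <- 0L
  for (ck in ref_groups) {
    poly <- poly_mult(poly, gaussian_binomial(m, ck))
    m <- m + ck
  }
  S <- T_pairs - 2 * (seq_along(poly) - 1L)
  list(S = rev(S), prob = rev(poly) / sum(poly))
}

compositions_capped <- function(total, caps) {
  # all nonnegative integer vectors k with sum(k) = total and k <= caps
  H <- length(caps)
  rec <- function(h, left) {
    if (h == H) {
      if (left <= caps[h]) return(matrix(left, 1L, 1L)) else
        return(matrix(0L, 0L, 1L))
    }
    out <- list()
    for (k in 0:min(caps[h], left)) {
      sub <- rec(h + 1L, left - k)
      if (nrow(sub)) out[[length(out) + 1L]] <- cbind(k, sub)
    }
    if (!length(out)) matrix(0L, 0L, H - h + 1L) else do.call(rbind, out)
  }
  rec(1L, total)
}

# General exact null with ties in both vectors: dynamic program over
# reference tie groups (ascending), state = multiset of data values
# consumed so far, tracking the polynomial of S over arrangements.
null_dist_general <- function(x_groups, ref_groups) {
  n <- sum(x_groups)
  if (n != sum(ref_groups)) stopf("inconsistent tie patterns")
  H <- length(x_groups)
  T_pairs <- (n * n - sum(ref_groups^2)) %/% 2L
  off <- T_pairs + 1L  # S in [-T, T] -> index S + off
  width <- 2L * T_pairs + 1L
  states <- new.env(parent = emptyenv())
  key0 <- paste(integer(H), collapse = ",")
  d0 <- numeric(width); d0[off] <- 1
  assign(key0, list(cons = integer(H), dist = d0), envir = states)
  lfac <- lgamma(seq_len(max(2L, n) + 1L))  # lfac[k+1] = log(k!)
  for (cg in ref_groups) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(states)) {
      st <- get(key, envir = states)
      caps <- x_groups - st$cons
      comps <- compositions_capped(cg, caps)
      for (r in seq_len(nrow(comps))) {
        k <- as.integer(comps[r, ])
        ways <- exp(lfac[cg + 1L] - sum(lfac[k + 1L]))
        # concordances/discordances between earlier placements and this group
        below <- cumsum(st$cons) - st$cons       # sum cons[a], a < b
        above <- sum(st$cons) - cumsum(st$cons)  # sum cons[a], a > b
        delta <- sum(k * (below - above))
        cons2 <- st$cons + k
        key2 <- paste(cons2, collapse = ",")
        shifted <- numeric(width)
        src <- which(st$dist != 0)
        shifted[src + delta] <- st$dist[src] * ways
        if (exists(key2, envir = nxt, inherits = FALSE)) {
          prev <- get(key2, envir = nxt)
          prev$dist <- prev$dist + shifted
          assign(key2, prev, envir = nxt)
        } else {
          assign(key2, list(cons = cons2, dist = shifted), envir = nxt)
        }
      }
    }
    states <- nxt
  }
  final <- get(paste(x_groups, collapse = ","), envir = states)
  prob <- final$dist / sum(final$dist)
  keep <- which(prob > 0)
  list(S = keep - off, prob = prob[keep])
}

#' Exact conditional null distribution of the tied Kendall S
#'
#' Distribution of \code{S} under uniform random pairing of the data
#' multiset against the reference multiset, conditional on both tie
#' patterns.  When one side is tie-free the distribution is computed as a
#' Harding-style convolution of Mann-Whitney distributions (a product of
#' Gaussian binomials); when both sides carry ties an exact dynamic
#' program over reference tie groups is used.
#'
#' @param tie_pattern_x,tie_pattern_ref integer vectors of tie-group sizes
#'   (same total).
#' @return list with integer support \code{S} and \code{prob} summing to 1.
#' @export
kendall_null_distribution <- function(tie_pattern_x, tie_pattern_ref) {
  tie_pattern_x <- as.integer(tie_pattern_x)
  tie_pattern_ref <- as.integer(tie_pattern_ref)
  if (sum(tie_pattern_x) != sum(tie_pattern_ref))
    stopf("tie patterns describe different lengths (%d vs %d)",
          sum(tie_pattern_x), sum(tie_pattern_ref))
  if (all(tie_pattern_x == 1L)) return(null_dist_distinct(tie_pattern_ref))
  if (all(tie_pattern_ref == 1L)) return(null_dist_distinct(tie_pattern_x))
  null_dist_general(tie_pattern_x, tie_pattern_ref)
}

#' Exact two-sided p-value for the tied Kendall S
#'
#' \code{P(|S| >= |S_obs|)} under the exact conditional null of
#' \code{\link{kendall_null_distribution}}.  Always in \code{(0, 1]};
#' \code{S_obs = 0} gives exactly 1.
#'
#' @param S_obs observed statistic.
#' @param tie_pattern_x,tie_pattern_ref tie-group size vectors.
#' @return p-value.
#' @export
exact_null_pvalue <- function(S_obs, tie_pattern_x, tie_pattern_ref) {
  d <- kendall_null_distribution(tie_pattern_x, tie_pattern_ref)
  sum(d$prob[abs(d$S) >= abs(S_obs)])
}

## ---- per-gene scan ------------------------------------------------------

cosinor_amplitude <- function(x, t, period_h, phase_zt) {
  cc <- cos(2 * pi * (t - phase_zt) / period_h)
  cx <- cc - mean(cc)
  den <- sum(cx^2)
  if (den < 1e-12) return(0)
  abs(sum(cx * (x - mean(x))) / den)
}

jtk_empty_result <- function(gene_id) {
  data.frame(gene_id = gene_id, p_raw_min = 1, p_adj = 1,
             period_h = NA_real_, lag_h = NA_real_, phase_zt = NA_real_,
             tau = 0, amplitude = 0, stringsAsFactors = FALSE)
}

#' Scan one expression series over the period/lag grid
#'
#' For every period/lag combination the series is scored against the
#' reference cosine ranks with the tied Kendall S, the exact conditional
#' two-sided p-value is computed, and the minimum p over the grid is
#' Bonferroni-adjusted by the number of combinations (capped at 1).  The
#' reported combination is the argmin of p, ties broken by smaller period
#' then smaller lag.  Phase is the reference peak time,
#' \code{(t0 + lag) mod 24} ZT hours; amplitude is the absolute cosine
#' coefficient of an ordinary least-squares cosinor fit at the selected
#' period and phase.
#'
#' @param series numeric vector, one value per sample column.
#' @param times_h,n_replicates the sampling design.
#' @param grid scan grid from \code{\link{jtk_grid}} (built for the same
#'   time base); defaults to the 20-28 h window.
#' @param missing_mask optional logical vector marking pruned samples.
#' @param bonferroni multiple-testing factor; defaults to the number of
#'   grid combinations.
#' @param gene_id id used in the returned row.
#' @return one-row data.frame with columns \code{gene_id, p_raw_min,
#'   p_adj, period_h, lag_h, phase_zt, tau, amplitude}.  A constant or
#'   all-missing series yields \code{p_adj = 1, tau = 0, amplitude = 0}.
#' @export
jtk_scan <- function(series, times_h, n_replicates, grid = NULL,
                     missing_mask = NULL, bonferroni = NULL,
                     gene_id = "gene") {
  if (length(n_replicates) == 1L)
    n_replicates <- rep(as.integer(n_replicates), length(times_h))
  grid <- grid %||% jtk_grid(times_h)
  keep <- !(missing_mask %||% rep(FALSE, length(series))) & !is.na(series)
  x <- series[keep]
  if (length(x) < 2L || length(unique(x)) == 1L)
    return(jtk_empty_result(gene_id))
  t_all <- rep(times_h, n_replicates)
  tvec <- t_all[keep]
  n_combos <- nrow(grid)
  bonf <- bonferroni %||% n_combos
  pvals <- numeric(n_combos)
  stats <- vector("list", n_combos)
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(n_combos)) {
    ref <- cos(2 * pi * (tvec - times_h[1L] - grid$lag_h[k]) /
                 grid$period_h[k])
    ref <- round(ref, 9)
    ks <- kendall_s(x, ref)
    key <- paste(paste(ks$tie_pattern_x, collapse = "."),
                 paste(ks$tie_pattern_ref, collapse = "."), sep = "|")
    d <- if (exists(key, envir = cache, inherits = FALSE)) {
      get(key, envir = cache)
    } else {
      dd <- kendall_null_distribution(ks$tie_pattern_x, ks$tie_pattern_ref)
      assign(key, dd, envir = cache)
      dd
    }
    pvals[k] <- sum(d$prob[abs(d$S) >= abs(ks$S)])
    stats[[k]] <- ks
  }
  best <- which(pvals == min(pvals))[1L]  # grid ordered by period then lag
  P <- grid$period_h[best]
  lag <- grid$lag_h[best]
  tau <- stats[[best]]$tau
  if (stats[[best]]$S < 0) {
    # an anticorrelated pattern is the cosine at lag L + P/2; re-anchor
    # there so phase and tau describe the positive match
    lag <- (lag + P / 2) %% P
    tau <- -tau
  }
  phase <- (times_h[1L] + lag) %% 24
  amp <- cosinor_amplitude(x, tvec, P, phase)
  data.frame(gene_id = gene_id, p_raw_min = pvals[best],
             p_adj = min(1, bonf * pvals[best]),
             period_h = P, lag_h = lag,
             phase_zt = phase, tau = tau, amplitude = amp,
             stringsAsFactors = FALSE)
}

#' Rhythm detection over a whole time-course matrix
#'
#' Applies \code{\link{jtk_scan}} to every gene of a
#' \code{\link{timecourse_matrix}}, sharing exact-null distributions
#' across genes with identical tie structure.
#'
#' @param tc a \code{timecourse_matrix}.
#' @param period_min,period_max period window in hours (default 20-28).
#' @param alpha rhythmicity cutoff on the adjusted p-value (strict
#'   inequality; default 0.01).
#' @param lag_step optional lag resolution (hours).
#' @param bonferroni optional override of the Bonferroni factor.
#' @return data.frame with one row per gene (columns of
#'   \code{\link{jtk_scan}} plus logical \code{rhythmic}).
#' @export
jtk_cycle <- function(tc, period_min = 20, period_max = 28, alpha = 0.01,
                      lag_step = NULL, bonferroni = NULL) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  grid <- jtk_grid(tc$times_h, period_min, period_max, lag_step)
  n_combos <- nrow(grid)
  bonf <- bonferroni %||% n_combos
  times_h <- tc$times_h
  t_all <- rep(times_h, tc$n_replicates)
  n_samp <- length(t_all)
  null_cache <- new.env(parent = emptyenv())
  ref_cache <- new.env(parent = emptyenv())
  # per mask pattern: pair signs of each reference combo
  get_ref <- function(keep) {
    key <- paste(which(keep), collapse = ",")
    if (exists(key, envir = ref_cache, inherits = FALSE))
      return(get(key, envir = ref_cache))
    tvec <- t_all[keep]
    n <- length(tvec)
    pr <- pair_index(n)
    refsign <- matrix(0, nrow(pr), n_combos)
    refties <- vector("list", n_combos)
    for (k in seq_len(n_combos)) {
      ref <- round(cos(2 * pi * (tvec - times_h[1L] - grid$lag_h[k]) /
                         grid$period_h[k]), 9)
      refsign[, k] <- sign(ref[pr[, 1L]] - ref[pr[, 2L]])
      refties[[k]] <- tie_pattern(ref)
    }
    val <- list(pr = pr, refsign = refsign, refties = refties, tvec = tvec)
    assign(key, val, envir = ref_cache)
    val
  }
  get_null <- function(tx, tr) {
    key <- paste(paste(tx, collapse = "."), paste(tr, collapse = "."),
                 sep = "|")
    if (exists(key, envir = null_cache, inherits = FALSE))
      return(get(key, envir = null_cache))
    d <- kendall_null_distribution(tx, tr)
    assign(key, d, envir = null_cache)
    d
  }
  rows <- vector("list", nrow(tc$values))
  for (g in seq_len(nrow(tc$values))) {
    keep <- !tc$missing_mask[g, ]
    x <- tc$values[g, keep]
    if (length(x) < 2L || length(unique(x)) == 1L) {
      rows[[g]] <- jtk_empty_result(tc$gene_ids[g])
      next
    }
    rc <- get_ref(keep)
    sx <- sign(x[rc$pr[, 1L]] - x[rc$pr[, 2L]])
    S_all <- as.numeric(crossprod(sx, rc$refsign))
    tx <- tie_pattern(x)
    pvals <- vapply(seq_len(n_combos), function(k) {
      d <- get_null(tx, rc$refties[[k]])
      sum(d$prob[abs(d$S) >= abs(S_all[k])])
    }, 0)
    best <- which(pvals == min(pvals))[1L]
    smax <- max_kendall_s(tx, rc$refties[[best]])
    P <- grid$period_h[best]
    lag <- grid$lag_h[best]
    tau <- if (smax > 0) S_all[best] / smax else 0
    if (S_all[best] < 0) {  # anticorrelated match = cosine at lag + P/2
      lag <- (lag + P / 2) %% P
      tau <- -tau
    }
    phase <- (times_h[1L] + lag) %% 24
    amp <- cosinor_amplitude(x, rc$tvec, P, phase)
    rows[[g]] <- data.frame(
      gene_id = tc$gene_ids[g], p_raw_min = pvals[best],
      p_adj = min(1, bonf * pvals[best]), period_h = P,
      lag_h = lag, phase_zt = phase, tau = tau, amplitude = amp,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$rhythmic <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Genes called rhythmic at a cutoff
#'
#' Strict comparison: a gene is rhythmic iff its adjusted p-value is
#' strictly below \code{alpha}.
#'
#' @param results data.frame from \code{\link{jtk_cycle}}.
#' @param alpha cutoff (default 0.01).
#' @return character vector of gene ids.
#' @export
call_rhythmic <- function(results, alpha = 0.01) {
  if (!nrow(results)) return(character())
  results$gene_id[results$p_adj < alpha]
}
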