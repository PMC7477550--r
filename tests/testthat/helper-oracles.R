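# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: permutation enumeration for the tied
# Kendall null, an explicit choose()-sum for hypergeometric tails.

# all permutations of seq_len(n), one row each; cached per n
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
  }
  .perm_cache[[key]] <- P
  P
}

# exact distribution of S by enumerating all n! pairings of the x
# multiset against the reference multiset
brute_kendall_null <- function(tie_x, tie_ref) {
  xv <- rep(seq_along(tie_x), tie_x)
  rv <- rep(seq_along(tie_ref), tie_ref)
  n <- length(xv)
  stopifnot(n == length(rv), n <= 8L)
  P <- all_perms(n)
  X <- matrix(xv[P], nrow(P), n)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  S <- numeric(nrow(P))
  for (k in seq_along(i)) {
    S <- S + sign(X[, i[k]] - X[, j[k]]) * sign(rv[i[k]] - rv[j[k]])
  }
  tab <- table(S)
  list(S = as.integer(names(tab)), prob = as.numeric(tab) / nrow(P))
}

brute_kendall_pvalue <- function(S_obs, tie_x, tie_ref) {
  d <- brute_kendall_null(tie_x, tie_ref)
  sum(d$prob[abs(d$S) >= abs(S_obs)])
}

# random tie pattern of total n: composition drawn by random cut points
random_tie_pattern <- function(n) {
  if (n == 1L) return(1L)
  cuts <- sort(sample(seq_len(n - 1L), sample.int(n - 1L, 1L)))
  diff(c(0L, cuts, n))
}

# one-sided hypergeometric tail P(X >= k) by explicit summation
hyper_tail_oracle <- function(k, n_with, n_without, n_draw) {
  i <- k:min(n_draw, n_with)
  if (!length(i) || k > min(n_draw, n_with)) return(0)
  sum(exp(lchoose(n_with, i) + lchoose(n_without, n_draw - i) -
            lchoose(n_with + n_without, n_draw)))
}

# small time-course matrix with given per-row values
make_tc <- function(values, times_h = c(3, 7, 11, 15, 19, 23),
                    n_replicates = 3, condition = "test") {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  timecourse_matrix(values, times_h, n_replicates, condition)
}

# noise-free (or noisy) cosine series over the default design
cosine_series <- function(mu = 10, a = 0.5, phase = 7, period = 24,
                          times_h = c(3, 7, 11, 15, 19, 23), reps = 3,
                          noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_all <- rep(times_h, rep(reps, length(times_h)))
  base <- mu * (1 + a * cos(2 * pi * (t_all - phase) / period))
  if (noise_sd > 0) base <- base * exp(rnorm(length(base), 0, noise_sd))
  base
}
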