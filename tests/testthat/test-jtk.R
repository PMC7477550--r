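test_that("the scan grid enumerates period/lag combinations correctly", {
  g <- jtk_grid(c(3, 7, 11, 15, 19, 23))
  expect_equal(nrow(g), 18L)
  expect_equal(sort(unique(g$period_h)), c(20, 24, 28))
  expect_equal(sum(g$period_h == 24), 6L)
  expect_equal(g$lag_h[g$period_h == 20], seq(0, 16, 4))
  expect_error(jtk_grid(c(3, 7, 12)), "equally spaced")
})

test_that("reference patterns anchor phase at the first timepoint", {
  t6 <- c(3, 7, 11, 15, 19, 23)
  r <- reference_pattern(24, 0, t6, 1)
  expect_equal(r[1], 1)
  expect_equal(reference_pattern(24, 12, t6, 1), -r)
  r3 <- reference_pattern(24, 0, t6, 3)
  expect_equal(r3, rep(r, rep(3, 6)))
})

test_that("kendall_s enumerates concordant and discordant pairs", {
  r <- kendall_s(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$S, 6)
  expect_equal(r$tau, 1)
  expect_equal(kendall_s(c(1, 2, 3, 4), c(40, 30, 20, 10))$S, -6)
  r <- kendall_s(c(1, 1, 2), c(0, 1, 2))
  expect_equal(r$S, 2)
  expect_equal(r$tie_pattern_x, c(2L, 1L))
  expect_equal(r$tie_pattern_ref, c(1L, 1L, 1L))
  expect_error(kendall_s(1:3, 1:2), "length")
  expect_error(kendall_s(1, 1), "fewer than 2")
  expect_error(kendall_s(c(1, 2), c(1, 2), missing_mask = c(FALSE, TRUE)),
               "fewer than 2")
})

test_that("exact null p-values match first principles on small cases", {
  expect_equal(exact_null_pvalue(0, c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(exact_null_pvalue(6, rep(1, 4), rep(1, 4)), 2 / 24)
  # n = 6, reference ties (3, 3), distinct data, S at its maximum (9)
  d <- kendall_null_distribution(rep(1, 6), c(3, 3))
  expect_equal(exact_null_pvalue(9, rep(1, 6), c(3, 3)),
               brute_kendall_pvalue(9, rep(1, 6), c(3, 3)))
  expect_equal(sum(d$prob), 1)
})

test_that("the DP null equals exhaustive enumeration for random tie patterns", {
  set.seed(101)
  for (rep_i in 1:40) {
    n <- sample(3:7, 1)
    tx <- random_tie_pattern(n)
    tr <- random_tie_pattern(n)
    dp <- kendall_null_distribution(tx, tr)
    bf <- brute_kendall_null(tx, tr)
    expect_equal(dp$S[dp$prob > 1e-15], bf$S,
                 info = paste("x:", paste(tx, collapse = ","),
                              "ref:", paste(tr, collapse = ",")))
    expect_equal(dp$prob[dp$prob > 1e-15], bf$prob, tolerance = 1e-12)
    # distribution is symmetric about 0 and sums to 1
    expect_equal(sum(dp$prob), 1, tolerance = 1e-12)
    expect_equal(sum(dp$prob * dp$S), 0, tolerance = 1e-9)
  }
})

test_that("max |S| given tie patterns agrees with enumeration", {
  set.seed(55)
  for (rep_i in 1:20) {
    n <- sample(3:7, 1)
    tx <- random_tie_pattern(n)
    tr <- random_tie_pattern(n)
    bf <- brute_kendall_null(tx, tr)
    expect_equal(diurnal:::max_kendall_s(tx, tr), max(bf$S))
  }
})

test_that("a noise-free ZT7 cosine is detected with tau 1 and phase 7", {
  x <- cosine_series(mu = 10, a = 0.5, phase = 7)
  r <- jtk_scan(x, c(3, 7, 11, 15, 19, 23), 3)
  expect_equal(r$tau, 1)
  expect_equal(r$phase_zt, 7)
  expect_lt(r$p_adj, 0.01)
  expect_gt(r$amplitude, 3.5)
})

test_that("antiphase signals report the half-period-shifted lag", {
  x <- cosine_series(mu = 10, a = 0.5, phase = 19, noise_sd = 0.05,
                     seed = 77)
  r <- jtk_scan(x, c(3, 7, 11, 15, 19, 23), 3)
  err <- abs(((r$phase_zt - 19 + 12) %% 24) - 12)
  expect_lte(err, 4)
  expect_gte(r$tau, 0)
})

test_that("degenerate series are reported, not errors", {
  r <- jtk_scan(rep(3, 18), c(3, 7, 11, 15, 19, 23), 3)
  expect_equal(r$p_adj, 1)
  expect_equal(r$tau, 0)
  expect_equal(r$amplitude, 0)
  r <- jtk_scan(rep(NA_real_, 18), c(3, 7, 11, 15, 19, 23), 3,
                missing_mask = rep(TRUE, 18))
  expect_equal(r$p_adj, 1)
})

test_that("p_adj is invariant under strictly monotone transforms", {
  set.seed(202)
  for (i in 1:5) {
    x <- cosine_series(a = 0.4, phase = runif(1, 0, 24), noise_sd = 0.2)
    r1 <- jtk_scan(x, c(3, 7, 11, 15, 19, 23), 3)
    r2 <- jtk_scan(exp(x / 10), c(3, 7, 11, 15, 19, 23), 3)
    expect_equal(r2$p_adj, r1$p_adj)
    expect_equal(r2$period_h, r1$period_h)
    expect_equal(r2$phase_zt, r1$phase_zt)
  }
})

test_that("shifting a noise-free oscillator by one sampling interval shifts its phase", {
  for (base_phase in c(7, 11, 15)) {
    x1 <- cosine_series(a = 0.5, phase = base_phase)
    x2 <- cosine_series(a = 0.5, phase = base_phase + 4)
    r1 <- jtk_scan(x1, c(3, 7, 11, 15, 19, 23), 3)
    r2 <- jtk_scan(x2, c(3, 7, 11, 15, 19, 23), 3)
    expect_equal((r2$phase_zt - r1$phase_zt) %% 24, 4)
  }
})

test_that("jtk_cycle agrees with gene-by-gene jtk_scan", {
  set.seed(404)
  vals <- rbind(cosine_series(a = 0.5, phase = 7, noise_sd = 0.1),
                cosine_series(a = 0.3, phase = 15, noise_sd = 0.1),
                rlnorm(18), rep(2, 18))
  tc <- make_tc(vals)
  tc$missing_mask[2, 4] <- TRUE
  res <- jtk_cycle(tc)
  for (g in 1:4) {
    single <- jtk_scan(vals[g, ], tc$times_h, 3,
                       missing_mask = tc$missing_mask[g, ],
                       gene_id = tc$gene_ids[g])
    expect_equal(res[g, names(single)], single, ignore_attr = TRUE)
  }
})

test_that("rhythmic calls use a strict cutoff", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    p_adj = c(0.005, 0.01, 0.5))
  expect_equal(call_rhythmic(res), "a")
  expect_equal(call_rhythmic(res, alpha = 1), c("a", "b", "c"))
  expect_equal(call_rhythmic(res[0, ]), character())
})

test_that("the false-positive rate on null data respects the cutoff", {
  set.seed(505)
  n <- 400
  vals <- matrix(rlnorm(n * 18, log(10), 0.4), n, 18)
  res <- jtk_cycle(make_tc(vals))
  expect_lte(mean(res$p_adj < 0.01),
             0.01 + 3 * sqrt(0.01 * 0.99 / n))
})
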