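noise_free_spec <- function(...) {
  simulation_spec(n_genes = 40, conditions = c("ctrl", "treat"),
                  de_novo_condition = "treat", baseline_log_sd = 0,
                  noise_sd = 0, outlier_rate = 0, seed = 17, ...)
}

test_that("amplitude-zero, noise-free genes are flat at their baseline", {
  spec <- noise_free_spec(frac_exclusive_a = 0, frac_common = 0,
                          frac_de_novo = 0)
  sim <- generate_timecourse(spec)
  for (m in sim$matrices) {
    expect_equal(m$values, matrix(rep(sim$truth$mu, 18), 40, 18,
                                  dimnames = dimnames(m$values)))
  }
})

test_that("the cosine model evaluates exactly at planted parameters", {
  # mu = 10, a = 0.5, phase = ZT7, P = 24: value 15 at ZT7, 5 at ZT19
  spec <- noise_free_spec(frac_exclusive_a = 0, frac_common = 0,
                          frac_de_novo = 1, phase_de_novo = 7,
                          phase_jitter_sd = 0,
                          amplitude_range = c(0.5, 0.5))
  sim <- generate_timecourse(spec)
  treat <- sim$matrices$treat
  zt7 <- which(tc_sample_times(treat) == 7)
  zt19 <- which(tc_sample_times(treat) == 19)
  expect_equal(unname(treat$values[, zt7]),
               matrix(15, 40, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(treat$values[, zt19]),
               matrix(5, 40, 3), tolerance = 1e-12, ignore_attr = TRUE)
  # control condition has no oscillation for de-novo genes
  expect_equal(unname(sim$matrices$ctrl$values[1, ]), rep(10, 18))
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- simulation_spec(n_genes = 30, seed = 17)
  a <- generate_timecourse(spec)
  b <- generate_timecourse(spec)
  expect_identical(a, b)
  c <- generate_timecourse(simulation_spec(n_genes = 30, seed = 18))
  expect_false(identical(a$matrices[[1]]$values, c$matrices[[1]]$values))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(simulation_spec(frac_common = 0.9, frac_de_novo = 0.5),
               "sum")
  expect_error(simulation_spec(amplitude_range = c(0.5, 1.2)),
               "nonnegative|amplitude")
  expect_error(simulation_spec(p_in = 1.4), "probabilities")
  expect_error(simulation_spec(times_h = c(3, 7, 24)), "24")
})

test_that("outlier injection hits exactly one replicate per draw", {
  spec <- noise_free_spec(frac_exclusive_a = 0, frac_common = 0,
                          frac_de_novo = 0)
  tc <- generate_timecourse(spec)$matrices$ctrl
  expect_identical(inject_outliers(tc, 0, 8, seed = 3)$matrix$values,
                   tc$values)
  inj <- inject_outliers(tc, 1, 8, seed = 3)
  ratio <- inj$matrix$values / tc$values
  tp <- tc_timepoint_index(tc)
  for (t in unique(tp)) {
    expect_true(all(rowSums(ratio[, tp == t] == 8) == 1))
  }
  expect_equal(nrow(inj$log), 40 * 6)
})

test_that("injected counts follow the binomial law at q = 0.1", {
  set.seed(9)
  vals <- matrix(rlnorm(500 * 18), 500, 18)
  tc <- make_tc(vals)
  inj <- inject_outliers(tc, 0.1, 8, seed = 21)
  n_cells <- 500 * 6
  expect_lt(abs(nrow(inj$log) - 0.1 * n_cells),
            3 * sqrt(n_cells * 0.1 * 0.9))
})

test_that("focal-TF sites land in target promoters and nowhere else", {
  spec <- simulation_spec(n_genes = 60, p_in = 1, p_out = 0,
                          n_decoy_tfs = 0, seed = 5)
  sim <- generate_timecourse(spec)
  ann <- generate_motif_annotation(spec, sim$truth)
  expect_true(all(ann$sites$tf_name == "PPARG"))
  # permissive quality filter: placement, not score, is under test
  hits <- genes_with_site("PPARG", ann$sites, ann$annotation,
                          window = c(3000, 1000),
                          filter = site_filter(0, 1, 1e6))
  targets <- names(which(sim$truth$is_focal_target))
  expect_setequal(hits, targets)
  expect_setequal(targets,
                  names(sim$truth$class)[sim$truth$class == "de_novo"])
})

test_that("site scores and peak coverage follow the stated model", {
  spec <- simulation_spec(n_genes = 300, seed = 11)
  sim <- generate_timecourse(spec)
  ann <- generate_motif_annotation(spec, sim$truth)
  expect_true(all(ann$sites$site_fdr >= 0 & ann$sites$site_fdr < 0.5))
  expect_true(all(ann$sites$bbls > 0))
  expect_true(all(ann$sites$start < ann$sites$end))
  n_focal <- sum(ann$sites$tf_name == "PPARG")
  expect_equal(n_focal, sum(sim$truth$is_focal_target))
  # ~90% of focal sites carry a covering peak
  expect_gt(nrow(ann$peaks), 0.75 * n_focal)
  expect_lt(nrow(ann$peaks), n_focal + 1)
})
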