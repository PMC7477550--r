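two_gene_annotation <- data.frame(
  gene_id = c("gPlus", "gMinus"), chrom = "chr1",
  tss = c(100000L, 100000L), strand = c("+", "-"),
  stringsAsFactors = FALSE)

site_row <- function(start, end, tf = "TF1", bbls = 5, fdr = 0.01) {
  data.frame(tf_name = tf, chrom = "chr1", start = start, end = end,
             bbls = bbls, site_fdr = fdr, stringsAsFactors = FALSE)
}

test_that("promoter windows are strand-aware and half-open", {
  ann <- two_gene_annotation[1, ]
  expect_setequal(genes_with_site("TF1", site_row(95000, 95010), ann),
                  "gPlus")
  # base 102000 is one past the half-open end of [90000, 102000)
  expect_length(genes_with_site("TF1", site_row(102000, 102001), ann), 0)
  expect_setequal(genes_with_site("TF1", site_row(101999, 102000), ann),
                  "gPlus")
  # minus strand: upstream extends rightward
  annm <- two_gene_annotation[2, ]
  expect_setequal(genes_with_site("TF1", site_row(101999, 102005), annm),
                  "gMinus")
  expect_length(genes_with_site("TF1", site_row(85000, 85010), annm), 0)
  expect_setequal(genes_with_site("TF1", site_row(98000, 98010), annm),
                  "gMinus")
})

test_that("site quality thresholds are strict inequalities", {
  ann <- two_gene_annotation[1, ]
  expect_length(genes_with_site("TF1",
                                site_row(95000, 95010, bbls = 1.0), ann),
                0)
  expect_setequal(genes_with_site("TF1",
                                  site_row(95000, 95010, bbls = 1.001),
                                  ann), "gPlus")
  expect_length(genes_with_site("TF1",
                                site_row(95000, 95010, fdr = 0.25), ann),
                0)
  expect_warning(out <- genes_with_site("NOPE", site_row(1, 2), ann),
                 "no sites")
  expect_length(out, 0)
})

# synthetic annotation used by the table-level tests: gene g_i owns
# territory [i*1e4, (i+1)*1e4) with tss at its centre, + strand
grid_annotation <- function(n) {
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), chrom = "chrT",
             tss = as.integer((seq_len(n) - 1) * 10000 + 5000),
             strand = "+", stringsAsFactors = FALSE)
}

sites_for_genes <- function(idx, tf = "TF1") {
  ann <- grid_annotation(max(idx))
  data.frame(tf_name = tf, chrom = "chrT",
             start = ann$tss[idx] - 100L, end = ann$tss[idx] - 80L,
             bbls = 5, site_fdr = 0.01, stringsAsFactors = FALSE)
}

test_that("fisher enrichment reproduces the exact hypergeometric tail", {
  n_bg <- 1000
  ann <- grid_annotation(n_bg)
  bg <- ann$gene_id
  gene_set <- bg[1:50]
  with_site <- c(1:20, 101:180)  # 20 in the set, 80 outside, 100 total
  sites <- sites_for_genes(with_site)
  rec <- fisher_enrichment(gene_set, bg, sites, ann,
                           window = c(2000, 500))
  expect_equal(rec$k, 20)
  expect_equal(rec$K, 80)
  oracle <- hyper_tail_oracle(20, 100, 900, 50)
  expect_equal(rec$p_one_sided, oracle, tolerance = 1e-12)
  expect_equal(rec$p_one_sided,
               fisher.test(matrix(c(20, 30, 80, 870), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)
})

test_that("proportional composition yields no enrichment", {
  n_bg <- 1000
  ann <- grid_annotation(n_bg)
  bg <- ann$gene_id
  gene_set <- bg[1:100]
  sites <- sites_for_genes(c(1:10, 101:190))  # 10% in and out of set
  rec <- fisher_enrichment(gene_set, bg, sites, ann,
                           window = c(2000, 500))
  expect_equal(rec$odds_ratio, 1)
  expect_gt(rec$p_one_sided, 0.5)
  expect_error(fisher_enrichment(c("nope"), bg, sites, ann), "subset")
})

test_that("enrichment matches the summation oracle on random tables", {
  set.seed(91)
  for (i in 1:25) {
    N <- sample(20:600, 1)
    ann <- grid_annotation(N)
    n_set <- sample(5:(N %/% 2), 1)
    gene_set <- ann$gene_id[sample.int(N, n_set)]
    hit_idx <- sample.int(N, sample.int(N, 1))
    rec <- fisher_enrichment(gene_set, ann$gene_id,
                             sites_for_genes(hit_idx), ann,
                             window = c(2000, 500))
    k <- sum(ann$gene_id[hit_idx] %in% gene_set)
    expect_equal(rec$k, k)
    expect_equal(rec$p_one_sided,
                 hyper_tail_oracle(k, length(hit_idx),
                                   N - length(hit_idx), n_set),
                 tolerance = 1e-10)
  }
})

test_that("degenerate motifs are excluded from testing", {
  ann <- grid_annotation(20)
  sites <- do.call(rbind, replicate(3, sites_for_genes(1:20), FALSE))
  sites$tf_name <- "BLUR"
  rec <- fisher_enrichment(ann$gene_id[1:5], ann$gene_id, sites, ann,
                           filter = site_filter(max_sites_per_tf = 50))
  expect_equal(rec$excluded_reason, "degenerate motif")
  expect_true(is.na(rec$p_one_sided))
})

test_that("meta-analysis labels exclusive and shared TFs", {
  mk <- function(p) data.frame(tf_name = c("TFa", "TFb", "TFc"),
                               p_one_sided = p,
                               neg_log10_p = -log10(p),
                               stringsAsFactors = FALSE)
  recs <- list(c1 = mk(c(0.001, 0.002, 0.5)),
               c2 = mk(c(0.2, 0.005, 0.6)),
               c3 = mk(c(0.8, 0.9, 0.7)),
               c4 = mk(c(0.5, 0.4, 0.3)))
  meta <- meta_exclusive_tfs(recs, alpha_tf = 0.01)
  expect_equal(meta$exclusive[meta$tf_name == "TFa"], "c1")
  expect_equal(meta$exclusive[meta$tf_name == "TFb"], "shared")
  expect_equal(meta$exclusive[meta$tf_name == "TFc"], "none")
  bad <- recs
  bad$c2$tf_name <- c("TFx", "TFy", "TFz")
  expect_error(meta_exclusive_tfs(bad), "universe")
})

test_that("target sets combine motif and peak evidence", {
  ann <- grid_annotation(10)
  sites <- sites_for_genes(1:4)
  no_peaks <- data.frame(chrom = character(), start = integer(),
                         end = integer())
  expect_length(build_target_set("TF1", sites, no_peaks, ann,
                                 window = c(3000, 1000)), 0)
  peaks <- data.frame(chrom = "chrT",
                      start = ann$tss[c(1, 2)] - 150L,
                      end = ann$tss[c(1, 2)] - 50L)
  got <- build_target_set("TF1", sites, peaks, ann,
                          window = c(3000, 1000))
  expect_setequal(got, c("g0001", "g0002"))
  # peak outside the window does not rescue a gene
  far_peak <- data.frame(chrom = "chrT", start = ann$tss[3] - 9000L,
                         end = ann$tss[3] - 8000L)
  expect_false("g0003" %in%
                 build_target_set("TF1", sites, far_peak, ann,
                                  window = c(3000, 1000)))
  expect_setequal(build_target_set("TF1", sites, no_peaks, ann,
                                   window = c(3000, 1000),
                                   require_peak = FALSE),
                  genes_with_site("TF1", sites, ann,
                                  window = c(3000, 1000)))
  # peak requirement can only shrink the set
  expect_true(all(got %in% sprintf("g%04d", 1:4)))
})

test_that("gene-set enrichment ranks overlap and applies BH", {
  bg <- sprintf("g%03d", 1:200)
  study <- bg[1:20]
  coll <- list(hit = study, half = bg[11:30], miss = bg[150:170])
  res <- gene_set_enrichment(study, bg, coll)
  expect_equal(res$set_name[1], "hit")
  expect_equal(res$p_one_sided[res$set_name == "miss"], 1)
  expect_equal(res$q_bh, p.adjust(res$p_one_sided, "BH"))
  # BH on a known p-vector: step-up gives all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_warning(out <- gene_set_enrichment(study, bg,
                                            list(x = c("zz"))),
                 "no gene set")
  expect_equal(nrow(out), 0)
})
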