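test_that("TPM normalization scales each sample to one million", {
  m <- matrix(c(1, 1, 2, 5, 5, 10), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  tpm <- normalize_tpm(m)
  expect_equal(tpm[, "s1"], c(g1 = 250000, g2 = 250000, g3 = 500000))
  expect_equal(unname(colSums(tpm)), c(1e6, 1e6))
  expect_equal(normalize_tpm(tpm), tpm)  # idempotent
  m2 <- m
  m2[, 2] <- 0
  expect_error(normalize_tpm(m2), "s2")
  expect_error(normalize_tpm(-m), "nonnegative")
})

test_that("log2 fold change follows the pseudocount arithmetic", {
  genes <- sprintf("g%02d", 1:10)
  ctrl <- matrix(rep(c(100, rep(50, 9)), 3), ncol = 3,
                 dimnames = list(genes, c("c1", "c2", "c3")))
  ctrl["g05", ] <- c(49, 50, 51)  # some control variance
  kd <- matrix(c(25, rep(50, 9)), ncol = 1,
               dimnames = list(genes, "k1"))
  de <- differential_expression(cbind(kd, ctrl), "k1", c("c1", "c2", "c3"),
                                pseudocount = 1)
  expect_equal(de$log2fc[de$gene == "g01"], log2(26 / 101),
               tolerance = 1e-12)
  expect_equal(de$log2fc[de$gene == "g02"], 0)
  ## a larger pseudocount shrinks |log2FC| for low-expression genes
  low <- matrix(c(2, rep(50, 9), rep(c(8, rep(50, 9)), 3)), ncol = 4,
                dimnames = list(genes, c("k1", "c1", "c2", "c3")))
  d1 <- differential_expression(low, "k1", c("c1", "c2", "c3"),
                                pseudocount = 1)
  d5 <- differential_expression(low, "k1", c("c1", "c2", "c3"),
                                pseudocount = 5)
  expect_lt(abs(d5$log2fc[1]), abs(d1$log2fc[1]))
})

test_that("experiment-wide scaling uses the sample standard deviation", {
  m <- rbind(a = c(-1, 0, 1), b = c(2, 2, 2), c = c(0, 1, 5))
  z <- scale_changes(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))  # sample SD of (-1,0,1) is 1
  expect_equal(unname(z["b", ]), c(0, 0, 0))   # zero spread
  expect_equal(unname(rowMeans(z)), c(0, 0, 0))
  expect_error(scale_changes(m[, 1:2]), "at least 3")
})

test_that("DEG calls require all three gates", {
  expect_equal(call_degs(0.6, 2.0, 0.04), 1L)
  expect_equal(call_degs(0.6, 1.0, 0.04), 0L)   # z gate fails
  expect_equal(call_degs(0.6, 2.0, 0.06), 0L)   # fdr gate fails
  expect_equal(call_degs(0.4, 2.0, 0.04), 0L)   # fold-change gate fails
  expect_equal(call_degs(-0.6, -2.0, 0.01), -1L)
  expect_equal(call_degs(c(0.6, -0.6), c(2, -2), c(0.04, 0.04)),
               c(1L, -1L))
})

test_that("signed DEG sets encode gene and direction", {
  calls <- matrix(c(1L, 0L, -1L, 0L, 0L, 1L), nrow = 3,
                  dimnames = list(c("g1", "g2", "g3"), c("a1", "a2")))
  s <- deg_sets(calls)
  expect_equal(s$a1, c("g1|+", "g3|-"))
  expect_equal(s$a2, "g3|+")
})

test_that("targeted genes are called down-regulated after efficient knockdown", {
  scr <- simulate_screen(screen_config(n_targets = 12, asos_per_target = 5,
                                       n_genes = 400, n_motifs = 3,
                                       n_gene_sets = 3, seed = 19))
  mp <- molecular_phenotype(scr$expression, scr$sample_sheet)
  e <- scr$truth$kd_efficiency
  strong <- names(e)[e >= 0.6]
  calls <- vapply(strong, function(a) {
    mp$calls[scr$truth$aso_target[[a]], a]
  }, integer(1))
  expect_gte(mean(calls == -1), 0.95)
})

test_that("divergent partner summary reports the median absolute change", {
  lfc <- matrix(c(0.1, -0.2, 0.13, 0, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("pcg1", "pcg2"),
                                c("a1", "a2", "a3")))
  fdr <- matrix(1, 2, 3, dimnames = dimnames(lfc))
  mp <- list(log2fc = lfc, fdr = fdr)
  tm <- data.frame(aso_id = c("a1", "a2", "a3"),
                   target_id = c("t1", "t2", "t3"))
  pm <- data.frame(target_id = c("t1", "t2", "t3"),
                   partner_gene = c("pcg1", "pcg1", "pcg1"))
  res <- divergent_partner_response(mp, tm, pm)
  expect_equal(res$median_abs_log2fc, 0.13)
  ## missing partner genes are excluded, empty maps give NA
  pm2 <- data.frame(target_id = "t1", partner_gene = "absent")
  res2 <- divergent_partner_response(mp, tm, pm2)
  expect_true(res2$per_aso$missing)
  expect_true(is.na(res2$median_abs_log2fc))
  res3 <- divergent_partner_response(mp, tm, pm[0, ])
  expect_true(is.na(res3$median_abs_log2fc))
})

test_that("null screens produce almost no false DEGs", {
  fp <- 0
  ng <- 0
  for (s in 1:5) {
    cfg <- screen_config(n_targets = 10, asos_per_target = 5,
                         n_genes = 300, n_motifs = 3, n_gene_sets = 3,
                         frac_true_growth_hits = 0,
                         frac_true_molecular_hits = 0,
                         growth_effect_size = 0,
                         offtarget_effect_size = 0, seed = 600 + s)
    scr <- simulate_screen(cfg)
    mp <- molecular_phenotype(scr$expression, scr$sample_sheet)
    m <- mp$calls[!(rownames(mp$calls) %in% scr$truth$aso_target), ]
    fp <- fp + sum(m != 0)
    ng <- ng + length(m)
  }
  expect_lte(fp / ng, 0.005)
})
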