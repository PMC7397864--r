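test_that("confluence model is exact without noise and clips to range", {
  t <- seq(0, 30, by = 3)
  expect_equal(simulate_confluence(2, t, start = 10, noise_sd = 0), 10 + 2 * t)
  expect_equal(simulate_confluence(0, t, start = 50, noise_sd = 0),
               rep(50, length(t)))
  expect_equal(simulate_confluence(5, 10, start = 80, noise_sd = 0), 100)
  expect_equal(simulate_confluence(-10, c(0, 5, 10), start = 30,
                                   noise_sd = 0), c(30, 0, 0))
  expect_error(simulate_confluence(1, numeric(0)), "empty time grid")
  expect_error(simulate_confluence(1, 0:5, start = 120), "0, 100")
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(screen_config(n_targets = 0), "n_targets")
  expect_error(screen_config(frac_true_growth_hits = 1.2),
               "frac_true_growth_hits")
  expect_error(screen_config(timepoints_h = c(0, 3, 3)), "timepoints_h")
  expect_error(screen_config(timepoints_h = c(0, 3)), "timepoints_h")
  expect_error(screen_config(kd_efficiency_params = c(1, -1)),
               "kd_efficiency_params")
  expect_error(screen_config(n_targets = 50, n_genes = 10), "n_genes")
})

test_that("simulation is deterministic given config and seed", {
  cfg <- test_config(seed = 42)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  c <- simulate_screen(test_config(seed = 43))
  expect_false(identical(a$expression, c$expression))
})

test_that("screen tables satisfy their structural invariants", {
  scr <- simulate_screen(test_config(seed = 3))
  cf <- scr$confluence
  expect_true(all(cf$confluence >= 0 & cf$confluence <= 100))
  nc_wells <- unique(cf[cf$role == "NC_A", c("plate", "well")])
  expect_true(all(table(nc_wells$plate) == scr$config$controls_per_plate))
  expect_setequal(scr$sample_sheet$sample_id, colnames(scr$expression))
  expect_true(all(scr$expression >= 0))
  expect_true(all(scr$kd$efficiency >= 0 & scr$kd$efficiency <= 1))
  ## every ASO maps to exactly one target, and module genes exist
  expect_true(all(table(names(scr$truth$aso_target)) == 1))
  for (m in scr$truth$shared_modules) {
    expect_true(all(m$gene %in% rownames(scr$expression)))
  }
})

test_that("null screens put ASO wells on the control slope", {
  cfg <- test_config(frac_true_growth_hits = 0, frac_true_molecular_hits = 0,
                     growth_effect_size = 0, slope_sd_well = 0,
                     noise_sd_confluence = 0, seed = 5)
  scr <- simulate_screen(cfg)
  expect_true(all(abs(scr$truth$well_slopes - cfg$base_slope) < 1e-12))
})

test_that("null-screen ASO and control well slopes are indistinguishable", {
  sl_aso <- c(); sl_nc <- c()
  for (s in 1:5) {
    cfg <- screen_config(n_targets = 20, asos_per_target = 5, n_genes = 50,
                         n_motifs = 3, n_gene_sets = 3,
                         frac_true_growth_hits = 0,
                         frac_true_molecular_hits = 0,
                         growth_effect_size = 0, seed = 700 + s)
    scr <- simulate_screen(cfg)
    w <- unique(scr$confluence[, c("plate", "well", "role")])
    sl <- scr$truth$well_slopes[paste(w$plate, w$well, sep = ":")]
    sl_aso <- c(sl_aso, sl[w$role == "ASO"])
    sl_nc <- c(sl_nc, sl[w$role == "NC_A"])
  }
  expect_gte(length(sl_aso), 200)
  ks <- suppressWarnings(stats::ks.test(sl_aso, sl_nc))
  expect_gt(ks$p.value, 0.01)
})

test_that("knockdown reduces target expression by the efficiency in expectation", {
  ## force efficiency ~ 0.8 and average the target's knockdown/control
  ## expression ratio over >= 100 knockdown libraries
  cfg <- screen_config(n_targets = 2, asos_per_target = 25, kd_reps = 4,
                       n_genes = 100, n_motifs = 3, n_gene_sets = 3,
                       kd_efficiency_params = c(8000, 2000),
                       frac_true_growth_hits = 0,
                       frac_true_molecular_hits = 0,
                       offtarget_effect_size = 0,
                       noise_sd_logexpr = 0.1, seed = 9)
  scr <- simulate_screen(cfg)
  sheet <- scr$sample_sheet
  tg <- "LNC001"
  kd_samples <- sheet$sample_id[!sheet$is_control & sheet$target_id == tg]
  ctrl_samples <- sheet$sample_id[sheet$is_control]
  expect_gte(length(kd_samples), 100)
  ratio <- mean(scr$expression[tg, kd_samples]) /
    mean(scr$expression[tg, ctrl_samples])
  expect_gt(ratio, 0.17)
  expect_lt(ratio, 0.23)
})

test_that("larger planted growth effects reduce true-hit well slopes", {
  means <- vapply(c(0.2, 0.4, 0.6), function(es) {
    scr <- simulate_screen(test_config(frac_true_growth_hits = 0.5,
                                       growth_effect_size = es, seed = 77))
    w <- unique(scr$confluence[, c("plate", "well", "role", "aso_id")])
    sl <- scr$truth$well_slopes[paste(w$plate, w$well, sep = ":")]
    hit_aso <- w$role == "ASO" &
      scr$truth$aso_target[w$aso_id] %in% scr$truth$growth_hit_targets &
      scr$truth$aso_success[w$aso_id]
    mean(sl[hit_aso])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
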