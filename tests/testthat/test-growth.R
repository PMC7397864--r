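make_plate <- function(nc_values, aso_values, times = seq(0, 48, 3)) {
  rows <- list()
  add <- function(well, role, aso, vals) {
    data.frame(plate = 1, well = well, role = role, aso_id = aso,
               time_h = times, confluence = vals,
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(nc_values)) {
    rows[[length(rows) + 1]] <- add(sprintf("NC%d", i), "NC_A", NA,
                                    nc_values[[i]])
  }
  for (i in seq_along(aso_values)) {
    rows[[length(rows) + 1]] <- add(sprintf("A%d", i), "ASO",
                                    sprintf("aso%d", i), aso_values[[i]])
  }
  do.call(rbind, rows)
}

test_that("series are truncated at the first time plate controls reach 90%", {
  t <- seq(0, 48, 3)
  ## controls cross 90 at t = 30
  plate <- make_plate(list(10 + (80 / 30) * t), list(5 + t))
  out <- truncate_to_control_window(plate)
  expect_equal(sort(unique(out$time_h)), seq(0, 30, 3))
  ## controls never reach 90: full series kept
  plate2 <- make_plate(list(pmin(10 + t, 70)), list(5 + t))
  expect_equal(nrow(truncate_to_control_window(plate2)), nrow(plate2))
  ## controls at 90 already by t = 3: fewer than 3 points -> plate error
  plate3 <- make_plate(list(c(89, rep(95, length(t) - 1))), list(5 + t))
  expect_error(truncate_to_control_window(plate3), "fewer than 3")
  ## no NC_A wells at all
  plate4 <- make_plate(list(), list(5 + t))
  expect_error(truncate_to_control_window(plate4), "no NC_A")
})

test_that("growth-rate estimator is exact on linear input", {
  t <- seq(0, 30, 3)
  expect_equal(estimate_growth_rate(t, 10 + 2 * t), 2)
  expect_equal(estimate_growth_rate(t, rep(50, length(t))), 0)
  expect_equal(estimate_growth_rate(c(0, 3, 6), c(60, 54, 48)), -2)
  expect_error(estimate_growth_rate(c(0, 3), c(1, 2)), "at least 3")
  expect_error(estimate_growth_rate(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("slope estimator is unbiased with RMSE matching the OLS closed form", {
  set.seed(5)
  t <- seq(0, 48, 3)
  true_slope <- 1.2
  noise <- 2
  sl <- replicate(400, estimate_growth_rate(
    t, simulate_confluence(true_slope, t, 10, noise)))
  se_theory <- noise / sqrt(sum((t - mean(t))^2))
  expect_lt(abs(mean(sl) - true_slope), 0.02)
  expect_lt(abs(sqrt(mean((sl - true_slope)^2)) / se_theory - 1), 0.1)
})

test_that("normalization divides by plate control mean and keeps signs", {
  expect_equal(normalize_growth_rate(1.5, c(1.4, 1.5, 1.6)), 1)
  expect_equal(normalize_growth_rate(-0.5, c(1, 1, 1)), -0.5)
  expect_equal(normalize_growth_rate(0, c(2, 2)), 0)
  expect_error(normalize_growth_rate(1, numeric(0)), "at least one")
  expect_error(normalize_growth_rate(1, c(-1, 0.5)), "controls failed")
})

test_that("pooled t-test matches the textbook formula and its symmetries", {
  reps <- c(0.5, 0.6)
  ctrl <- c(1.0, 1.1, 0.9, 1.0, 1.05, 0.95)
  res <- growth_significance(reps, ctrl)
  expect_equal(res$df, 6)
  expect_equal(res$t_stat, -7.7942286, tolerance = 1e-6)
  o <- pooled_t_oracle(reps, ctrl)
  expect_equal(res$t_stat, o$t, tolerance = 1e-12)
  expect_equal(res$p_value, o$p, tolerance = 1e-12)
  ## swapping groups negates t, p unchanged
  sw <- growth_significance(ctrl, reps)
  expect_equal(sw$t_stat, -res$t_stat)
  expect_equal(sw$p_value, res$p_value)
  ## identical groups: t = 0, p = 1; zero variance unequal means: p = 0
  same <- growth_significance(c(1, 1), c(1, 1, 1))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  deg <- growth_significance(c(2, 2), c(1, 1, 1))
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
})

test_that("pooled t-test matches the oracle on random instances", {
  set.seed(21)
  for (i in 1:300) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 2))
    res <- growth_significance(x, y)
    o <- pooled_t_oracle(x, y)
    expect_equal(res$t_stat, o$t, tolerance = 1e-10)
    expect_equal(res$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("FDR adjustment reproduces the step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_error(adjust_fdr(c(0.5, 1.5)), "0, 1")
  set.seed(31)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("per-ASO growth analysis normalizes and tests against plate controls", {
  t <- seq(0, 48, 3)
  nc <- lapply(c(1.0, 1.1, 0.9, 1.0, 1.05, 0.95),
               function(s) pmin(10 + s * t, 100))
  aso <- lapply(c(0.5, 0.6, 1.02, 0.98), function(s) pmin(10 + s * t, 100))
  plate <- make_plate(nc, aso)
  plate$aso_id[plate$role == "ASO"] <-
    rep(c("slow", "slow", "norm", "norm"), each = length(t))
  res <- analyze_growth(plate)
  slow <- res[res$aso_id == "slow", ]
  expect_equal(slow$normalized_rate, 0.55, tolerance = 1e-6)
  expect_equal(slow$t_stat, -7.7942286, tolerance = 1e-4)
  expect_true(slow$significant_inhibition)
  expect_false(res$significant_inhibition[res$aso_id == "norm"])
  ## control wells normalize to mean exactly 1 by construction
  trunc <- truncate_to_control_window(plate)
  nc_rows <- trunc[trunc$role == "NC_A", ]
  nc_slopes <- vapply(split(nc_rows, nc_rows$well), function(w) {
    estimate_growth_rate(w$time_h, w$confluence)
  }, numeric(1))
  expect_equal(mean(nc_slopes / mean(nc_slopes)), 1, tolerance = 1e-12)
})
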