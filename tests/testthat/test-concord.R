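test_that("Jaccard index matches its definition on signed sets", {
  expect_equal(jaccard_index(c("a|+", "b|-"), c("a|+", "b|-")), 1)
  expect_equal(jaccard_index(c("a|+"), c("b|+")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 0)
  expect_equal(jaccard_index(c("a|+", "b|+", "c|-", "d|-"),
                             c("c|-", "d|-", "e|+")), 0.4)
  set.seed(41)
  universe <- sprintf("g%02d|%s", 1:30, sample(c("+", "-"), 30, TRUE))
  for (i in 1:200) {
    a <- sample(universe, sample(0:12, 1))
    b <- sample(universe, sample(0:12, 1))
    expect_equal(jaccard_index(a, b), jaccard_oracle(a, b))
  }
})

test_that("growth concordance p-value equals exhaustive enumeration", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    labels <- sample(rep(c("t1", "t2", "t3"), length.out = n))
    if (sum(table(labels) >= 2) < 2) next
    rates <- stats::setNames(rnorm(n), sprintf("a%d", 1:n))
    tm <- data.frame(aso_id = names(rates), target_id = labels)
    res <- global_growth_concordance(rates, tm, exhaustive = TRUE)
    d_obs <- pair_stat_oracle(rates, labels)
    d_all <- vapply(perms_oracle(labels),
                    function(l) pair_stat_oracle(rates, l), numeric(1))
    expect_equal(res$statistic, d_obs, tolerance = 1e-12)
    expect_equal(res$p_value, mean(d_all <= d_obs + 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("growth concordance handles degenerate and sampled cases", {
  rates <- stats::setNames(rep(1, 6), sprintf("a%d", 1:6))
  tm <- data.frame(aso_id = names(rates),
                   target_id = rep(c("t1", "t2", "t3"), each = 2))
  expect_equal(global_growth_concordance(rates, tm,
                                         exhaustive = TRUE)$p_value, 1)
  expect_equal(global_growth_concordance(rates, tm, n_perm = 200, seed = 1,
                                         exhaustive = FALSE)$p_value, 1)
  ## concordant same-target rates give a small plus-one p
  rates2 <- stats::setNames(c(1, 1.01, 2, 2.01, 3, 3.01, 1.5, 2.5),
                            sprintf("a%d", 1:8))
  tm2 <- data.frame(aso_id = names(rates2),
                    target_id = c("t1", "t1", "t2", "t2", "t3", "t3",
                                  "t4", "t4"))
  res <- global_growth_concordance(rates2, tm2, n_perm = 999, seed = 2,
                                   exhaustive = FALSE)
  expect_gt(res$p_value, 0)
  expect_lt(res$p_value, 0.05)
  expect_error(global_growth_concordance(rates2, tm2, n_perm = 50,
                                         exhaustive = FALSE), "n_perm")
})

test_that("pair concordance p-values follow the plus-one null rank", {
  ## 6 ASOs, 3 targets: 12 different-target pairs, exhaustively used
  sets <- list(a1 = c("g1|+", "g2|+", "g3|-"),
               a2 = c("g1|+", "g2|+", "g3|-"),
               b1 = c("g4|+"), b2 = c("g5|-"),
               c1 = c("g6|+"), c2 = character(0))
  tm <- data.frame(aso_id = names(sets),
                   target_id = rep(c("ta", "tb", "tc"), each = 2))
  res <- pair_concordance_test(sets, tm, min_null_pairs = 5, seed = 1)
  null_j <- attr(res, "null_jaccard")
  expect_equal(length(null_j), 12)
  expect_true(all(null_j == 0))
  ## identical nonempty pair: J = 1 beats all 12 nulls -> p = 1/13
  row_a <- res[res$target_id == "ta", ]
  expect_equal(row_a$jaccard, 1)
  expect_equal(row_a$n_common_degs, 3)
  expect_equal(row_a$empirical_p, 1 / 13)
  ## disjoint pair: J = 0 ties every null -> p = 1
  expect_equal(res$empirical_p[res$target_id == "tb"], 1)
  expect_error(pair_concordance_test(sets, tm), "fewer than 100")
})

test_that("reproducible pairs require both the count and the p gate", {
  pairs <- data.frame(
    aso_a = c("a", "b", "c"), aso_b = c("x", "y", "z"),
    target_id = c("t1", "t2", "t3"), pair_type = "same_target",
    n_common_degs = c(5, 4, 20), jaccard = c(0.2, 0.3, 0.4),
    empirical_p = c(0.04, 0.001, 0.2))
  keep <- reproducible_pairs(pairs)
  expect_equal(keep$target_id, "t1")
  expect_equal(attr(keep, "targets"), "t1")
})

test_that("conditional cutoffs match the closed-form hypergeometric tail", {
  expect_equal(conditional_cutoff(3, rep(FALSE, 60)), 1)
  expect_equal(conditional_cutoff(3, rep(TRUE, 60)), 4)
  pool <- rep(c(TRUE, FALSE), c(10, 90))
  expect_equal(conditional_cutoff(2, pool), kmin_hyper_oracle(2, pool))
  expect_equal(conditional_cutoff(2, pool), 2)
  set.seed(61)
  for (i in 1:300) {
    n <- sample(1:10, 1)
    pool <- sample(c(TRUE, FALSE), sample(50:200, 1), replace = TRUE,
                   prob = c(runif(1, 0, 0.5), 1))
    expect_equal(conditional_cutoff(n, pool, alpha = 0.05),
                 kmin_hyper_oracle(n, pool, alpha = 0.05))
  }
  expect_error(conditional_cutoff(2, logical(0)), "empty")
  expect_error(conditional_cutoff(2, rep(TRUE, 10)), "at least 50")
  expect_error(conditional_cutoff(11, rep(FALSE, 60)), "between 1 and 10")
})

test_that("Monte Carlo cutoffs agree with the exact tail off the boundary", {
  pool <- rep(c(TRUE, FALSE), c(30, 70))  # clear margins at alpha = 0.05
  exact <- conditional_cutoff(5, pool)
  mc <- conditional_cutoff(5, pool, n_resample = 20000, seed = 3)
  expect_equal(mc, exact)
})

test_that("lncRNA hit calls apply k_min per target", {
  growth <- data.frame(
    aso_id = sprintf("a%d", 1:10),
    significant_inhibition = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                               TRUE, FALSE, FALSE, FALSE, FALSE))
  tm <- data.frame(aso_id = growth$aso_id,
                   target_id = rep(c("t1", "t2"), each = 5))
  cutoffs <- c(t1 = 2, t2 = 2)
  hits <- call_lncrna_hits(growth, tm, cutoffs = cutoffs)
  expect_equal(hits$is_hit, c(TRUE, FALSE))
  expect_equal(hits$n_significant_asos, c(2, 1))
  expect_error(call_lncrna_hits(growth, tm, cutoffs = c(t1 = 2)),
               "absent from supplied cutoffs")
})
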