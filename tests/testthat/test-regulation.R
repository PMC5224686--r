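make_expr <- function(y, o, ids = sprintf("t%03d", seq_along(y))) {
  vals <- cbind(Y_1 = y, Y_2 = y, Y_3 = y, O_1 = o, O_2 = o, O_3 = o)
  rownames(vals) <- ids
  structure(list(values = vals, timepoints = c("Y", "O"),
                 col_tp = rep(c("Y", "O"), each = 3),
                 col_rep = rep(as.character(1:3), 2)),
            class = "expression_table")
}

test_that("fold changes normalize, average and guard zero baselines", {
  tab <- make_expr(c(100, 0, 50), c(89, 10, 50))
  ch <- fold_changes(tab)
  # depth normalization: totals differ between Y (150) and O (149),
  # so verify on a depth-balanced pair instead
  tab2 <- make_expr(c(100, 100), c(89, 111))
  ch2 <- fold_changes(tab2)
  expect_equal(unname(ch2["t001"]), -0.11)
  # zero young mean excluded and counted
  expect_false("t002" %in% names(ch))
  expect_equal(attr(ch, "excluded_zero_young"), 1)
  # rescaling one timepoint's depth leaves changes untouched
  tab3 <- make_expr(c(100, 100), c(89, 111) * 50)
  expect_equal(fold_changes(tab3), ch2)
})

test_that("regulation classes use strict thresholds", {
  ch <- c(a = -0.11, b = -0.05, c = 0.3, d = 0.0)
  expect_equal(unname(classify_regulation(ch, 0.05)),
               c("DOWN", "NEUTRAL", "UP", "NEUTRAL"))
  expect_equal(unname(classify_regulation(ch, 0.10)["a"]), "DOWN")
  expect_equal(unname(classify_regulation(ch, 0.20)["a"]), "NEUTRAL")
  expect_equal(unname(classify_regulation(ch, 0.20)["c"]), "UP")
})

test_that("down/up ratios count strictly and handle the zero-up sentinel", {
  cls <- setNames(c(rep("DOWN", 11), "UP", rep("NEUTRAL", 3)),
                  sprintf("t%02d", 1:15))
  r <- down_up_ratio(names(cls), cls)
  expect_equal(r$ratio, 11)
  expect_equal(r$n_down + r$n_up + r$n_neutral, 15)
  cls2 <- setNames(c(rep("DOWN", 4), rep("UP", 4)), sprintf("u%d", 1:8))
  expect_equal(down_up_ratio(names(cls2), cls2)$ratio, 1)
  cls3 <- setNames(rep("DOWN", 3), c("a", "b", "c"))
  expect_equal(down_up_ratio(c("a", "b", "c"), cls3)$ratio, Inf)
  expect_error(down_up_ratio("zzz", cls), "does not intersect")
})

test_that("resampling is seeded and degenerates to the global ratio", {
  set.seed(300)
  cls <- setNames(sample(c("DOWN", "UP", "NEUTRAL"), 500, replace = TRUE),
                  sprintf("t%03d", 1:500))
  n1 <- resample_null(50, cls, 200, seed = 5)
  n2 <- resample_null(50, cls, 200, seed = 5)
  expect_identical(n1, n2)
  # full-size draws reproduce the global ratio with zero variance
  full <- resample_null(500, cls, 10, seed = 6)
  expect_equal(unique(as.numeric(full)), sum(cls == "DOWN") / sum(cls == "UP"))
  # symmetric null centers near 1
  fin <- n1[is.finite(n1)]
  expect_lt(abs(median(fin) - 1), 0.35)
})

test_that("significance modes agree on extremes and assign tiers", {
  null <- c(seq(0.5, 1.5, length.out = 1000))
  s <- regulation_significance(11, null, "empirical")
  expect_equal(s$p_value, 2 / 1001)
  expect_equal(s$tier, "***")  # p < 0.005 in the star convention
  mid <- regulation_significance(median(null), null, "empirical")
  expect_gt(mid$p_value, 0.9)
  expect_equal(mid$tier, "#")
  tt <- regulation_significance(11, null, "t_test")
  expect_lt(tt$p_value, 1e-10)
  expect_error(regulation_significance(2, rep(1, 100), "t_test"),
               "degenerate")
  expect_equal(trftools:::significance_tier(0.007), "**")
  expect_equal(trftools:::significance_tier(0.03), "*")
  expect_equal(trftools:::significance_tier(0.2), "#")
})

test_that("planted down-regulation is detected across the three thresholds", {
  cfg <- sim_config(seed = 41, n_transcripts = 2000,
                    target_downregulation = 0.15)
  targets <- sprintf("tx%05d", sample.int(2000, 200))
  sim <- simulate_expression(cfg, targets)
  rt <- regulation_test(sim$table, list(trf = targets),
                        n_resamples = 1000, seed = 42)
  expect_equal(nrow(rt$results), 3)
  expect_true(all(rt$results$n_down + rt$results$n_up +
                    rt$results$n_neutral == 200))
  expect_true(all(rt$results$ratio > 1))
  expect_true(all(rt$results$p_value < 0.05))
  expect_true(all(rt$results$tier %in% c("*", "**", "***")))
  # both interpretations of the test are reported side by side
  expect_true(all(is.finite(rt$results$p_empirical)))
  expect_true(all(is.na(rt$results$p_ttest) | rt$results$p_ttest <= 1))
  # reproducibility
  rt2 <- regulation_test(sim$table, list(trf = targets),
                         n_resamples = 1000, seed = 42)
  expect_identical(rt$results, rt2$results)
})

test_that("union target sets are testable like single sets", {
  cfg <- sim_config(seed = 43, n_transcripts = 1500,
                    target_downregulation = 0.12)
  t1 <- sprintf("tx%05d", 1:80)
  t2 <- sprintf("tx%05d", 60:150)
  sim <- simulate_expression(cfg, list(a = t1, b = t2))
  rt <- regulation_test(sim$table,
                        list(a = t1, b = t2, union = union(t1, t2)),
                        thresholds = 0.05, seed = 44)
  u <- rt$results[rt$results$set_id == "union", ]
  expect_equal(u$n_down + u$n_up + u$n_neutral, length(union(t1, t2)))
  expect_lt(u$p_value, 0.05)
})

test_that("change histograms bin half-open at 2.5% multiples and sum to 1", {
  h <- change_histogram(list(x = rep(-0.11, 7)))
  expect_equal(nrow(h), 1)
  expect_equal(c(h$bin_lo, h$bin_hi), c(-0.125, -0.10))
  expect_equal(h$density, 1)
  set.seed(301)
  ch <- rnorm(2000, 0, 0.1)
  h2 <- change_histogram(list(a = ch, b = ch[1:100]))
  for (s in c("a", "b")) {
    expect_equal(sum(h2$density[h2$set_id == s]), 1, tolerance = 1e-9)
  }
  expect_true(all(abs(h2$bin_lo / 0.025 - round(h2$bin_lo / 0.025)) < 1e-9))
  # boundary values fall in the bin they open
  hb <- change_histogram(list(e = c(-0.05, 0.05)))
  expect_setequal(hb$bin_lo, c(-0.05, 0.05))
})
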