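test_that("rank-sum exact mode matches hand calculation and the enumeration oracle", {
  rs <- ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 0.1)                         # 2/20 by enumeration
  expect_identical(rs$method, "exact")

  expect_equal(ranksum(c(2, 4, 6), c(2, 4, 6))$p, 1)   # identical multisets
  expect_warning(p_deg <- ranksum(rep(3, 5), rep(3, 7))$p, "zero pooled SD")
  expect_equal(p_deg, 1)                               # fully degenerate

  set.seed(11)
  for (r in 1:25) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    pool <- sample(1000, n1 + n2)                 # tie-free
    x <- pool[seq_len(n1)]
    y <- pool[-seq_len(n1)]
    expect_equal(ranksum(x, y)$p, ranksum_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("p-values are invariant to monotone transforms and agree with wilcox.test", {
  set.seed(12)
  x <- rnorm(15)
  y <- rnorm(18, 0.4)
  p1 <- ranksum(x, y)$p
  expect_equal(ranksum(exp(x), exp(y))$p, p1, tolerance = 1e-12)
  # tie-corrected normal path cross-checked against the base implementation
  xi <- sample(5, 20, TRUE)
  yi <- sample(5, 25, TRUE)
  ours <- ranksum(xi, yi)$p
  base <- suppressWarnings(stats::wilcox.test(xi, yi, exact = FALSE,
                                              correct = TRUE))$p.value
  expect_equal(ours, base, tolerance = 1e-10)
})

test_that("post-hoc power follows the noncentral t and its limits", {
  es <- posthoc_power(c(0, 1, -1, 0.5, -0.5), c(1, 2, 0, 1.5, 0.5))
  sp <- sqrt((var(c(0, 1, -1, 0.5, -0.5)) + var(c(1, 2, 0, 1.5, 0.5))) / 2)
  expect_equal(es$effect_size, -1 / sp)

  pw <- posthoc_power(d = 1, n1 = 30, n2 = 30)$power
  expect_equal(pw, stats::power.t.test(n = 30, delta = 1, sd = 1)$power,
               tolerance = 1e-6)
  # Monte Carlo oracle: simulated two-sample t tests at d = 1
  set.seed(13)
  rej <- mean(replicate(3000, {
    stats::t.test(rnorm(30, 1), rnorm(30), var.equal = TRUE)$p.value <= 0.05
  }))
  expect_equal(rej, pw, tolerance = 0.025)
  expect_equal(posthoc_power(d = 0, n1 = 40, n2 = 40)$power, 0.05,
               tolerance = 1e-9)
  expect_warning(posthoc_power(rep(1, 5), rep(1, 5)), "zero pooled SD")
})

test_that("rank-sum rejection rate at d = 1 tracks the t-test power prediction", {
  set.seed(14)
  n <- 30
  rej <- mean(replicate(400, ranksum(rnorm(n, 1), rnorm(n))$p <= 0.05))
  pred <- posthoc_power(d = 1, n1 = n, n2 = n)$power
  expect_equal(rej, pred, tolerance = 0.06)   # ARE of ranks vs t is ~0.95
})

test_that("the comparison harness localizes a planted stage-2 alpha shift", {
  set.seed(15)
  ft <- gaussian_feature_table(60, shift_stage = 2, shift = 1)
  res <- run_comparisons(ft, comparison_plan(measures = "alpha",
                                             regions = "whole"))
  expect_identical(nrow(res), 3L)
  with2 <- grepl("2", res$contrast)
  expect_true(all(res$p[with2] < 0.001))
  expect_gt(res$p[!with2], 0.05)
  expect_true(all(res$stars[with2] == "***"))
  expect_true(all(abs(res$effect_size[with2]) > 0.5))
})

test_that("left and right hemispheres behave alike under a symmetric generator", {
  set.seed(16)
  ft <- gaussian_feature_table(80)
  res <- run_comparisons(ft, comparison_plan(measures = "alpha",
                                             regions = c("left", "right")))
  expect_identical(nrow(res), 6L)
  expect_true(all(res$p > 0.001))    # null data: no spurious strong effects
})

test_that("contrasts with an empty group are skipped with a message", {
  set.seed(17)
  ft <- gaussian_feature_table(30, stages = c(1, 3))
  expect_message(
    res <- run_comparisons(ft, comparison_plan(measures = "alpha",
                                               regions = "whole")),
    "empty group")
  expect_identical(nrow(res), 1L)
  expect_identical(res$contrast, "1 vs 3")
})

test_that("optional BH adjustment only increases p-values", {
  set.seed(18)
  ft <- gaussian_feature_table(40)
  raw <- run_comparisons(ft, comparison_plan(measures = c("alpha", "high_beta"),
                                             regions = "whole"))
  adj <- run_comparisons(ft, comparison_plan(measures = c("alpha", "high_beta"),
                                             regions = "whole", adjust = "BH"))
  expect_true(all(adj$p >= raw$p - 1e-12))
})
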