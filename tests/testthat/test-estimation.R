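test_that("paired mean difference follows its arithmetic definition", {
  expect_equal(paired_mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(paired_mean_difference(c(0, 0, 0), c(1, 2, 3)), 2)
  x <- c(1.5, -2, 4); y <- c(0.3, 8, -1)
  expect_equal(paired_mean_difference(y, x), -paired_mean_difference(x, y))
  expect_error(paired_mean_difference(1:3, 1:4), "lengths")
})

test_that("BCa interval matches an independent transcription on shared resamples", {
  x <- c(1, 2, 3, 4, 5)
  set.seed(99)
  boot_stats <- rowMeans(matrix(sample(x, 5 * 4000, replace = TRUE), 4000))
  mine <- bca_bootstrap_ci(x, boot_stats = boot_stats)
  ref <- reference_bca(x, boot_stats)
  expect_equal(as.numeric(mine), ref, tolerance = 1e-9)
  # degenerate data give the degenerate interval
  expect_equal(as.numeric(bca_bootstrap_ci(rep(2.5, 6))), c(2.5, 2.5))
  # deterministic under a fixed seed
  expect_identical(bca_bootstrap_ci(x, 1000, seed = 7),
                   bca_bootstrap_ci(x, 1000, seed = 7))
})

test_that("BCa endpoints agree with boot::boot.ci within Monte-Carlo error", {
  skip_if_not_installed("boot")
  set.seed(3)
  x <- rnorm(15, mean = 2, sd = 1.5) + rexp(15)  # mildly skewed sample
  mine <- bca_bootstrap_ci(x, n_resamples = 20000, seed = 5)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 20000)
  bc <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # independent resample streams: endpoints agree to a few SE of a quantile
  tol <- 3 * stats::sd(bt$t) / sqrt(20000) * 15
  expect_lt(abs(mine[["ci_low"]] - bc[1]), tol)
  expect_lt(abs(mine[["ci_high"]] - bc[2]), tol)
})

test_that("BCa reduces to the percentile interval for a symmetric bootstrap distribution", {
  set.seed(11)
  x <- rnorm(40)  # large symmetric sample: z0 ~ 0, a ~ 0
  b <- bca_bootstrap_ci(x, n_resamples = 10000, seed = 2)
  set.seed(2)
  idx <- sample.int(40, 40 * 10000, replace = TRUE)
  boots <- rowMeans(matrix(x[idx], nrow = 10000))
  perc <- quantile(boots, c(0.025, 0.975), names = FALSE)
  se <- sd(boots)
  expect_lt(abs(b[["ci_low"]] - perc[1]), 0.1 * se)
  expect_lt(abs(b[["ci_high"]] - perc[2]), 0.1 * se)
})

test_that("exhaustive sign-flip enumeration gives exact small-sample p-values", {
  # all-positive differences, m = 5: only the identity and the full flip
  # reach |t_obs|, so p = 2/32 exactly
  res <- permutation_t_test(c(1, 2, 3, 4, 5), design = "one_group")
  expect_identical(res$p_value, 2 / 32)
  expect_identical(res$n_permutations, 32L)
  expect_true(res$exhaustive)
  # identical samples, unpaired: every relabelling ties the observed t
  res2 <- permutation_t_test(c(1, 2, 3), c(1, 2, 3), design = "unpaired")
  expect_identical(res2$p_value, 1)
  # degenerate zero-variance data
  expect_identical(permutation_t_test(rep(0, 5), design = "one_group")$p_value,
                   1)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration within 3 SE", {
  set.seed(6)
  d <- rnorm(10, mean = 0.6)
  exact <- permutation_t_test(d, design = "one_group")$p_value
  mc <- permutation_t_test(d, design = "one_group", max_exhaustive = 2,
                           n_resamples = 4000, seed = 8)
  expect_false(mc$exhaustive)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1 / 4000)
  # deterministic under a fixed seed
  mc2 <- permutation_t_test(d, design = "one_group", max_exhaustive = 2,
                            n_resamples = 4000, seed = 8)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("paired and one-group designs coincide when one condition is identically zero", {
  set.seed(14)
  y <- rnorm(8, 1)
  a <- permutation_t_test(rep(0, 8), y, design = "paired")
  b <- permutation_t_test(y, design = "one_group")
  expect_identical(a$p_value, b$p_value)
})

test_that("correlation helpers follow Pearson/Spearman conventions", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlations(x, 2 * x + 1), 1)
  y <- exp(x)  # monotone but nonlinear
  expect_equal(correlations(x, y, kind = "spearman"), 1)
  expect_lt(correlations(x, y), 1)
  # 5-point set against a brute-force rank computation
  b <- c(3, 1, 4, 1, 5)
  expect_equal(correlations(x, b, kind = "spearman"),
               cor(rank(x), rank(b)))
  expect_error(correlations(x, rep(1, 5)), "variance")
  expect_error(correlations(1:2, 1:2), "length")
})

test_that("group summaries report estimates, CIs and p-values per contrast", {
  set.seed(19)
  df <- tibble::tibble(
    id = rep(sprintf("d%02d", 1:8), 2),
    condition = rep(c("baseline", "drug"), each = 8),
    nl = c(rnorm(8, 50, 10), rnorm(8, 10, 10))
  )
  # one-group-vs-zero per condition
  s1 <- group_summary(df, nl, condition, design = "one_group_vs_zero",
                      n_resamples = 1000, seed = 4)
  expect_identical(nrow(s1), 2L)
  expect_true(all(s1$ci_low <= s1$estimate & s1$estimate <= s1$ci_high))
  # paired contrast recovers the mean within-unit difference
  s2 <- group_summary(df, nl, condition, pair_id = id, design = "paired",
                      n_resamples = 1000, seed = 4)
  d <- df$nl[df$condition == "drug"] - df$nl[df$condition == "baseline"]
  expect_equal(s2$estimate, mean(d))
  expect_lt(s2$p_value, 0.05)
  # identical groups: difference 0, p = 1
  df2 <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                        v = rep(c(1, 2, 3, 4), 2))
  s3 <- group_summary(df2, v, g, design = "unpaired",
                      n_resamples = 500, seed = 4)
  expect_equal(s3$estimate, 0)
  expect_identical(s3$p_value, 1)
  # a single-unit group is skipped with a warning
  df3 <- tibble::tibble(g = c("a", "a", "b"), v = c(1, 2, 3))
  expect_warning(out <- group_summary(df3, v, g,
                                      design = "one_group_vs_zero",
                                      n_resamples = 200, seed = 1),
                 "skipped")
  expect_identical(nrow(out), 1L)
})

test_that("known-shift simulation: the BCa interval brackets the true shift at ~95%", {
  set.seed(27)
  hits <- 0; n_sim <- 200; delta <- 1
  for (i in 1:n_sim) {
    d <- rnorm(10, mean = delta)
    ci <- bca_bootstrap_ci(d, n_resamples = 1000)
    hits <- hits + (ci[["ci_low"]] <= delta && delta <= ci[["ci_high"]])
  }
  expect_gt(hits / n_sim, 0.88)
  expect_lt(hits / n_sim, 0.99)
})
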