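# Agreement statistics: relative differences, signed-rank test,
# Bland-Altman limits of agreement.

# independent enumeration oracle for the exact signed-rank p value
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- apply(as.matrix(expand.grid(rep(list(0:1), n))), 1,
              function(s) sum(r * s))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

test_that("relative difference is the percent of the pair mean", {
  expect_equal(relative_difference(1, 1), 0)
  expect_equal(relative_difference(0.9, 1.1), -20)
  expect_equal(relative_difference(1.1, 0.9),
               -relative_difference(0.9, 1.1))
  expect_warning(out <- relative_difference(0, 0), "zero mean")
  expect_true(is.na(out))
})

test_that("symmetric differences give p = 1 and same-sign runs are
           significant", {
  expect_equal(rank_test(c(1, -1, 2, -2, 3, -3))$p_value, 1)
  rt <- rank_test(rep(c(0.5, 1, 1.5, 2, 2.5), 2))
  expect_true(rt$exact)
  expect_lt(rt$p_value, 0.05)
  expect_warning(z <- rank_test(c(0, 0, 0)), "zero")
  expect_equal(z$p_value, 1)
})

test_that("exact branch equals enumeration and wilcox.test for n <= 10", {
  set.seed(3)
  for (n in 5:10) {
    for (rep in 1:3) {
      d <- round(rnorm(n, 0.3, 1), 3)
      d <- d[d != 0]
      rt <- rank_test(d)
      expect_true(rt$exact)
      expect_equal(rt$p_value, signed_rank_oracle(d), tolerance = 1e-12)
      if (!any(duplicated(abs(d)))) {
        wt <- wilcox.test(d, exact = TRUE)
        expect_equal(rt$p_value, wt$p.value, tolerance = 1e-12)
      }
    }
  }
})

test_that("large-sample branch approximates the exact p value", {
  set.seed(4)
  d <- rnorm(30, 0.3, 1)
  rt <- rank_test(d)
  expect_false(rt$exact)
  wt <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(rt$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("rank-sum variant delegates to the two-sample test", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12, 1)
  rt <- rank_test(x, y, type = "rank_sum")
  expect_equal(rt$p_value, wilcox.test(x, y)$p.value)
})

test_that("Bland-Altman reproduces the mean +/- 1.96 SD construction", {
  # identical methods: zero mean difference, zero-width limits
  x <- c(1, 2, 3, 4)
  ba0 <- suppressWarnings(bland_altman(x, x))
  expect_equal(ba0$mean_diff_pct, 0)
  expect_equal(ba0$loa_halfwidth_pct, 0)
  # machine-precision agreement with a direct recomputation
  set.seed(6)
  y <- exp(rnorm(20, 0, 0.1))
  z <- exp(rnorm(20, 0.05, 0.1))
  ba <- bland_altman(y, z)
  d <- 100 * (y - z) / ((y + z) / 2)
  expect_equal(ba$mean_diff_pct, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff_pct, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_halfwidth_pct, 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_lower_pct, mean(d) - 1.96 * sd(d),
               tolerance = 1e-12)
  expect_equal(ba$median_diff_pct, median(d), tolerance = 1e-12)
  expect_equal(ba$median_diff_abs, median(y - z), tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("limits of agreement cover about 95% of normal differences", {
  set.seed(7)
  n <- 1000
  y <- exp(rnorm(n, 0, 0.001))
  z <- y * exp(rnorm(n, 0, 0.05))
  ba <- bland_altman(y, z)
  inside <- mean(ba$pair_diff_pct >= ba$loa_lower_pct &
                   ba$pair_diff_pct <= ba$loa_upper_pct)
  # binomial 99.9% band around 0.95 at n = 1000
  expect_gt(inside, 0.95 - 3.3 * sqrt(0.95 * 0.05 / n))
  expect_lt(inside, 0.95 + 3.3 * sqrt(0.95 * 0.05 / n))
})

test_that("comparison table reproduces injected bias ordering", {
  set.seed(8)
  n <- 40
  inst <- seq_len(n)
  d3 <- exp(rnorm(n, 0, 0.1))
  doses <- rbind(
    data.frame(region = "kidneys", instance = inst, method = "3D",
               dose_Gy_per_GBq = d3),
    data.frame(region = "kidneys", instance = inst, method = "2D",
               dose_Gy_per_GBq = d3 * exp(rnorm(n, -0.10, 0.05))),
    data.frame(region = "kidneys", instance = inst, method = "hybrid",
               dose_Gy_per_GBq = d3 * exp(rnorm(n, -0.03, 0.05))))
  ct <- comparison_table(doses)
  r2 <- ct[ct$comparison == "2D vs 3D", ]
  rh <- ct[ct$comparison == "hybrid vs 3D", ]
  expect_lt(r2$median_diff_pct, 0)
  expect_lt(rh$median_diff_pct, 0)
  expect_gt(abs(r2$median_diff_pct), abs(rh$median_diff_pct))
})

test_that("comparison table handles identical methods and single pairs", {
  doses <- rbind(
    data.frame(region = "liver", instance = 1:3, method = "3D",
               dose_Gy_per_GBq = c(1, 2, 3)),
    data.frame(region = "liver", instance = 1:3, method = "2D",
               dose_Gy_per_GBq = c(1, 2, 3)))
  ct <- suppressWarnings(comparison_table(doses))
  expect_equal(ct$median_diff_pct, 0)
  expect_equal(ct$p_value, 1)
  single <- rbind(
    data.frame(region = "liver", instance = 1, method = "3D",
               dose_Gy_per_GBq = 1.0),
    data.frame(region = "liver", instance = 1, method = "2D",
               dose_Gy_per_GBq = 0.9))
  ct1 <- comparison_table(single, methods = "2D")
  expect_equal(ct1$median_diff_Gy_per_GBq, -0.1, tolerance = 1e-12)
  # unmatched instances are dropped with a message
  expect_message(
    suppressWarnings(
      comparison_table(rbind(doses,
                             data.frame(region = "liver", instance = 4,
                                        method = "2D",
                                        dose_Gy_per_GBq = 1)))),
    "unmatched")
})
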