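test_that("basic daily test: nulls, skipping, and degenerate series", {
  # single-day series: the null equals the day's own proportions, so the
  # observation is modal and p = 1
  s1 <- make_series(rbind(c(30, 10, 10)))
  r1 <- basic_daily_test(s1)
  expect_equal(r1$p_value, 1, tolerance = 1e-9)
  expect_equal(r1$method, "exact")

  # zero-volume days are skipped, not rejected
  s2 <- make_series(rbind(c(30, 10, 10), c(0, 0, 0), c(28, 12, 10)))
  r2 <- basic_daily_test(s2)
  expect_true(r2$skipped[2])
  expect_equal(r2$skip_reason[2], "low_volume")
  expect_false(any(r2$skipped[c(1, 3)]))
  expect_true(all(r2$p_value[!r2$skipped] >= 0 &
                    r2$p_value[!r2$skipped] <= 1))

  # min_volume threshold respected
  r3 <- basic_daily_test(s2, min_volume = 60)
  expect_true(all(r3$skipped))
  expect_error(basic_daily_test(make_series(rbind(c(0, 0, 0)))),
               "zero total volume")
})

test_that("basic test switches to seeded Monte Carlo above the exact cap", {
  s <- make_series(rbind(c(30, 10, 10), c(2600, 700, 600)))
  r1 <- basic_daily_test(s, seed = 5)
  r2 <- basic_daily_test(s, seed = 5)
  expect_equal(r1$method, c("exact", "monte_carlo"))
  expect_identical(r1$p_value, r2$p_value)
})

test_that("running test builds its null from the preceding window", {
  # abrupt +0.15 shift in p_F after a stable stretch is flagged hard
  stable <- matrix(rep(c(350, 80, 70), 20), ncol = 3, byrow = TRUE)
  shifted <- c(425, 40, 35)  # p_F = 0.85 at volume 500
  s <- make_series(rbind(stable, shifted))
  r <- running_daily_test(s, window = 15)
  expect_true(all(r$skipped[1:15]))
  expect_equal(r$skip_reason[1], "warmup")
  expect_lt(r$p_value[21], 0.01)
  # stable days in between are not flagged
  expect_true(all(r$p_value[16:20] > 0.99))

  # a category absent from the running null but observed today: p = 0
  zeroC <- matrix(rep(c(50, 0, 10), 16), ncol = 3, byrow = TRUE)
  s0 <- make_series(rbind(zeroC, c(45, 5, 10)))
  r0 <- running_daily_test(s0, window = 15)
  expect_equal(r0$p_value[17], 0)

  # window as long as the series: nothing tested
  rall <- running_daily_test(s, window = nrow(s))
  expect_true(all(rall$skipped))

  # insufficient non-empty history is skipped
  sparse <- make_series(rbind(matrix(0, 14, 3), c(10, 2, 2), c(9, 3, 3)))
  rs <- running_daily_test(sparse, window = 15, min_history = 5)
  expect_equal(rs$skip_reason[16], "insufficient_history")

  # pooled-count null variant runs and stays in [0, 1]
  rp <- running_daily_test(s, window = 15, null_type = "pooled")
  expect_true(all(rp$p_value[!rp$skipped] >= 0 &
                    rp$p_value[!rp$skipped] <= 1))
  expect_error(running_daily_test(s, window = 1), "window")
})

test_that("running-variance statistic and p-value follow the chi-square law", {
  set.seed(3)
  x <- rnorm(60, 0.7, 0.03)
  w <- 15
  out <- running_variance_pvalues(x, window = w)
  sigma0 <- var(x)
  # recompute day 40 from the definition as an oracle
  t <- 40
  s2 <- var(x[(t - w + 1):t])
  T_stat <- (w - 1) * s2 / sigma0
  expect_equal(out$statistic[t], T_stat, tolerance = 1e-12)
  expect_equal(out$p_value[t],
               min(1, 2 * min(pchisq(T_stat, w - 1),
                              1 - pchisq(T_stat, w - 1))),
               tolerance = 1e-12)
  expect_equal(out$direction[t], if (s2 >= sigma0) "high" else "low")
  expect_true(all(out$skipped[1:(w - 1)]))

  # a window with constant values: T = 0, direction low, p = 0
  xc <- c(rnorm(30, 0.7, 0.05), rep(0.7, 15))
  outc <- running_variance_pvalues(xc, window = 15)
  expect_equal(outc$statistic[45], 0)
  expect_equal(outc$direction[45], "low")
  expect_equal(outc$p_value[45], 0)

  # s_w^2 equal to the reference variance at w = 15 -> T = 14
  xx <- rnorm(20, 0, 1)
  s2w <- var(xx[6:20])
  out2 <- running_variance_pvalues(xx, window = 15, sigma0_sq = s2w)
  expect_equal(out2$statistic[20], 14, tolerance = 1e-12)
  expect_equal(out2$p_value[20],
               2 * min(pchisq(14, 14), 1 - pchisq(14, 14)),
               tolerance = 1e-12)

  expect_error(running_variance_pvalues(rep(1, 20), window = 15),
               "positive")
  expect_error(running_variance_pvalues(x, window = 2), "window")
})

test_that("running-variance test is invariant to shifting all proportions", {
  set.seed(9)
  x <- rnorm(50, 0.5, 0.04)
  a <- running_variance_pvalues(x, window = 10)
  b <- running_variance_pvalues(x + 0.17, window = 10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)

  # series interface: NA (zero-volume) days do not enter windows
  counts <- t(sapply(rnorm(40, 0.7, 0.03),
                     function(p) c(round(1000 * p), round(1000 * (1 - p)), 0)))
  counts[10, ] <- 0
  s <- make_series(counts)
  r <- running_variance_test(s, window = 15)
  expect_true(r$skipped[10])
  expect_equal(r$skip_reason[10], "no_data")
  expect_equal(sum(!r$skipped), 39 - 14)
})

test_that("rejection summaries count and expect correctly", {
  res <- data.frame(
    date = seq(as.Date("2018-01-01"), length.out = 8, by = "day"),
    p_value = c(0.001, 0.03, 0.07, 0.2, 0.5, NA, 0.009, 1),
    skipped = c(rep(FALSE, 5), TRUE, FALSE, FALSE))
  s <- rejection_summary(res, alphas = c(0.10, 0.05, 0.01))
  expect_equal(s$tested_days, rep(7, 3))
  expect_equal(s$rejected_days, c(4L, 3L, 2L))
  expect_equal(s$expected_days, c(0.7, 0.35, 0.07))
  # monotone non-decreasing in alpha
  expect_true(all(diff(s$rejected_days[order(s$alpha)]) >= 0))

  # the benchmark arithmetic: 365 tested days at the 5% level
  res365 <- data.frame(p_value = runif(365), skipped = FALSE)
  s365 <- rejection_summary(res365, alphas = 0.05)
  expect_equal(s365$expected_days, 18.25)

  expect_equal(rejection_summary(res[0, ], 0.05)$rejected_days, 0L)
  all1 <- data.frame(p_value = rep(1, 10), skipped = FALSE)
  expect_equal(rejection_summary(all1, 0.05)$rejected_days, 0L)
})

test_that("window sensitivity table matches direct calls", {
  set.seed(21)
  counts <- t(rmultinom(60, 300, c(0.7, 0.164, 0.136)))
  s <- make_series(counts)
  tab <- window_sensitivity(s, windows = c(7, 15), seed = 1)
  expect_equal(nrow(tab), 2 * 2 * 3)      # windows x tests x alphas
  direct <- rejection_summary(running_daily_test(s, window = 15, seed = 1))
  got <- tab[tab$window == 15 & tab$test == "running", ]
  expect_equal(got$rejected_days, direct$rejected_days)
  expect_equal(got$tested_days, direct$tested_days)

  empty <- window_sensitivity(s, windows = integer(0))
  expect_equal(nrow(empty), 0)
})
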