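test_that("uptake proxy differentiates and smooths as specified", {
  t <- seq(0, 86400 - 600, by = 600)
  # constant content: no uptake
  expect_true(all(rwu_series(t, rep(0.3, length(t)))$rwu == 0))
  # linear decline at rate s: flat uptake of s away from edges
  s <- 1e-7
  r <- rwu_series(t, 0.3 - s * t)
  mid <- seq(20, length(t) - 20)
  expect_lt(max(abs(r$rwu[mid] - s)), 1e-18)
  # symmetric drawdown peaking 14:00: the filter chain preserves the peak
  h <- t / 3600
  rate <- exp(-((h - 14) / 2)^2 / 2)
  theta <- 0.35 - cumsum(rate) * 1e-5 + rate / 2 * 1e-5
  r2 <- rwu_series(t, theta)
  expect_lt(abs(r2$t[which.max(r2$rwu)] / 3600 - 14), 600 / 3600 + 1e-9)
  # irregular grids error unless resampled
  t_bad <- t; t_bad[5] <- t_bad[5] + 100
  expect_error(rwu_series(t_bad, theta), "resample")
  expect_silent(rwu_series(t_bad, theta, resample = TRUE))
})

test_that("wet days and their successors are excluded", {
  expect_equal(wet_day_mask(c(0, 0.2, 0, 0), threshold = 0.15),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(wet_day_mask(rep(0, 5), threshold = 0.15), rep(FALSE, 5))
  # consecutive wet days: each wet day plus the single trailing day
  expect_equal(wet_day_mask(c(0, 1, 1, 0, 0), threshold = 0.15),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # default threshold is the first quartile
  p <- c(0, 0, 0.1, 0.4, 2, 0, 0, 0.05)
  expect_equal(wet_day_mask(p),
               wet_day_mask(p, threshold = quantile(p, 0.25, names = FALSE)))
})

test_that("daily peak times are found per day with ties to the earliest", {
  t <- seq(0, 3 * 86400 - 600, by = 600)
  h <- (t %% 86400) / 3600
  y <- sin(pi * pmax(pmin((h - 6.5) / 12, 1), 0))  # peak 12:30
  pk <- daily_peak_times(t, y)
  expect_equal(nrow(pk), 3)
  expect_true(all(abs(pk$peak_hour - 12.5) <= 600 / 3600 + 1e-9))
  # a single spike wins its day
  y2 <- rep(0, length(t)); y2[h == 9 & t < 86400] <- 1
  pk2 <- daily_peak_times(t, y2)
  expect_equal(pk2$peak_hour[1], 9)
  # excluded days are dropped
  pk3 <- daily_peak_times(t, y, exclude_days = c(FALSE, TRUE, FALSE))
  expect_equal(pk3$day, c(0, 2))
})

test_that("timing distributions fit by ML and KDE with credible modes", {
  set.seed(99)
  x <- rgamma(500, shape = 9, scale = 1.5)
  fit <- fit_timing_distribution(x, "gamma")
  expect_equal(fit$mean, 13.5, tolerance = 0.05)
  expect_equal(fit$shape * fit$scale, fit$mean)
  k1 <- fit_timing_distribution(x[x < 24], "kde")
  expect_equal(length(k1$modes), 1)
  expect_equal(k1$modes, 12, tolerance = 0.2)    # gamma mode (a-1)*scale
  set.seed(3)
  tt <- c(rnorm(200, 9, 0.8), rnorm(200, 14, 0.8))
  k2 <- fit_timing_distribution(tt, "kde")
  expect_equal(length(k2$modes), 2)
  expect_lt(abs(k2$modes[1] - 9), 0.5)
  expect_lt(abs(k2$modes[2] - 14), 0.5)
  expect_error(fit_timing_distribution(c(-1, 2), "gamma"), "negative")
  expect_error(fit_timing_distribution(1:5, "gamma"), ">= 10")
})

test_that("mean lag is the day-matched difference and offset-invariant", {
  a <- data.frame(day = 0:19, peak_hour = rep(12, 20))
  b <- data.frame(day = 0:19, peak_hour = rep(12, 20))
  expect_equal(mean_lag(a, b)$mean_pairwise, 0)
  b$peak_hour <- b$peak_hour + 1.5
  expect_equal(mean_lag(a, b)$mean_pairwise, 1.5)
  # adding a constant clock offset to both series leaves the lag unchanged
  a2 <- a; b2 <- b
  a2$peak_hour <- a2$peak_hour + 2; b2$peak_hour <- b2$peak_hour + 2
  expect_equal(mean_lag(a2, b2)$mean_pairwise, 1.5)
  expect_error(mean_lag(a, data.frame(day = 100, peak_hour = 1)), "matched")
})

test_that("the full pipeline recovers an imposed 2-h lag from a synthetic month", {
  spec <- generator_spec(seed = 42, lag_h = 2, n_days = 60)
  d <- gen_diel(spec)
  rwu <- rwu_series(d$t, d$theta)
  mask <- wet_day_mask(tapply(d$precip_mm_day, d$day, max), threshold = 0.15)
  pk_s <- daily_peak_times(d$t, d$qs, exclude_days = mask)
  pk_r <- daily_peak_times(rwu$t, rwu$rwu, exclude_days = mask)
  lag <- mean_lag(pk_s, pk_r)
  expect_equal(lag$mean_pairwise, 2, tolerance = 0.1 / 2)  # 2.0 +- 0.1 h
  expect_equal(lag$mean_dist_diff, 2, tolerance = 0.15 / 2)
})
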