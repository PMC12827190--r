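test_that("RR intervals and cumulative times follow the definitions", {
  s1 <- compute_rr(c(0.5, 1.3, 2.1))
  expect_equal(s1$rr, c(0.8, 0.8))
  expect_equal(s1$x, c(0.8, 1.6))
  s2 <- compute_rr(c(0, 1, 3))
  expect_equal(s2$rr, c(1, 2))
  expect_equal(s2$x, c(1, 3))
  expect_false(s2$corrected)
  expect_false(any(s2$outlier_mask))
  expect_error(compute_rr(c(0, 1)), class = "mecg_insufficient_beats")
})

test_that("outlier flagging applies the mu +/- n*sigma band once", {
  rr <- c(rep(0.8, 4), 1.6, rep(0.8, 5))
  s <- flag_rr_outliers(compute_rr(c(0, cumsum(rr))), n = 1.5)
  expect_equal(s$stats$mu_RR, 0.88)
  expect_equal(s$stats$sigma_RR, 0.24)
  expect_equal(which(s$outlier_mask), 5)
  # constant series: zero-width band contains everything (dyadic value so
  # the cumulative times reconstruct the intervals exactly)
  cst <- flag_rr_outliers(compute_rr(c(0, cumsum(rep(0.5, 10)))))
  expect_equal(cst$stats$sigma_RR, 0)
  expect_false(any(cst$outlier_mask))
  # huge multiplier flags nothing
  s2 <- flag_rr_outliers(compute_rr(c(0, cumsum(rr))), n = 100)
  expect_false(any(s2$outlier_mask))
})

test_that("correction interpolates flagged intervals without changing x", {
  rr <- c(0.8, 0.8, 1.6, 0.8, 0.8)
  s <- flag_rr_outliers(compute_rr(c(0, cumsum(rr))), n = 1.5)
  expect_equal(which(s$outlier_mask), 3)
  cs <- correct_rr(s)
  expect_equal(cs$rr_corrected[3], 0.8)
  expect_identical(cs$x, s$x)           # cumulative axis untouched
  expect_equal(length(cs$rr_corrected), length(rr))
  # flagged first interval: nearest-valid constant extension
  s2 <- compute_rr(c(0, cumsum(c(2, 0.8, 0.8, 0.8, 0.8))))
  s2 <- flag_rr_outliers(s2, n = 1)
  expect_true(s2$outlier_mask[1])
  expect_equal(correct_rr(s2)$rr_corrected[1], 0.8)
  # no flags: identity
  s3 <- correct_rr(flag_rr_outliers(compute_rr(c(0, cumsum(rep(0.5, 6))))))
  expect_false(any(s3$outlier_mask))
  expect_identical(s3$rr_corrected, s3$rr)
  # all flagged: unusable
  s4 <- flag_rr_outliers(compute_rr(c(0, 1, 2, 3)))
  s4$outlier_mask[] <- TRUE
  expect_error(correct_rr(s4), class = "mecg_unusable_series")
})

test_that("uncorrected intervals conserve total elapsed time", {
  set.seed(4)
  times <- sort(runif(50, 0, 100))
  s <- compute_rr(times)
  expect_lt(abs(sum(s$rr) - (times[50] - times[1])), 1e-9)
  expect_lt(max(abs(diff(c(0, s$x)) - s$rr)), 1e-12)
})

test_that("flag + correct repairs deleted beats without trimming", {
  spec <- synthetic_spec(seed = 3)
  gt <- simulate_rr(spec)
  thin <- drop_peaks(gt$true_peak_times_s, frac = 0.05, seed = 3)
  s <- correct_rr(flag_rr_outliers(compute_rr(thin), n = 1.5))
  expect_equal(length(s$rr_corrected), length(thin) - 1)  # no trimming
  truth_mean <- mean(gt$true_rr_s)
  truth_sdnn <- sqrt(mean((gt$true_rr_s - truth_mean)^2))
  got_mean <- mean(s$rr_corrected)
  got_sdnn <- sqrt(mean((s$rr_corrected - got_mean)^2))
  expect_lt(abs(got_mean - truth_mean) / truth_mean, 0.01)
  expect_lt(abs(got_sdnn - truth_sdnn) / truth_sdnn, 0.10)
  raw_sdnn <- sqrt(mean((s$rr - mean(s$rr))^2))
  expect_gt(abs(raw_sdnn - truth_sdnn) / truth_sdnn, 0.5)
})

test_that("tachogram resampling reproduces constants, lines and sinusoids", {
  cst <- correct_rr(flag_rr_outliers(compute_rr(c(0, cumsum(rep(0.5, 10))))))
  t1 <- resample_tachogram(cst, n_points = 850)
  expect_equal(t1$n_points, 850)
  expect_equal(unique(round(t1$values, 12)), 0.5)
  expect_equal(t1$rate, 849 / (t1$span[2] - t1$span[1]))
  # RR exactly linear in cumulative time: rr_i = (a + b*x_{i-1}) / (1 - b)
  a <- 0.7; b <- 0.02
  rr <- numeric(20); x <- 0
  for (i in 1:20) { rr[i] <- (a + b * x) / (1 - b); x <- x + rr[i] }
  lin <- correct_rr(flag_rr_outliers(compute_rr(c(0, cumsum(rr))), n = 100))
  t2 <- resample_tachogram(lin, n_points = 200)
  fit <- stats::lm(t2$values ~ t2$times)
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
  # sinusoidal RR evaluated self-consistently at interval end times
  f <- function(x) 0.8 + 0.05 * sin(2 * pi * 0.1 * x)
  tk <- 0
  repeat {
    nxt <- tk[length(tk)] + f(tk[length(tk)] + 0.8)
    for (i in 1:5) nxt <- tk[length(tk)] + f(nxt)
    if (nxt > 300) break
    tk <- c(tk, nxt)
  }
  s <- correct_rr(flag_rr_outliers(compute_rr(tk), n = 100))
  t3 <- resample_tachogram(s, n_points = 850)
  expect_lt(max(abs(t3$values - f(t3$times))), 0.005)
  # preconditions
  expect_error(resample_tachogram(flag_rr_outliers(compute_rr(c(0, 1, 2)))),
               "corrected")
  short <- correct_rr(flag_rr_outliers(compute_rr(c(0, 1, 2, 3))))
  expect_error(resample_tachogram(short), class = "mecg_spline_error")
})
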