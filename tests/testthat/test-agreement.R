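test_that("sequential pairing computes offsets and the quality gate", {
  rep1 <- pair_peaks_sequential(c(1.01, 2.00, 3.05), c(1, 2, 3))
  expect_equal(rep1$pairs$offset_s, c(0.01, 0, 0.05))
  expect_equal(rep1$n_misaligned, 1)
  expect_equal(rep1$pct_misaligned, 100 / 3, tolerance = 1e-9)
  expect_false(rep1$passes_gate)
  ident <- pair_peaks_sequential(1:10, 1:10)
  expect_equal(ident$pairs$offset_s, rep(0, 10))
  expect_equal(ident$beat_count_agreement, 100)
  expect_true(ident$passes_gate)
  expect_error(pair_peaks_sequential(numeric(0), 1:3),
               class = "mecg_empty_input")
})

test_that("gate boundaries follow the 3% / 98% rule exactly", {
  # 98 of 100 beats, all aligned: agreement exactly 98% -> pass
  i <- as.numeric(1:100)
  r98 <- pair_peaks_sequential(i[1:98], i)
  expect_equal(r98$beat_count_agreement, 98)
  expect_true(r98$passes_gate)
  # 979 of 1000 beats: 97.9% -> fail
  i2 <- as.numeric(1:1000)
  r979 <- pair_peaks_sequential(i2[1:979], i2)
  expect_equal(r979$beat_count_agreement, 97.9)
  expect_false(r979$passes_gate)
  # exactly 3% misaligned -> fail; 2.9% -> pass
  mis <- function(k) {
    m <- i2
    m[seq_len(k)] <- m[seq_len(k)] + 0.05
    pair_peaks_sequential(m, i2)
  }
  expect_equal(mis(30)$pct_misaligned, 3)
  expect_false(mis(30)$passes_gate)
  expect_equal(mis(29)$pct_misaligned, 2.9)
  expect_true(mis(29)$passes_gate)
})

test_that("adding a misaligned pair never rescues a failing gate", {
  i <- as.numeric(1:200)
  for (k in c(6, 10, 20)) { # already failing at 3%+
    m <- i; m[seq_len(k)] <- m[seq_len(k)] + 0.05
    base <- pair_peaks_sequential(m, i)
    expect_false(base$passes_gate)
    worse <- pair_peaks_sequential(c(m, 200.5 + 0.05), c(i, 200.5))
    expect_false(worse$passes_gate)
  }
})

test_that("detection benchmarking counts TP/FP/FN within tolerance", {
  b <- benchmark_detection(c(1, 2, 3, 4.2), c(1, 2, 3, 4))
  expect_equal(c(b$tp, b$fp, b$fn), c(3, 1, 1))
  expect_equal(c(b$sensitivity, b$ppv, b$f1), c(0.75, 0.75, 0.75))
  ident <- benchmark_detection(1:50, 1:50)
  expect_equal(c(ident$sensitivity, ident$ppv, ident$f1), c(1, 1, 1))
  disj <- benchmark_detection(c(1, 2, 3), c(10, 20, 30))
  expect_equal(c(disj$tp, disj$f1), c(0, 0))
})

test_that("DTW handles identity, length mismatch, and matches the path oracle", {
  expect_equal(dtw_distance(c(0.8, 0.9, 0.8), c(0.8, 0.9, 0.8)), 0)
  expect_equal(dtw_distance(c(0.8, 0.8), c(0.8, 0.8, 0.8)), 0)
  set.seed(20)
  for (k in 1:25) {
    a <- runif(sample(2:8, 1), 0.5, 1.2)
    b <- runif(sample(2:8, 1), 0.5, 1.2)
    expect_equal(dtw_distance(a, b), oracle_dtw(a, b), tolerance = 1e-12)
  }
  expect_error(dtw_distance(numeric(0), 1:3), class = "mecg_empty_input")
})

test_that("Lin's CCC penalizes bias and never exceeds |Pearson|", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 2.1, 3.1, 4.1)
  expect_equal(lin_ccc(x, x), 1)
  expect_lt(lin_ccc(x, y), 1)
  set.seed(21)
  for (k in 1:20) {
    a <- rnorm(15); b <- rnorm(15) + 0.5 * a
    expect_lte(abs(lin_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(lin_ccc(rep(1, 5), rep(1, 5)), class = "mecg_undefined_statistic")
})

test_that("comparison statistics: identity, shift, ties, and errors", {
  set.seed(22)
  rr <- runif(70, 0.7, 0.9)
  cs <- comparison_stats(rr, rr)
  expect_equal(cs$spearman_rho, 1)
  expect_equal(cs$rmse_s, 0)
  expect_equal(cs$mae_s, 0)
  expect_equal(unlist(cs$bland_altman), c(mean_diff_s = 0, loa_upper_s = 0,
                                          loa_lower_s = 0))
  expect_equal(cs$ccc_mean_rr, 1)
  expect_equal(cs$ccc_rmssd, 1)
  expect_equal(cs$dtw_distance_s, 0)
  # constant shift: BA reflects M - I
  cs2 <- comparison_stats(rr, rr + 0.01)
  expect_equal(cs2$bland_altman$mean_diff_s, -0.01)
  expect_equal(cs2$bland_altman$loa_upper_s - cs2$bland_altman$loa_lower_s, 0,
               tolerance = 1e-12)
  expect_equal(cs2$spearman_rho, 1)
  # exhaustive tie-corrected Mann-Whitney on tiny vectors
  cs3 <- comparison_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cs3$mwu_rr$statistic, 4.5)
  expect_equal(cs3$mwu_rr$p, 1)
  expect_error(comparison_stats(rep(0.8, 10), runif(10)),
               class = "mecg_undefined_statistic")
})

test_that("element-wise statistics match the brute-force oracle", {
  set.seed(23)
  for (k in 1:20) {
    n <- sample(35:90, 1)
    x <- runif(n, 0.6, 1); y <- x + rnorm(n, 0, 0.01)
    cs <- comparison_stats(x, y)
    o <- oracle_stats(x, y)
    expect_rel_equal(cs$rmse_s, o$rmse)
    expect_rel_equal(cs$mae_s, o$mae)
    expect_rel_equal(unlist(cs$bland_altman, use.names = FALSE), o$ba, tol = 1e-11)
  }
})
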