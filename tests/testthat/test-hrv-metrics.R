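series_from_rr <- function(rr) correct_rr(flag_rr_outliers(compute_rr(c(0, cumsum(rr))), n = 1e6))

test_that("time-domain metrics follow the population formulas", {
  m <- time_domain_metrics(series_from_rr(c(0.8, 0.9, 0.8, 0.9)))
  expect_equal(m$mean_rr, 0.85)
  expect_equal(m$sdnn, 0.05)
  expect_equal(m$sd, m$sdnn)
  expect_equal(m$rmssd, 0.1)
  expect_equal(m$cv, 0.05 / 0.85)
  m2 <- time_domain_metrics(series_from_rr(rep(0.7, 6)))
  expect_equal(m2$sdnn, 0)
  expect_equal(m2$rmssd, 0)
  expect_equal(m2$ci95, c(0.7, 0.7))
  m3 <- time_domain_metrics(series_from_rr(c(1, 1, 1.2)))
  expect_equal(m3$rmssd, sqrt((0^2 + 0.2^2) / 2))
  one <- compute_rr(c(0, 1, 2)); one$rr <- one$rr[1]; one$x <- one$x[1]
  one$outlier_mask <- FALSE
  expect_error(time_domain_metrics(one), class = "mecg_insufficient_data")
})

test_that("metrics match the definitional brute-force oracle exactly", {
  set.seed(10)
  for (k in 1:20) {
    rr <- runif(sample(10:60, 1), 0.6, 1.1)
    m <- time_domain_metrics(series_from_rr(rr))
    o <- oracle_stats(rr, rr)
    expect_rel_equal(m$sdnn, o$sdnn)
    expect_rel_equal(m$rmssd, o$rmssd)
    expect_rel_equal(m$cv, o$cv)
    expect_rel_equal(m$ci95, o$ci95)
  }
})

test_that("Welch PSD localizes known tachogram modulations", {
  ts <- seq(0, 358, length.out = 850)
  fs <- 849 / 358
  hf_tach <- list(values = 0.8 + 0.05 * sin(2 * pi * 0.25 * ts), rate = fs,
                  span = range(ts))
  r <- welch_psd(hf_tach)
  expect_lt(abs(r$freqs[which.max(r$psd)] - 0.25), 0.02)
  expect_gt(r$band_powers[["HF"]], 10 * r$band_powers[["LF"]])
  expect_false(r$vlf_interpretable)
  # equal-amplitude LF + HF: band powers within a factor of 2
  mixed <- list(values = 0.8 + 0.05 * sin(2 * pi * 0.1 * ts) +
                  0.05 * sin(2 * pi * 0.25 * ts), rate = fs, span = range(ts))
  r2 <- welch_psd(mixed)
  ratio <- r2$band_powers[["LF"]] / r2$band_powers[["HF"]]
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
  # constant tachogram: nothing left after constant detrend
  r3 <- welch_psd(list(values = rep(0.8, 850), rate = fs))
  expect_lt(sum(r3$psd), 1e-12)
  expect_error(welch_psd(list(values = numeric(0), rate = fs)),
               class = "mecg_empty_input")
  expect_warning(welch_psd(list(values = rnorm(100), rate = fs)), "shrink")
})

test_that("total Welch power approximates the modulation variance", {
  ts <- seq(0, 358, length.out = 850)
  fs <- 849 / 358
  r <- welch_psd(list(values = 0.8 + 0.05 * sin(2 * pi * 0.25 * ts), rate = fs))
  total <- sum(diff(r$freqs) * (head(r$psd, -1) + tail(r$psd, -1)) / 2)
  expect_lt(abs(total - 0.05^2 / 2) / (0.05^2 / 2), 0.2)
})

test_that("Morlet spectrogram maps tones to frequency and beats to bursts", {
  rate <- 200
  sine <- cardiac_trace(sin(2 * pi * 10 * (0:1999) / rate), rate)
  cw <- cwt_spectrogram(sine, n_scales = 64)
  f_hit <- attr(cw, "freqs")[which.max(rowMeans(cw^2))]
  expect_lt(abs(f_hit - 10), 1)
  # zero signal -> all-zero scalogram
  z <- cwt_spectrogram(cardiac_trace(rep(0, 500), rate))
  expect_equal(max(abs(z)), 0)
  # clean ECG: power bursts within 0.05 s of >= 90% of true beats
  ce <- clean_ecg(duration_s = 40, rate = rate)
  cwe <- cwt_spectrogram(ce$trace, n_scales = 32)
  colp <- colSums(cwe^2)
  bursts <- find_candidate_peaks(cardiac_trace(colp + 1e-12, rate), 0.5)
  hits <- vapply(ce$gt$true_peak_times_s,
                 function(t) any(abs(bursts$times - t) <= 0.05), logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(cwt_spectrogram(sine, freq_range = c(0.5, 150)),
               class = "mecg_spec_error")
})

test_that("peak-triggered averaging recovers the beat template", {
  ce <- clean_ecg(duration_s = 60, rate = 200)
  pk <- detect_rpeaks(baseline_normalize(ce$trace))
  avg <- peak_averaged_waveform(ce$trace, pk, half_window_s = 0.3)
  expect_length(avg, 2 * round(0.3 * 200) + 1)
  # identical beats: the average equals any single beat
  i <- pk$indices[5]; hw <- round(0.3 * 200)
  expect_lt(max(abs(avg - ce$trace$values[(i - hw):(i + hw)])), 1e-6)
  # noisy beats: the average converges to the clean template
  set.seed(6)
  noisy <- cardiac_trace(ce$trace$values + 0.3 * rnorm(length(ce$trace$values)),
                         200)
  avg_n <- peak_averaged_waveform(noisy, pk, half_window_s = 0.3)
  expect_gt(cor(avg_n, avg), 0.95)
  few <- pk; few$indices <- pk$indices[1:2]; few$times <- pk$times[1:2]
  expect_error(peak_averaged_waveform(ce$trace, few, 0.3),
               class = "mecg_insufficient_data")
})
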