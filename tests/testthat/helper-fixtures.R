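# Shared in-code fixtures, kept small so unit tests stay fast. A compact
# study spec: 60 s at 200 Hz with 12 channels, used wherever the full
# 5-minute/600-Hz conditions are not the point of the test.

small_spec <- function(seed = 0, ...) {
  args <- list(duration_s = 60, n_channels = 12, seed = seed)
  extra <- list(...)
  do.call(synthetic_spec, utils::modifyList(args, extra))
}

# clean constant-rate ECG trace plus its ground truth
clean_ecg <- function(duration_s = 60, rate = 200, mean_rr_s = 0.8, seed = 0) {
  spec <- synthetic_spec(duration_s = duration_s, mean_rr_s = mean_rr_s,
                         lf = list(freq_hz = 0.1, amp_s = 0),
                         hf = list(freq_hz = 0.25, amp_s = 0),
                         jitter_sd_s = 0, amp_mod_frac = 0, noise_sd = 0,
                         seed = seed)
  gt <- simulate_rr(spec)
  list(trace = synthesize_ecg(gt, rate = rate), gt = gt)
}

# random smooth-ish trace for detector-oracle comparisons
random_trace <- function(n, rate = 100) {
  x <- stats::rnorm(n)
  k <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  k[is.na(k)] <- 0
  cardiac_trace(as.numeric(k) + 1e-3 * stats::rnorm(n), rate)
}
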